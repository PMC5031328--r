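#' Assemble a holo complex from the chains of a PDB file
#'
#' Peptide-bound PDZ structures deposit the domain and the peptide as
#' separate chains; this helper picks which is which. The peptide chain can
#' be named explicitly; otherwise the shortest chain of at most
#' `max_peptide_length` residues is taken as the peptide and the longest
#' chain as the receptor.
#'
#' @param chains Named list of `chain_structure` objects (from
#'   [read_pdb()]).
#' @param peptide_chain Chain id of the peptide, or `NULL` to auto-detect.
#' @param max_peptide_length Longest chain still considered a peptide when
#'   auto-detecting (default 12 residues).
#' @param pdz_id Optional identifier stored on the complex.
#' @return A [complex_structure()]; the peptide slot is `NULL` when no chain
#'   qualifies (apo input).
#' @export
as_holo_complex <- function(chains, peptide_chain = NULL,
                            max_peptide_length = 12L, pdz_id = NULL) {
  stopifnot(is.list(chains), length(chains) >= 1)
  lens <- map_dbl(chains, n_residues)
  if (!is.null(peptide_chain)) {
    if (!peptide_chain %in% names(chains)) {
      abort(paste0("no chain with id '", peptide_chain, "' in input"))
    }
    pep <- chains[[peptide_chain]]
    rec_pool <- chains[names(chains) != peptide_chain]
    receptor <- rec_pool[[which.max(map_dbl(rec_pool, n_residues))]]
    return(complex_structure(receptor, pep, pdz_id = pdz_id))
  }
  receptor <- chains[[which.max(lens)]]
  cand <- chains[lens <= max_peptide_length &
                   names(chains) != receptor$chain_id]
  pep <- if (length(cand) > 0) {
    cand[[which.min(map_dbl(cand, n_residues))]]
  } else NULL
  complex_structure(receptor, pep, pdz_id = pdz_id)
}
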