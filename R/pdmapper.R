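#' Extract C-terminal peptides from a proteome
#'
#' PDZ domains read the extreme C-terminus of their partners, so a proteome
#' is reduced to its set of last-`k`-residue peptides (k = 5 by default)
#' before peptide matching. Sequences shorter than `k` are skipped; the skip
#' count is kept in the `"n_skipped"` attribute.
#'
#' @param proteome FASTA file path, a `Biostrings::AAStringSet`, or a named
#'   character vector of sequences (names are accessions).
#' @param k Number of C-terminal residues to keep (default 5).
#' @return Tibble with `accession` and `cterm` (the last `k` residues), in
#'   input order; attribute `"n_skipped"` counts too-short sequences.
#' @export
extract_cterm <- function(proteome, k = 5L) {
  stopifnot(k >= 1)
  seqs <- if (is.character(proteome) && length(proteome) == 1 &&
              file.exists(proteome)) {
    s <- tryCatch(Biostrings::readAAStringSet(proteome),
                  error = function(e) abort(paste0("malformed FASTA: ",
                                                   conditionMessage(e))))
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else if (inherits(proteome, "AAStringSet")) {
    setNames(as.character(proteome), sub("\\s.*$", "", names(proteome)))
  } else if (is.character(proteome)) {
    if (is.null(names(proteome))) {
      names(proteome) <- sprintf("SEQ%04d", seq_along(proteome))
    }
    proteome
  } else {
    abort("proteome must be a FASTA path, AAStringSet, or named character vector")
  }
  lens <- nchar(seqs)
  keep <- lens >= k
  out <- tibble(
    accession = names(seqs)[keep],
    cterm = unname(substr(seqs[keep], lens[keep] - k + 1L, lens[keep]))
  )
  attr(out, "n_skipped") <- sum(!keep)
  out
}

# Default hydrophobic set for the C-terminal (P0) constraint: covers the
# phi positions of the canonical PDZ class motifs.
HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Match peptides against proteome C-termini
#'
#' Hamming matching of the C-terminal 5-mer of each query peptide against
#' every proteome C-terminus, allowing up to `max_mismatch` mismatches at
#' any position, optionally requiring the matched C-terminal residue (P0) to
#' be hydrophobic (PDZ ligands end hydrophobically). `"X"` in a query (the
#' phage-display wildcard, as in `"XXXXXFETLV"`) matches anything and is not
#' counted as a mismatch; `"X"` in a proteome C-terminus never matches.
#'
#' @param queries Character vector of peptides, each at least 5 residues;
#'   only the last five are used.
#' @param cterms Tibble from [extract_cterm()] (columns `accession`,
#'   `cterm`, 5-mers).
#' @param max_mismatch Maximum mismatches allowed: 0, 1 or 2 (default 0).
#' @param require_hydrophobic_p0 Keep only hits whose matched P0 residue is
#'   hydrophobic (default `TRUE`).
#' @param hydrophobic The hydrophobic residue set (default
#'   A, C, F, I, L, M, V, W, Y).
#' @return Tibble of hits: `query` (as supplied), `accession`, `matched`
#'   (the C-terminal 5-mer), `n_mismatches`, `mismatch_positions`
#'   (comma-joined P-register labels, `""` for exact matches).
#' @examples
#' prot <- make_toy_proteome(5, planted_cterms = "FETLV", seed = 7)
#' ct <- extract_cterm(prot)
#' match_peptides("XXXXXFETLV", ct)
#' @export
match_peptides <- function(queries, cterms, max_mismatch = 0L,
                           require_hydrophobic_p0 = TRUE,
                           hydrophobic = HYDROPHOBIC_AA) {
  stopifnot(max_mismatch %in% 0:2)
  cterms <- as_tibble(cterms)
  if (!all(c("accession", "cterm") %in% names(cterms))) {
    abort("cterms needs columns 'accession' and 'cterm'")
  }
  if (any(nchar(queries) < 5)) {
    abort("every query peptide must have at least 5 residues")
  }
  empty_hits <- tibble(query = character(), accession = character(),
                       matched = character(), n_mismatches = integer(),
                       mismatch_positions = character())
  if (nrow(cterms) == 0 || length(queries) == 0) return(empty_hits)
  if (any(nchar(cterms$cterm) != 5)) {
    abort("all proteome C-termini must be exactly 5 residues")
  }

  labs <- peptide_position_labels(5)  # column i (1..5) -> "P-4".."P0"
  cmat <- do.call(rbind, strsplit(cterms$cterm, ""))

  hits <- map(queries, function(q) {
    q5 <- substr(q, nchar(q) - 4L, nchar(q))
    qc <- strsplit(q5, "")[[1]]
    # mismatch unless the query position is the wildcard 'X' or the two
    # residues agree on a real residue (proteome 'X' never matches)
    mm <- sweep(cmat, 2, qc, FUN = function(cc, qq) {
      !(qq == "X") & (cc != qq | cc == "X")
    })
    nmm <- rowSums(mm)
    keep <- nmm <= max_mismatch
    if (require_hydrophobic_p0) keep <- keep & cmat[, 5] %in% hydrophobic
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    tibble(
      query = q,
      accession = cterms$accession[idx],
      matched = cterms$cterm[idx],
      n_mismatches = as.integer(nmm[idx]),
      mismatch_positions = vapply(idx, function(i) {
        paste(labs[which(mm[i, ])], collapse = ",")
      }, character(1))
    )
  })
  bind_rows(empty_hits, hits)
}

#' Annotate matched interactions against a known PPI edge table
#'
#' Each (PDZ protein, matched partner) pair is labelled `"known"` if it
#' appears in the edge table (unordered lookup) and `"novel"` otherwise;
#' novel edges are candidate PDZ-mediated interactions absent from the
#' interaction database.
#'
#' @param hits Tibble from [match_peptides()] (needs an `accession` column).
#' @param pdz_protein Accession of the PDZ-containing protein.
#' @param known_edges Two-column table (or tibble) of accession pairs.
#' @return `hits` with added `pdz_protein` and `novelty` columns.
#' @export
flag_novel_edges <- function(hits, pdz_protein, known_edges) {
  hits <- as_tibble(hits)
  ke <- as.data.frame(known_edges)
  if (ncol(ke) < 2) abort("known_edges must have two accession columns")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  known <- key(as.character(ke[[1]]), as.character(ke[[2]]))
  hits %>%
    mutate(pdz_protein = pdz_protein,
           novelty = ifelse(key(pdz_protein, .data$accession) %in% known,
                            "known", "novel"))
}

#' Map single amino-acid polymorphisms onto domain ranges
#'
#' Keeps the SAPs falling inside a domain's 1-based inclusive residue range
#' on the matching protein accession.
#'
#' @param saps Tibble with `accession`, `position` (1-based), `from_aa`,
#'   `to_aa`, `disease_associated`.
#' @param domains Tibble with `pdz_id`, `accession`, `start`, `end`
#'   (1-based inclusive).
#' @return Tibble of mapped SAPs with their `pdz_id`, one row per
#'   (domain, SAP) pair.
#' @seealso [summarize_sap_mapping()]
#' @export
map_saps <- function(saps, domains) {
  saps <- as_tibble(saps)
  domains <- as_tibble(domains)
  stopifnot(all(c("accession", "position") %in% names(saps)),
            all(c("pdz_id", "accession", "start", "end") %in% names(domains)))
  if (any(domains$start > domains$end)) abort("domain start must be <= end")
  inner_join(domains, saps, by = "accession",
             relationship = "many-to-many") %>%
    filter(.data$position >= .data$start, .data$position <= .data$end) %>%
    select(-"start", -"end")
}

#' @rdname map_saps
#' @param mapped Result of [map_saps()].
#' @export
summarize_sap_mapping <- function(mapped) {
  mapped %>%
    group_by(.data$pdz_id) %>%
    summarise(n_saps = n(),
              n_disease = sum(.data$disease_associated),
              .groups = "drop")
}
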