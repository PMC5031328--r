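#' Load a residue-pair contact-energy matrix
#'
#' The binding score of a modeled PDZ-peptide complex is the sum, over all
#' receptor-peptide residue pairs in contact (any-atom distance < 4.5 A), of
#' a 20x20 statistical contact potential; more negative means stronger
#' predicted binding. The intended potential is the Betancourt-Thirumalai
#' (BT) matrix, a knowledge-based energy derived from contact frequencies in
#' solved structures with a Thr-like reference state.
#'
#' The file bundled with the package
#' (`bt_style_contact_potential_synthetic.tsv`) is a *synthetic*
#' reconstruction in the BT style: it reproduces the published potential's
#' units and range, its near-zero threonine row (the reference-state
#' signature) and its qualitative chemistry (hydrophobic and aromatic
#' attraction, like-charge repulsion, attractive salt bridges), but it is not
#' a verbatim transcription of the published table. To score with the
#' genuine published matrix, pass its path: any whitespace-delimited 20x20
#' table with one-letter row and column labels is accepted.
#'
#' @param path Path to a 20x20 labelled matrix file; `NULL` (default) loads
#'   the bundled BT-style matrix.
#' @param tol Symmetry tolerance (default 1e-9).
#' @return A `bt_matrix`: numeric 20x20 matrix, rows/columns named by the 20
#'   one-letter codes, validated symmetric and finite.
#' @export
load_bt_matrix <- function(path = NULL, tol = 1e-9) {
  if (is.null(path)) {
    path <- system.file("extdata", "bt_style_contact_potential_synthetic.tsv",
                        package = "pdzthread", mustWork = TRUE)
  }
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (!all(dim(m) == c(20, 20))) {
    abort("contact matrix must be 20x20 with residue labels")
  }
  if (!setequal(rownames(m), AA20) || !setequal(colnames(m), AA20)) {
    abort("contact matrix labels must be the 20 one-letter amino-acid codes")
  }
  m <- m[AA20, AA20]
  if (!all(is.finite(m))) abort("contact matrix entries must all be finite")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    abort(sprintf("contact matrix is asymmetric (max |e(a,b)-e(b,a)| = %g)",
                  asym))
  }
  structure(m, class = c("bt_matrix", "matrix", "array"))
}

# P0 register labels for a peptide of length L: last residue is P0,
# preceding ones P-1, P-2, ...
peptide_position_labels <- function(length) {
  offs <- rev(seq_len(length) - 1L)
  ifelse(offs == 0, "P0", paste0("P-", offs))
}

#' Thread a query peptide sequence through a template complex
#'
#' Positional threading: the template peptide's backbone and atom geometry
#' are retained unchanged and the residue identities are replaced by the
#' query sequence, registered at the C-terminus (query P0 sits on template
#' P0). The modeled length is `min(nchar(query), template peptide length)`:
#' longer queries are truncated to their C-terminal segment, shorter queries
#' occupy the template's C-terminal positions only.
#'
#' @param entry A `template_entry` (from [graft_peptide()] or
#'   [build_library()]) or a [complex_structure()] with a peptide.
#' @param query Query peptide sequence (one-letter codes; `"X"` allowed).
#' @return A [complex_structure()] whose peptide carries the query residue
#'   identities on the template geometry; the modeled query segment is kept
#'   in attribute `"query_modeled"`.
#' @export
thread_peptide <- function(entry, query) {
  cx <- if (inherits(entry, "template_entry")) entry$complex else entry
  stopifnot(inherits(cx, "complex_structure"))
  if (is.null(cx$peptide)) abort("template has no bound peptide to thread")
  if (!is.character(query) || length(query) != 1 || nchar(query) < 1) {
    abort("query peptide must be a non-empty string")
  }
  qchars <- strsplit(query, "")[[1]]
  if (!all(qchars %in% c(AA20, "X"))) {
    abort("query peptide contains non-amino-acid characters")
  }

  tlen <- n_residues(cx$peptide)
  L <- min(length(qchars), tlen)
  qseg <- tail(qchars, L)                      # C-terminal L residues
  keep_idx <- sort(unique(cx$peptide$atoms$res_index))
  keep_idx <- tail(keep_idx, L)                # template P0..P-(L-1)

  atoms <- cx$peptide$atoms
  atoms <- atoms[atoms$res_index %in% keep_idx, , drop = FALSE]
  atoms$aa <- qseg[match(atoms$res_index, keep_idx)]
  # renumber residue indices from 0 after truncation
  atoms$res_index <- as.integer(match(atoms$res_index, keep_idx) - 1L)
  peptide <- chain_structure(cx$peptide$chain_id, atoms)

  out <- complex_structure(cx$receptor, peptide, pdz_id = cx$pdz_id)
  attr(out, "query_modeled") <- paste(qseg, collapse = "")
  out
}

#' Receptor-peptide contact map
#'
#' All receptor-peptide residue pairs whose minimum any-atom distance is
#' strictly less than `cutoff`, with that distance. Peptide positions carry
#' the C-terminal register labels (`P0` = last residue).
#'
#' @param complex [complex_structure()] with a peptide.
#' @param cutoff Distance cutoff in Angstroms (default 4.5, strict `<`).
#' @return Tibble with `receptor_index`, `receptor_aa`, `peptide_index`,
#'   `peptide_label`, `peptide_aa`, `min_dist`.
#' @export
contact_map <- function(complex, cutoff = 4.5) {
  stopifnot(inherits(complex, "complex_structure"))
  if (is.null(complex$peptide)) abort("complex has no peptide")
  stopifnot(cutoff > 0)

  ra <- complex$receptor$atoms
  pa <- complex$peptide$atoms
  rc <- as.matrix(ra[, c("x", "y", "z")])
  pc <- as.matrix(pa[, c("x", "y", "z")])
  d2 <- outer(rowSums(rc^2), rowSums(pc^2), "+") - 2 * rc %*% t(pc)
  d2[d2 < 0] <- 0

  plen <- n_residues(complex$peptide)
  labs <- peptide_position_labels(plen)
  pairs <- tibble(
    receptor_index = rep(ra$res_index, times = nrow(pa)),
    peptide_index  = rep(pa$res_index, each = nrow(ra)),
    d2 = as.vector(d2)
  ) %>%
    group_by(.data$receptor_index, .data$peptide_index) %>%
    summarise(min_dist = sqrt(min(.data$d2)), .groups = "drop") %>%
    filter(.data$min_dist < cutoff)

  rres <- residue_table(complex$receptor)
  pres <- residue_table(complex$peptide)
  pairs %>%
    mutate(
      receptor_aa = rres$aa[match(.data$receptor_index, rres$res_index)],
      peptide_aa = pres$aa[match(.data$peptide_index, pres$res_index)],
      peptide_label = labs[.data$peptide_index + 1L]
    ) %>%
    select("receptor_index", "receptor_aa", "peptide_index",
           "peptide_label", "peptide_aa", "min_dist") %>%
    arrange(.data$receptor_index, .data$peptide_index)
}

#' Score a modeled PDZ-peptide complex
#'
#' Binding energy as the sum of contact-potential energies over all
#' receptor-peptide residue pairs within the cutoff (lower = stronger
#' predicted binding). Contacts involving an `"X"` residue on either side
#' are skipped and counted in `n_skipped`.
#'
#' @param complex [complex_structure()] with a peptide (typically from
#'   [thread_peptide()]).
#' @param bt A [load_bt_matrix()] matrix.
#' @param cutoff Contact cutoff in Angstroms (default 4.5).
#' @return One-row tibble: `pdz_id`, `peptide`, `score`, `n_contacts`,
#'   `n_skipped`, and list-column `pocket` (receptor residue indices in
#'   contact).
#' @export
score_complex <- function(complex, bt, cutoff = 4.5) {
  stopifnot(inherits(bt, "bt_matrix"))
  cm <- contact_map(complex, cutoff = cutoff)
  usable <- cm$receptor_aa %in% AA20 & cm$peptide_aa %in% AA20
  score <- if (any(usable)) {
    sum(unclass(bt)[cbind(cm$receptor_aa[usable], cm$peptide_aa[usable])])
  } else 0
  tibble(
    pdz_id = complex$pdz_id %||% NA_character_,
    peptide = if (is.null(complex$peptide)) NA_character_ else
      chain_sequence(complex$peptide),
    score = score,
    n_contacts = sum(usable),
    n_skipped = sum(!usable),
    pocket = list(sort(unique(cm$receptor_index)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank query peptides against one PDZ template
#'
#' Threads each peptide through the template, scores it, and returns the
#' panel sorted by ascending score (best predicted binder first; ties keep
#' input order). The binder call uses `score <= threshold`.
#'
#' @param entry `template_entry` or peptide-bound [complex_structure()].
#' @param peptides Character vector of query peptide sequences.
#' @param bt A [load_bt_matrix()] matrix.
#' @param cutoff Contact cutoff in Angstroms (default 4.5).
#' @param threshold Binder-call score cutoff (default -2.11).
#' @return Tibble sorted by `score`: `pdz_id`, `peptide`, `score`,
#'   `n_contacts`, `n_skipped`, `binder`, list-column `pocket`.
#' @export
rank_peptides <- function(entry, peptides, bt, cutoff = 4.5,
                          threshold = -2.11) {
  if (length(peptides) == 0) abort("peptide panel is empty")
  res <- bind_rows(map(peptides, function(p) {
    sc <- score_complex(thread_peptide(entry, p), bt, cutoff = cutoff)
    sc$peptide <- p
    sc
  }))
  res %>%
    mutate(binder = .data$score <= threshold) %>%
    arrange(.data$score)
}

#' Rank PDZ library entries against one peptide
#'
#' Scores the peptide threaded through every entry of a [build_library()]
#' library and returns entries sorted by ascending score. Entries that fail
#' to thread or score are skipped and reported in the `"failures"` attribute.
#'
#' @param library A `pdz_library`.
#' @param peptide A single query peptide sequence.
#' @inheritParams rank_peptides
#' @return Tibble as in [rank_peptides()], one row per scored entry.
#' @export
rank_pdzs <- function(library, peptide, bt, cutoff = 4.5, threshold = -2.11) {
  stopifnot(inherits(library, "pdz_library"))
  if (length(library$entries) == 0) abort("library has no entries")
  rows <- list()
  failures <- tibble(pdz_id = character(), reason = character())
  for (e in library$entries) {
    r <- tryCatch({
      sc <- score_complex(thread_peptide(e, peptide), bt, cutoff = cutoff)
      sc$pdz_id <- e$pdz_id
      sc$peptide <- peptide
      sc
    }, error = function(err) err)
    if (inherits(r, "error")) {
      failures <- bind_rows(failures, tibble(pdz_id = e$pdz_id,
                                             reason = conditionMessage(r)))
    } else {
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- bind_rows(rows) %>%
    mutate(binder = .data$score <= threshold) %>%
    arrange(.data$score)
  attr(out, "failures") <- failures
  out
}
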