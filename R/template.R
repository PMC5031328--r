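#' Select the most similar holo template for a query PDZ sequence
#'
#' Aligns the query sequence against the receptor sequence of every
#' peptide-bound (holo) entry and returns the entry with the highest
#' alignment identity. Ties are broken lexicographically by template id;
#' [build_library()] additionally breaks identity ties by superposition RMSD
#' when structures are in hand.
#'
#' @param query_seq One-letter amino-acid sequence of the apo PDZ domain.
#' @param holo_library Named list of [complex_structure()] objects with bound
#'   peptides; names are template ids.
#' @return List with `template_id` and the winning `alignment`
#'   (a `seq_alignment`, query vs template receptor).
#' @export
select_template <- function(query_seq, holo_library) {
  if (length(holo_library) == 0) abort("holo template library is empty")
  ids <- names(holo_library)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("holo_library must be a named list (names are template ids)")
  }
  alns <- map(holo_library, function(cx) {
    stopifnot(inherits(cx, "complex_structure"))
    align_sequences(query_seq, chain_sequence(cx$receptor))
  })
  ident <- map_dbl(alns, "identity")
  best <- ids[ident == max(ident)]
  winner <- sort(best)[1]
  list(template_id = winner, alignment = alns[[winner]],
       identity = ident[[winner]])
}

#' Graft a template peptide onto an apo PDZ structure
#'
#' The holo receptor is superposed onto the apo structure (holo mobile, apo
#' reference) over alignment-mapped C-alpha atoms, and the resulting rigid
#' transform is applied to the holo peptide, which is then attached to the
#' apo receptor as chain `"P"`. Because the motion is rigid, a noise-free apo
#' copy of the holo receptor recovers the holo peptide coordinates exactly.
#'
#' @param apo `chain_structure` of the peptide-free PDZ domain.
#' @param holo [complex_structure()] with a bound peptide.
#' @param pdz_id Identifier for the resulting entry (default: apo chain id).
#' @param template_id Identifier of the holo template (for provenance).
#' @param cutoff Contact cutoff in Angstroms for pocket detection
#'   (default 4.5, strict less-than).
#' @param source Provenance label stored on the entry.
#' @return A `template_entry`: list with the grafted `complex`
#'   (receptor = apo, peptide = transformed holo peptide), `pocket` (receptor
#'   `res_index` set), `peptide_length`, `identity_to_template`,
#'   `superpose_rmsd`, `template_id`, `source`.
#' @export
graft_peptide <- function(apo, holo, pdz_id = NULL, template_id = "template",
                          cutoff = 4.5, source = "grafted") {
  stopifnot(inherits(apo, "chain_structure"),
            inherits(holo, "complex_structure"))
  if (is.null(holo$peptide)) abort("holo complex has no peptide to graft")
  if (is.null(pdz_id)) pdz_id <- apo$chain_id

  aln <- align_sequences(chain_sequence(holo$receptor), chain_sequence(apo))
  sp <- superpose(holo$receptor, apo, mapping = aln)
  peptide <- apply_transform(holo$peptide, sp$transform)
  peptide$chain_id <- "P"
  cx <- complex_structure(apo, peptide, pdz_id = pdz_id)

  structure(
    list(pdz_id = pdz_id, source = source, complex = cx,
         peptide_length = n_residues(peptide),
         pocket = find_pocket(cx, cutoff = cutoff),
         template_id = template_id,
         identity_to_template = aln$identity,
         superpose_rmsd = sp$rmsd),
    class = "template_entry"
  )
}

#' @export
print.template_entry <- function(x, ...) {
  cat(sprintf(
    "<template_entry> %s (%s): peptide %s (%d aa), template %s, identity %.3f, rmsd %.3f A, pocket %d residues\n",
    x$pdz_id, x$source, chain_sequence(x$complex$peptide),
    x$peptide_length, x$template_id, x$identity_to_template,
    x$superpose_rmsd, length(x$pocket)))
  invisible(x)
}

#' Binding-pocket residues of a peptide-bound complex
#'
#' Receptor residues having at least one atom at a distance strictly less
#' than `cutoff` from at least one peptide atom. The 4.5-Angstrom any-atom
#' rule is the same one used to define scored contacts, so the pocket is
#' exactly the receptor side of the contact map.
#'
#' @param complex [complex_structure()] with a peptide.
#' @param cutoff Distance cutoff in Angstroms (default 4.5, strict `<`).
#' @return Sorted integer vector of receptor `res_index` values.
#' @export
find_pocket <- function(complex, cutoff = 4.5) {
  cm <- contact_map(complex, cutoff = cutoff)
  sort(unique(cm$receptor_index))
}

#' Build a library of peptide-bound PDZ templates
#'
#' Holo inputs pass through as `source = "holo-crystal"` entries (their own
#' template); each apo model is assigned its most similar holo template by
#' sequence identity (identity ties broken by lower superposition RMSD, then
#' lexicographic template id) and receives that template's peptide by rigid
#' grafting. Per-entry failures are recorded in `excluded`, not raised.
#'
#' @param apo_models Named list of `chain_structure` apo PDZ models (possibly
#'   empty).
#' @param holo_templates Named list of [complex_structure()] holo templates.
#' @param cutoff Pocket/contact cutoff in Angstroms (default 4.5).
#' @return A `pdz_library`: list with `entries` (named list of
#'   `template_entry`), `manifest` (tibble: pdz_id, source, template_id,
#'   identity, rmsd, peptide_length, n_pocket), `excluded` (tibble: pdz_id,
#'   reason) and `n_attempted`.
#' @export
build_library <- function(apo_models, holo_templates, cutoff = 4.5) {
  if (length(holo_templates) == 0) abort("holo template library is empty")
  entries <- list()
  excluded <- tibble(pdz_id = character(), reason = character())

  for (id in names(holo_templates)) {
    cx <- holo_templates[[id]]
    cx$pdz_id <- id
    entries[[id]] <- structure(
      list(pdz_id = id, source = "holo-crystal", complex = cx,
           peptide_length = n_residues(cx$peptide),
           pocket = find_pocket(cx, cutoff = cutoff),
           template_id = id, identity_to_template = 1,
           superpose_rmsd = 0),
      class = "template_entry")
  }

  for (id in names(apo_models)) {
    apo <- apo_models[[id]]
    res <- tryCatch({
      qseq <- chain_sequence(apo)
      ident <- map_dbl(holo_templates, function(h) {
        align_sequences(qseq, chain_sequence(h$receptor))$identity
      })
      tied <- sort(names(holo_templates)[ident == max(ident)])
      grafts <- map(tied, function(tid) {
        graft_peptide(apo, holo_templates[[tid]], pdz_id = id,
                      template_id = tid, cutoff = cutoff)
      })
      grafts[[which.min(map_dbl(grafts, "superpose_rmsd"))]]
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- bind_rows(excluded,
                            tibble(pdz_id = id, reason = conditionMessage(res)))
    } else {
      entries[[id]] <- res
    }
  }

  manifest <- bind_rows(map(entries, function(e) {
    tibble(pdz_id = e$pdz_id, source = e$source, template_id = e$template_id,
           identity = e$identity_to_template, rmsd = e$superpose_rmsd,
           peptide_length = e$peptide_length, n_pocket = length(e$pocket))
  }))
  structure(
    list(entries = entries, manifest = manifest, excluded = excluded,
         n_attempted = length(holo_templates) + length(apo_models)),
    class = "pdz_library"
  )
}

#' @export
print.pdz_library <- function(x, ...) {
  cat(sprintf("<pdz_library> %d entries (%s), %d excluded, %d attempted\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$source)),
                            table(x$manifest$source)), collapse = ", "),
              nrow(x$excluded), x$n_attempted))
  invisible(x)
}

#' @export
tidy.pdz_library <- function(x, ...) x$manifest

#' Library coverage of the attempted PDZ domains
#'
#' Fraction of attempted domains for which a peptide-bound model exists,
#' as a percentage. Given counts (e.g. 260 modeled of 264 mapped human
#' PDZ domains) it is plain arithmetic; given a `pdz_library` the counts are
#' taken from its manifest and exclusion list.
#'
#' @param x A `pdz_library`, or the number of modeled domains.
#' @param n_attempted Number of attempted domains (when `x` is a count).
#' @return Tibble with `n_modeled`, `n_attempted`, `coverage_pct`.
#' @examples
#' library_coverage(260, 264)  # ~98%
#' @export
library_coverage <- function(x, n_attempted = NULL) {
  if (inherits(x, "pdz_library")) {
    n_mod <- nrow(x$manifest)
    n_att <- x$n_attempted
  } else {
    stopifnot(is.numeric(x), is.numeric(n_attempted))
    n_mod <- x
    n_att <- n_attempted
  }
  tibble(n_modeled = n_mod, n_attempted = n_att,
         coverage_pct = 100 * n_mod / n_att)
}
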