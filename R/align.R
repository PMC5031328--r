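#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment with affine gaps, used both to pick the
#' most similar holo template for an apo PDZ domain and to map residues
#' between two chains before superposition. The alignment engine is
#' `Biostrings::pairwiseAlignment()`; defaults are the standard protein
#' settings (BLOSUM62, gap open 11, gap extend 1).
#'
#' Identity is defined over aligned columns only: matches divided by the
#' number of aligned (both non-gap) pairs, so it is symmetric in its
#' arguments.
#'
#' @param a,b Amino-acid sequences (one-letter codes; `"X"` allowed).
#' @param substitution Name of the substitution matrix (default "BLOSUM62").
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A `seq_alignment`: list with `pairs` (tibble of 0-based aligned
#'   index pairs `index_a`, `index_b` with residues and a `match` flag),
#'   `identity` in `[0, 1]`, and the alignment `score`.
#' @examples
#' al <- align_sequences("PDSGMW", "PDSGMW")
#' al$identity  # 1
#' @export
align_sequences <- function(a, b, substitution = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  check_seq <- function(s, what) {
    if (!is.character(s) || length(s) != 1 || nchar(s) < 1) {
      abort(paste0(what, " must be a single non-empty string"))
    }
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(chars), c(AA20, "X"))
    if (length(bad) > 0) {
      abort(paste0("non-amino-acid character(s) in ", what, ": ",
                   paste(bad, collapse = ", ")))
    }
  }
  check_seq(a, "a")
  check_seq(b, "b")

  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]

  ia <- cumsum(pa != "-") - 1L
  ib <- cumsum(pb != "-") - 1L
  both <- pa != "-" & pb != "-"
  pairs <- tibble(
    index_a = ia[both], index_b = ib[both],
    aa_a = pa[both], aa_b = pb[both],
    match = pa[both] == pb[both]
  )
  identity <- if (nrow(pairs) == 0) 0 else mean(pairs$match)
  structure(
    list(pairs = pairs, identity = identity,
         score = Biostrings::score(al)),
    class = "seq_alignment"
  )
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d aligned pairs, identity %.3f, score %.1f\n",
              nrow(x$pairs), x$identity, x$score))
  invisible(x)
}

#' @export
tidy.seq_alignment <- function(x, ...) x$pairs
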