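#' Rigid-body transforms
#'
#' A `rigid_transform` is a proper rotation (3x3, det +1) plus a translation
#' (Angstroms), applied as `x' = R x + t`. It is what optimal superposition
#' returns and what peptide grafting applies.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1 to 1e-6).
#' @param translation Length-3 numeric translation vector.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param t A `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 4))
  cat("  translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

# Kabsch least-squares fit of mobile points P (n x 3) onto reference Q.
# Returns the rigid transform minimising sum |R p + t - q|^2 and its RMSD.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.vector(cq - R %*% cp)
  moved <- sweep(P %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd,
       deviations = sqrt(rowSums((moved - Q)^2)))
}

#' Optimal superposition of two chains
#'
#' Least-squares (Kabsch) superposition of the mobile chain's C-alpha atoms
#' onto the reference, guided by a sequence alignment. After the initial fit,
#' aligned pairs deviating by more than `trim_factor` times the current RMSD
#' are discarded and the fit repeated, until no pair is dropped or only
#' `min_pairs` remain; this focuses the fit on the conserved core the way a
#' fold-level structural aligner would, while staying deterministic.
#'
#' @param mobile,reference `chain_structure` objects.
#' @param mapping Optional [align_sequences()] result mapping
#'   `mobile -> reference` residues; computed from the two sequences when
#'   omitted.
#' @param trim_factor Multiple of the current RMSD beyond which an aligned
#'   pair is discarded (default 2).
#' @param min_pairs Trimming floor: never trim below this many pairs
#'   (default 20; chains aligning on fewer pairs are fit without trimming).
#' @return A `superposition`: list with `transform` ([rigid_transform()]),
#'   `rmsd` (Angstroms, over retained pairs), `n_pairs` (retained),
#'   `n_initial` (aligned pairs with C-alpha on both sides), and `identity`
#'   of the guiding alignment.
#' @examples
#' toy <- make_toy_complex()
#' moved <- make_apo_copy(toy, rotation_deg = 90)
#' sp <- superpose(moved$chain, toy$receptor)
#' sp$rmsd  # ~0
#' @export
superpose <- function(mobile, reference, mapping = NULL,
                      trim_factor = 2, min_pairs = 20) {
  stopifnot(inherits(mobile, "chain_structure"),
            inherits(reference, "chain_structure"))
  if (is.null(mapping)) {
    mapping <- align_sequences(chain_sequence(mobile),
                               chain_sequence(reference))
  }
  stopifnot(inherits(mapping, "seq_alignment"))

  ca_m <- mobile$atoms[mobile$atoms$atom_name == "CA", , drop = FALSE]
  ca_r <- reference$atoms[reference$atoms$atom_name == "CA", , drop = FALSE]
  im <- match(mapping$pairs$index_a, ca_m$res_index)
  ir <- match(mapping$pairs$index_b, ca_r$res_index)
  ok <- !is.na(im) & !is.na(ir)
  if (sum(ok) < 3) {
    abort("degenerate input: fewer than 3 aligned residue pairs with C-alpha atoms")
  }
  P <- as.matrix(ca_m[im[ok], c("x", "y", "z")])
  Q <- as.matrix(ca_r[ir[ok], c("x", "y", "z")])

  spread <- svd(sweep(P, 2, colMeans(P)))$d
  if (spread[2] < 1e-8) {
    warn("collinear points: superposition is not uniquely determined")
  }

  keep <- seq_len(nrow(P))
  floor_n <- max(3, min(min_pairs, nrow(P)))
  fit <- kabsch(P, Q)
  repeat {
    if (fit$rmsd < 1e-8 || length(keep) <= floor_n) break
    drop <- which(fit$deviations > trim_factor * fit$rmsd)
    if (length(drop) == 0) break
    # never trim below the floor; drop the worst offenders first
    if (length(keep) - length(drop) < floor_n) {
      drop <- order(fit$deviations, decreasing = TRUE)[
        seq_len(length(keep) - floor_n)]
      if (length(drop) == 0) break
    }
    keep <- keep[-drop]
    fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
  }

  structure(
    list(transform = fit$transform, rmsd = fit$rmsd,
         n_pairs = length(keep), n_initial = nrow(P),
         identity = mapping$identity),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> rmsd %.3f A over %d/%d C-alpha pairs (identity %.3f)\n",
    x$rmsd, x$n_pairs, x$n_initial, x$identity))
  invisible(x)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
         n_initial = x$n_initial, identity = x$identity)
}

#' Apply a rigid transform to a chain
#'
#' Maps every atom to `R x + t`; all non-coordinate fields are unchanged, so
#' all intra-chain distances are preserved.
#'
#' @param chain A `chain_structure`.
#' @param t A [rigid_transform()].
#' @return The transformed `chain_structure`.
#' @export
apply_transform <- function(chain, t) {
  stopifnot(inherits(chain, "chain_structure"),
            inherits(t, "rigid_transform"))
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(t$rotation), 2, t$translation, "+")
  chain$atoms$x <- xyz[, 1]
  chain$atoms$y <- xyz[, 2]
  chain$atoms$z <- xyz[, 3]
  chain
}
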