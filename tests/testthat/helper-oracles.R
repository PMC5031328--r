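# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and its dependencies' fast paths) so that
# agreement is evidence, not tautology.

# Gotoh global alignment score with affine gaps: a gap of length L costs
# open + L * extend (matching the pairwiseAlignment convention).
nw_score_oracle <- function(a, b, submat, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

blosum62 <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

random_aa_seq <- function(n) {
  paste(sample(pdzthread:::AA20, n, replace = TRUE), collapse = "")
}

# Uniform-ish random proper rotation (QR of a Gaussian matrix, det fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_rigid <- function(scale = 20) {
  rigid_transform(random_rotation(), rnorm(3, sd = scale))
}

# O(N^2) all-atom brute-force contact scan over residue pairs.
contact_oracle <- function(complex, cutoff = 4.5) {
  ra <- complex$receptor$atoms
  pa <- complex$peptide$atoms
  out <- NULL
  for (ri in unique(ra$res_index)) {
    rx <- ra[ra$res_index == ri, c("x", "y", "z")]
    for (pi in unique(pa$res_index)) {
      px <- pa[pa$res_index == pi, c("x", "y", "z")]
      dmin <- Inf
      for (i in seq_len(nrow(rx))) {
        for (j in seq_len(nrow(px))) {
          d <- sqrt(sum((as.numeric(rx[i, ]) - as.numeric(px[j, ]))^2))
          if (d < dmin) dmin <- d
        }
      }
      if (dmin < cutoff) {
        out <- rbind(out, data.frame(receptor_index = ri, peptide_index = pi,
                                     min_dist = dmin))
      }
    }
  }
  out
}

# Mann-Whitney pair statistic: P(binder scores below non-binder), ties 1/2.
mw_auc_oracle <- function(records) {
  pos <- records$score[records$label == "binder"]
  neg <- records$score[records$label == "non-binder"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p < q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Hanley-McNeil standard error of an empirical AUC.
auc_se <- function(A, n1, n2) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n2 - 1) * (Q2 - A^2)) /
         (n1 * n2))
}

# Brute-force Hamming scan over C-termini (query X wildcard, proteome X
# never matches), with optional hydrophobic-P0 constraint.
hamming_scan_oracle <- function(queries, cterms, max_mismatch,
                                require_hydrophobic_p0 = TRUE,
                                hydrophobic = c("A", "C", "F", "I", "L",
                                                "M", "V", "W", "Y")) {
  out <- NULL
  for (q in queries) {
    q5 <- substr(q, nchar(q) - 4, nchar(q))
    qc <- strsplit(q5, "")[[1]]
    for (k in seq_len(nrow(cterms))) {
      cc <- strsplit(cterms$cterm[k], "")[[1]]
      mm <- 0
      for (i in 1:5) {
        if (qc[i] == "X") next
        if (cc[i] == "X" || cc[i] != qc[i]) mm <- mm + 1
      }
      if (mm > max_mismatch) next
      if (require_hydrophobic_p0 && !(cc[5] %in% hydrophobic)) next
      out <- rbind(out, data.frame(query = q,
                                   accession = cterms$accession[k],
                                   n_mismatches = mm))
    }
  }
  out
}

# Tiny hand-built complex: residues given as list(aa =, xyz = matrix) so
# boundary-distance fixtures can be placed exactly.
build_chain <- function(chain_id, residues) {
  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    xyz <- matrix(r$xyz, ncol = 3)
    data.frame(serial = i, atom_name = paste0("C", seq_len(nrow(xyz))),
               element = "C", resno = i, res_index = i - 1L, aa = r$aa,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  chain_structure(chain_id, atoms)
}
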