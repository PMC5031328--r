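#' Deterministic toy PDZ-groove complex
#'
#' Builds a pseudo-atom (C-alpha + C-beta) complex with fully controlled
#' geometry: the receptor is two antiparallel idealised strands (C-alpha
#' spacing 3.8 A along x) at y = +/- `groove_gap`, and the peptide lies as an
#' extended strand on the groove axis (y = 0), C-terminus at the high-x end.
#' The nearest receptor-peptide atom distance for an x-aligned residue pair
#' is exactly `groove_gap`, so the contact map is known in closed form:
#' residue pair (r, p) is a contact iff `sqrt(dx^2 + groove_gap^2) < cutoff`
#' where `dx` is their x offset. The expected contact set is attached as
#' attribute `"expected_contacts"`.
#'
#' @param n_receptor_residues Total receptor residues, split over the two
#'   strands (default 8).
#' @param peptide_seq Peptide sequence (default `"FETLV"`).
#' @param groove_gap Peptide-to-strand distance in Angstroms (default 4.0:
#'   inside the 4.5 A cutoff; 6.0 gives an empty contact map).
#' @param receptor_seq Optional receptor sequence (defaults to a fixed
#'   deterministic sequence).
#' @param cutoff Cutoff used for the closed-form expected contact set
#'   (default 4.5).
#' @param seed Kept for API uniformity; the toy is fully deterministic.
#' @return A [complex_structure()] (`pdz_id = "TOY"`) with attributes
#'   `"expected_contacts"` (tibble `receptor_index`, `peptide_index`) and
#'   `"spec"`.
#' @export
make_toy_complex <- function(n_receptor_residues = 8L, peptide_seq = "FETLV",
                             groove_gap = 4.0, receptor_seq = NULL,
                             cutoff = 4.5, seed = 1L) {
  stopifnot(groove_gap > 0, nchar(peptide_seq) >= 1,
            n_receptor_residues >= 2)
  plen <- nchar(peptide_seq)
  if (is.null(receptor_seq)) {
    pool <- strsplit("LIVFAYWMTSCGHKRDEQNP", "")[[1]]
    receptor_seq <- paste(rep_len(pool, n_receptor_residues), collapse = "")
  }
  stopifnot(nchar(receptor_seq) == n_receptor_residues)
  rchars <- strsplit(receptor_seq, "")[[1]]
  pchars <- strsplit(peptide_seq, "")[[1]]

  n1 <- ceiling(n_receptor_residues / 2)
  n2 <- n_receptor_residues - n1
  # strand 1 runs +x at y = +gap; strand 2 antiparallel at y = -gap
  rx <- c((seq_len(n1) - 1) * 3.8, rev((seq_len(n2) - 1) * 3.8))
  ry <- c(rep(groove_gap, n1), rep(-groove_gap, n2))

  residue_atoms <- function(i, aa, x, y) {
    tibble(serial = c(2L * i - 1L, 2L * i),
           atom_name = c("CA", "CB"), element = "C",
           resno = i, res_index = i - 1L, aa = aa,
           x = x, y = y, z = c(0, 1.5))
  }
  rec_atoms <- bind_rows(map(seq_len(n_receptor_residues), function(i) {
    residue_atoms(i, rchars[i], rx[i], ry[i])
  }))
  receptor <- chain_structure("A", rec_atoms)

  px <- (seq_len(plen) - 1) * 3.8
  pep_atoms <- bind_rows(map(seq_len(plen), function(i) {
    residue_atoms(i, pchars[i], px[i], 0)
  }))
  peptide <- chain_structure("B", pep_atoms)

  cx <- complex_structure(receptor, peptide, pdz_id = "TOY")
  # closed-form contact prediction from the strand geometry
  expected <- bind_rows(map(seq_len(n_receptor_residues), function(r) {
    dx <- abs(rx[r] - px)
    hit <- sqrt(dx^2 + groove_gap^2) < cutoff
    if (!any(hit)) return(NULL)
    tibble(receptor_index = r - 1L, peptide_index = which(hit) - 1L)
  }))
  attr(cx, "expected_contacts") <- expected
  attr(cx, "spec") <- list(n_receptor_residues = n_receptor_residues,
                           peptide_seq = peptide_seq,
                           groove_gap = groove_gap, cutoff = cutoff,
                           seed = seed)
  cx
}

#' Apo copy of a receptor under a known rigid motion
#'
#' Takes the receptor of a complex, applies a known rotation about the z
#' axis plus a translation, and optionally adds Gaussian coordinate noise.
#' The applied transform is returned so tests can compare recovered
#' transforms and grafted peptides against the truth.
#'
#' @param complex A [complex_structure()].
#' @param rotation_deg Rotation about z, degrees (default 0).
#' @param translation Length-3 translation (default `c(5, -3, 2)`).
#' @param noise_sd Gaussian noise SD per coordinate, Angstroms (default 0).
#' @param seed Seed for the noise draw.
#' @return List: `chain` (the moved apo `chain_structure`) and `transform`
#'   (the applied [rigid_transform()]).
#' @export
make_apo_copy <- function(complex, rotation_deg = 0,
                          translation = c(5, -3, 2), noise_sd = 0,
                          seed = 1L) {
  stopifnot(inherits(complex, "complex_structure"), noise_sd >= 0)
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0,
                sin(th),  cos(th), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  tr <- rigid_transform(R, translation)
  chain <- apply_transform(complex$receptor, tr)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      matrix(rnorm(3 * nrow(chain$atoms), sd = noise_sd),
             ncol = 3)
    })
    chain$atoms$x <- chain$atoms$x + noise[, 1]
    chain$atoms$y <- chain$atoms$y + noise[, 2]
    chain$atoms$z <- chain$atoms$z + noise[, 3]
  }
  list(chain = chain, transform = tr)
}

#' Synthetic labelled score set with known AUC
#'
#' Binder scores are drawn from Normal(`mu_binder`, `sigma^2`) and
#' non-binder scores from Normal(`mu_nonbinder`, `sigma^2`), so the expected
#' ROC-AUC is `pnorm((mu_nonbinder - mu_binder) / (sigma * sqrt(2)))` in
#' closed form. The defaults emulate the balanced benchmark design used for
#' the confusion statistics: 290 peptides per class, class means straddling
#' the -2.11 score cutoff symmetrically, separation tuned to an expected
#' ROC-AUC of 0.79.
#'
#' @param n_binder,n_nonbinder Class sizes (default 290 each).
#' @param mu_binder,mu_nonbinder Class means in score units (defaults -2.68
#'   and -1.54; midpoint -2.11).
#' @param sigma Common SD (default 1).
#' @param seed Integer seed.
#' @return Interaction-record tibble: `pdz_id`, `peptide`, `label`, `score`,
#'   `source`.
#' @export
make_score_set <- function(n_binder = 290L, n_nonbinder = 290L,
                           mu_binder = -2.68, mu_nonbinder = -1.54,
                           sigma = 1, seed = 1L) {
  stopifnot(sigma > 0, n_binder >= 1, n_nonbinder >= 1)
  withr::with_seed(seed, {
    tibble(
      pdz_id = "SYNTH",
      peptide = sprintf("PEP%05d", seq_len(n_binder + n_nonbinder)),
      label = rep(c("binder", "non-binder"), c(n_binder, n_nonbinder)),
      score = c(rnorm(n_binder, mu_binder, sigma),
                rnorm(n_nonbinder, mu_nonbinder, sigma)),
      source = "synthetic"
    )
  })
}

#' Toy proteome with planted C-termini
#'
#' Random protein sequences (lengths 50-500, uniform over the 20 amino
#' acids) with chosen 5-mers installed as the C-termini of the first
#' sequences. Random (non-planted) C-terminal 5-mers are rejection-sampled
#' to avoid any 5-mer listed in `avoid`, so absence of a match can be
#' guaranteed by construction. Deterministic given the seed.
#'
#' @param n Number of sequences.
#' @param planted_cterms Character vector of 5-mers to install (may be
#'   empty); `n >= length(planted_cterms)`.
#' @param seed Integer seed.
#' @param avoid 5-mers that random C-termini must not equal (default:
#'   the planted ones).
#' @param path Optional path; when given, the proteome is also written as
#'   FASTA.
#' @return Named character vector of sequences (accessions `TOY0001`, ...);
#'   written to `path` as FASTA when requested.
#' @export
make_toy_proteome <- function(n, planted_cterms = character(), seed = 1L,
                              avoid = planted_cterms, path = NULL) {
  stopifnot(n >= length(planted_cterms))
  if (length(planted_cterms) > 0 && any(nchar(planted_cterms) != 5)) {
    abort("planted C-termini must be 5-mers")
  }
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      len <- sample(50:500, 1)
      s <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      if (i <= length(planted_cterms)) {
        substr(s, len - 4L, len) <- planted_cterms[i]
      } else if (length(avoid) > 0) {
        while (substr(s, len - 4L, len) %in% avoid) {
          substr(s, len - 4L, len) <-
            paste(sample(AA20, 5, replace = TRUE), collapse = "")
        }
      }
      s
    }, character(1))
  })
  names(seqs) <- sprintf("TOY%04d", seq_len(n))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path,
                                width = 60)
  }
  seqs
}
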