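bt <- load_bt_matrix()

test_that("bundled contact matrix satisfies the potential's invariants", {
  m <- unclass(bt)
  expect_equal(dim(m), c(20, 20))
  expect_true(all(is.finite(m)))
  expect_equal(m, t(m), tolerance = 1e-12)
  # 210 distinct unordered-pair energies
  expect_equal(length(unique(m[upper.tri(m, diag = TRUE)])), 210)
  # Thr-like reference state: threonine interactions near zero
  expect_lt(max(abs(m["T", ])), 0.1)
  # hydrophobic/aromatic attraction, like-charge repulsion, salt bridges
  expect_lt(m["L", "L"], -0.8)
  expect_lt(m["F", "F"], -0.8)
  expect_lt(m["C", "C"], -1.0)
  expect_gt(m["K", "K"], 0)
  expect_gt(m["D", "D"], 0)
  expect_gt(m["D", "E"], 0)
  expect_lt(m["K", "E"], 0)
  expect_lt(m["K", "D"], 0)
  # hydrophobic pairs bind tighter than polar ones
  expect_lt(m["L", "F"], m["S", "N"])
})

test_that("asymmetric or mislabelled matrices are rejected", {
  m <- unclass(bt)
  m["A", "C"] <- m["A", "C"] + 1e-3
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(aa = rownames(m), as.data.frame(m)), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_bt_matrix(f), "asymmetric")

  m2 <- unclass(bt)[1:19, 1:19]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(aa = rownames(m2), as.data.frame(m2)), f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_bt_matrix(f2), "20x20")
})

test_that("identity threading reproduces the template complex", {
  toy <- make_toy_complex(peptide_seq = "FETLV")
  threaded <- thread_peptide(toy, "FETLV")
  expect_equal(threaded$peptide$atoms, toy$peptide$atoms)
  expect_identical(score_complex(threaded, bt), score_complex(toy, bt))
})

test_that("threading registers at the C-terminus and respects template length", {
  toy <- make_toy_complex(peptide_seq = "FETLV")
  # 10-mer query on a 5-mer template models the query's last five residues
  long <- thread_peptide(toy, "WWWWWGHKLA")
  expect_equal(chain_sequence(long$peptide), "GHKLA")
  expect_equal(long$peptide$atoms[, c("x", "y", "z")],
               toy$peptide$atoms[, c("x", "y", "z")])
  # 3-mer query occupies template P0..P-2 (the C-terminal three residues)
  short <- thread_peptide(toy, "KLA")
  expect_equal(chain_sequence(short$peptide), "KLA")
  tmpl_tail <- toy$peptide$atoms[toy$peptide$atoms$res_index >= 2,
                                 c("x", "y", "z")]
  expect_equal(as.matrix(short$peptide$atoms[, c("x", "y", "z")]),
               as.matrix(tmpl_tail), ignore_attr = TRUE)
  expect_error(thread_peptide(toy, ""), "non-empty")
})

test_that("contact map equals the brute-force all-pairs scan", {
  for (gap in c(3.5, 4.2, 5.5)) {
    toy <- make_toy_complex(n_receptor_residues = 8, groove_gap = gap)
    got <- contact_map(toy)
    oracle <- contact_oracle(toy)
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$receptor_index, oracle$receptor_index)
      expect_equal(got$peptide_index, oracle$peptide_index)
      expect_equal(got$min_dist, oracle$min_dist, tolerance = 1e-9)
    }
  }
})

test_that("contact boundary is strict and counts are monotone in cutoff", {
  rec <- build_chain("A", list(list(aa = "L", xyz = c(0, 4.49, 0)),
                               list(aa = "F", xyz = c(0, -4.5, 0))))
  pep <- build_chain("P", list(list(aa = "V", xyz = c(0, 0, 0))))
  cx <- complex_structure(rec, pep)
  cm <- contact_map(cx, cutoff = 4.5)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$receptor_index, 0L)

  far <- complex_structure(
    build_chain("A", list(list(aa = "L", xyz = c(0, 20, 0)))),
    build_chain("P", list(list(aa = "V", xyz = c(0, 0, 0)))))
  expect_equal(nrow(contact_map(far)), 0)

  toy <- make_toy_complex(groove_gap = 4)
  counts <- vapply(c(2, 4.5, 6, 10), function(ct)
    nrow(contact_map(toy, cutoff = ct)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

complexify_apart <- function() {
  complex_structure(
    build_chain("A", list(list(aa = "L", xyz = c(0, 50, 0)))),
    build_chain("P", list(list(aa = "V", xyz = c(0, 0, 0)))))
}

test_that("score is the sum of matrix lookups over the contact map", {
  toy <- make_toy_complex(n_receptor_residues = 8, peptide_seq = "FETLV",
                          groove_gap = 4)
  cm <- contact_map(toy)
  manual <- sum(vapply(seq_len(nrow(cm)), function(i)
    unclass(bt)[cm$receptor_aa[i], cm$peptide_aa[i]], numeric(1)))
  sc <- score_complex(toy, bt)
  expect_equal(sc$score, manual, tolerance = 1e-12)
  expect_equal(sc$n_contacts, nrow(cm))

  # empty contact map scores zero
  far <- complexify_apart()
  sc0 <- score_complex(far, bt)
  expect_equal(sc0$score, 0)
  expect_equal(sc0$n_contacts, 0)
})

test_that("contacts with unknown residues are skipped and counted", {
  rec <- build_chain("A", list(list(aa = "X", xyz = c(0, 3, 0)),
                               list(aa = "L", xyz = c(0, -3, 0))))
  pep <- build_chain("P", list(list(aa = "V", xyz = c(0, 0, 0))))
  sc <- score_complex(complex_structure(rec, pep), bt)
  expect_equal(sc$n_contacts, 1)
  expect_equal(sc$n_skipped, 1)
  expect_equal(sc$score, unclass(bt)["L", "V"])
})

test_that("score is additive over any partition of the contact map", {
  toy <- make_toy_complex(n_receptor_residues = 10, peptide_seq = "FETLV",
                          groove_gap = 4)
  cm <- contact_map(toy)
  total <- score_complex(toy, bt)$score
  part <- sum(unclass(bt)[cbind(cm$receptor_aa[1:3], cm$peptide_aa[1:3])]) +
    sum(unclass(bt)[cbind(cm$receptor_aa[-(1:3)], cm$peptide_aa[-(1:3)])])
  expect_equal(total, part, tolerance = 1e-12)
})

test_that("score is invariant under rigid motions of the whole complex", {
  toy <- make_toy_complex(groove_gap = 4.2)
  base <- score_complex(toy, bt)$score
  withr::with_seed(31, {
    for (i in 1:10) {
      tr <- random_rigid()
      moved <- complex_structure(apply_transform(toy$receptor, tr),
                                 apply_transform(toy$peptide, tr))
      expect_equal(score_complex(moved, bt)$score, base, tolerance = 1e-9)
    }
  })
})

test_that("rank_peptides sorts ascending, keeps ties stable and flags binders", {
  toy <- make_toy_complex(groove_gap = 4)
  panel <- c("KKKKK", "FETLV", "GGGGG")
  r <- rank_peptides(toy, panel, bt, threshold = -2.11)
  expect_equal(r$score, sort(r$score))
  expect_equal(r$binder, r$score <= -2.11)
  # permutation invariance of the sorted scores
  r2 <- rank_peptides(toy, rev(panel), bt)
  expect_equal(r2$score, r$score)
  expect_setequal(r2$peptide, r$peptide)
  # singleton panel
  expect_equal(nrow(rank_peptides(toy, "FETLV", bt)), 1)
  # stable tie order: identical peptides keep input order
  rt <- rank_peptides(toy, c("FETLV", "FETLV"), bt)
  expect_equal(rt$peptide, c("FETLV", "FETLV"))
})

test_that("rank_pdzs matches independent per-entry scoring and skips failures", {
  holo <- list(
    H1 = make_toy_complex(receptor_seq = "LIVFAYWMTSCGHKRDEQNP",
                          n_receptor_residues = 20),
    H2 = make_toy_complex(receptor_seq = "GGGGGSSSSSGGGGGSSSSS",
                          n_receptor_residues = 20, groove_gap = 5.2),
    H3 = make_toy_complex(receptor_seq = "KKKKKDDDDDKKKKKDDDDD",
                          n_receptor_residues = 20, groove_gap = 3.5))
  lib <- build_library(list(), holo)
  res <- rank_pdzs(lib, "FETLV", bt)
  expect_equal(nrow(res), 3)
  expect_equal(res$score, sort(res$score))
  for (i in seq_len(nrow(res))) {
    direct <- score_complex(thread_peptide(lib$entries[[res$pdz_id[i]]],
                                           "FETLV"), bt)
    expect_equal(res$score[i], direct$score)
  }
  # an unthreadable entry is skipped and logged, not fatal
  lib2 <- lib
  lib2$entries$H2$complex$peptide <- NULL
  res2 <- rank_pdzs(lib2, "FETLV", bt)
  expect_equal(nrow(res2), 2)
  expect_equal(attr(res2, "failures")$pdz_id, "H2")
})
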