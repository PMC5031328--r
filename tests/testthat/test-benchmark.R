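worked_set <- tibble::tibble(
  label = c("binder", "binder", "binder", "non-binder", "non-binder"),
  score = c(-5, -4, -2, -3, -1))

test_that("roc_points enumerates every score threshold plus the (0,0) endpoint", {
  pts <- roc_points(worked_set)
  # hand enumeration: thresholds -5,-4,-3,-2,-1 with <= calls
  expect_equal(pts$threshold, c(-Inf, -5, -4, -3, -2, -1))
  expect_equal(pts$tpr, c(0, 1/3, 2/3, 2/3, 1, 1))
  expect_equal(pts$fpr, c(0, 0, 0, 1/2, 1/2, 1))
  expect_equal(pts$recall, pts$tpr)
  expect_true(all(pts$precision >= 0 & pts$precision <= 1))
})

test_that("degenerate and separable score sets give the expected curves", {
  sep <- tibble::tibble(label = rep(c("binder", "non-binder"), each = 3),
                        score = c(-9, -8, -7, -2, -1, 0))
  pts <- roc_points(sep)
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
  expect_equal(auc(sep), 1)

  anti <- sep
  anti$label <- rev(anti$label)
  expect_equal(auc(anti), 0)

  flat <- tibble::tibble(label = c("binder", "non-binder"), score = c(1, 1))
  pts_flat <- roc_points(flat)
  expect_equal(nrow(pts_flat), 2)
  expect_equal(pts_flat$tpr, c(0, 1))
  expect_equal(pts_flat$fpr, c(0, 1))
  expect_equal(auc(flat), 0.5)

  expect_error(roc_points(tibble::tibble(label = "binder", score = 1)),
               "at least one")
})

test_that("trapezoid ROC AUC equals the Mann-Whitney pair statistic", {
  expect_equal(auc(worked_set), 5 / 6)
  expect_equal(auc(worked_set), mw_auc_oracle(worked_set))
  withr::with_seed(17, {
    for (rep in 1:60) {
      n1 <- sample(2:20, 1)
      n2 <- sample(2:20, 1)
      rec <- tibble::tibble(
        label = rep(c("binder", "non-binder"), c(n1, n2)),
        score = round(rnorm(n1 + n2), sample(0:2, 1)))  # rounding forces ties
      expect_equal(auc(rec), mw_auc_oracle(rec), tolerance = 1e-12)
    }
  })
})

test_that("ROC AUC agrees with an independent implementation (pROC)", {
  withr::with_seed(23, {
    rec <- make_score_set(n_binder = 60, n_nonbinder = 45, seed = 2)
    p <- pROC::roc(response = rec$label, predictor = rec$score,
                   levels = c("non-binder", "binder"),
                   direction = ">", quiet = TRUE)
    expect_equal(auc(rec), as.numeric(pROC::auc(p)), tolerance = 1e-9)
  })
})

test_that("AUC invariances: label flip and monotone score transforms", {
  withr::with_seed(3, {
    rec <- tibble::tibble(label = rep(c("binder", "non-binder"), c(12, 9)),
                          score = rnorm(21))  # continuous: no ties
    flipped <- rec
    flipped$label <- ifelse(rec$label == "binder", "non-binder", "binder")
    expect_equal(auc(rec) + auc(flipped), 1, tolerance = 1e-12)
    mono <- rec
    mono$score <- exp(rec$score) * 3 - 2
    expect_equal(auc(mono), auc(rec), tolerance = 1e-12)
  })
})

test_that("binder-partition resampling splits binders into balanced subsets", {
  rec <- tibble::tibble(label = rep(c("binder", "non-binder"), c(10, 5)),
                        score = c(seq(-10, -1), seq(-5.5, -1.5)))
  res <- balanced_resample_auc(rec, "binder-partition", seed = 4)
  expect_equal(res$n_subsets, 2)
  expect_equal(res$per_subset$n_binder, c(5, 5))
  expect_equal(res$per_subset$n_nonbinder, c(5, 5))
  expect_equal(res$roc_auc, mean(res$per_subset$roc_auc))

  # equal class sizes: one subset, equal to the plain AUC
  bal <- tibble::tibble(label = rep(c("binder", "non-binder"), each = 6),
                        score = rnorm(12))
  res_bal <- balanced_resample_auc(bal, "binder-partition", seed = 1)
  expect_equal(res_bal$n_subsets, 1)
  expect_equal(res_bal$roc_auc, auc(bal))
})

test_that("resampling is reproducible given the seed", {
  rec <- make_score_set(n_binder = 80, n_nonbinder = 30, seed = 5)
  a <- balanced_resample_auc(rec, "equal-sample", seed = 11, n_subsets = 20)
  b <- balanced_resample_auc(rec, "equal-sample", seed = 11, n_subsets = 20)
  expect_equal(a$per_subset, b$per_subset)
  c <- balanced_resample_auc(rec, "equal-sample", seed = 12, n_subsets = 20)
  expect_false(isTRUE(all.equal(a$per_subset$roc_auc,
                                c$per_subset$roc_auc)))
})

test_that("confusion statistics follow the defining formulas", {
  cs <- confusion_stats(tp = 199, fp = 87, tn = 203, fn = 91)
  expect_equal(cs$sensitivity, 100 * 199 / 290)
  expect_equal(cs$fpr, 100 * 87 / 290)
  expect_equal(cs$specificity, 100 - cs$fpr)
  expect_equal(cs$ppv, 100 * 199 / 286)
  expect_equal(cs$accuracy, 100 * 402 / 580)
  p <- cs$ppv / 100
  r <- cs$sensitivity / 100
  expect_equal(cs$f1, 2 * p * r / (p + r))

  # on balanced classes accuracy = (sensitivity + specificity) / 2 exactly
  withr::with_seed(8, {
    rec <- make_score_set(n_binder = 150, n_nonbinder = 150, seed = 3)
    ca <- confusion_at(rec, threshold = -2.11)
    expect_equal(ca$accuracy, (ca$sensitivity + ca$specificity) / 2,
                 tolerance = 1e-12)
    expect_equal(ca$tp + ca$fn, 150)
    expect_equal(ca$fp + ca$tn, 150)
  })
})

test_that("confusion_at calls positives with score <= threshold (inclusive)", {
  rec <- tibble::tibble(label = c("binder", "binder", "non-binder"),
                        score = c(-2.11, -2.10, -2.11))
  cs <- confusion_at(rec, threshold = -2.11)
  expect_equal(cs$tp, 1)
  expect_equal(cs$fn, 1)
  expect_equal(cs$fp, 1)
})

test_that("the >=5/>=5 domain filter keeps exactly the benchmark set", {
  t1 <- benchmark_table1()
  kept <- filter_benchmark_domains(t1)
  expect_length(kept, 43)
  withmore <- dplyr::bind_rows(
    t1, tibble::tibble(domain = "FAKE_1", roc_auc = 0.9, pr_auc = 0.9,
                       n_binder = 4, n_nonbinder = 100))
  expect_length(filter_benchmark_domains(withmore), 43)
  expect_false("FAKE_1" %in% filter_benchmark_domains(withmore))
  empty <- t1[0, ]
  expect_length(filter_benchmark_domains(empty), 0)
})

test_that("the packaged per-domain AUC table averages to 0.71 / 0.75", {
  s <- summarize_auc_table(benchmark_table1())
  expect_equal(s$mean_roc_auc, 0.71)
  expect_equal(s$mean_pr_auc, 0.75)
  expect_equal(s$n_domains, 43)
  one <- summarize_auc_table(tibble::tibble(roc_auc = 0.9, pr_auc = 0.8))
  expect_equal(one$mean_roc_auc, 0.9)
  expect_equal(one$mean_pr_auc, 0.8)
})

test_that("tidiers return the documented shapes", {
  rec <- make_score_set(n_binder = 40, n_nonbinder = 25, seed = 6)
  res <- balanced_resample_auc(rec, "equal-sample", seed = 2, n_subsets = 10)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 10)
  g <- glance(res)
  expect_equal(g$roc_auc, res$roc_auc)
  cs <- confusion_at(rec)
  expect_equal(nrow(tidy(cs)), 6)
  expect_equal(ncol(glance(cs)), 11)
})
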