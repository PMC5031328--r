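#' Benchmarking of binder/non-binder score sets
#'
#' Interaction records are plain tibbles with columns `pdz_id`, `peptide`,
#' `label` (`"binder"`/`"non-binder"`) and `score` (lower = stronger
#' predicted binding; a record is called positive at threshold `t` when
#' `score <= t`). [roc_points()] and [pr_points()] sweep every distinct score
#' as a threshold, [auc()] integrates by the trapezoid rule,
#' [balanced_resample_auc()] implements the two resampling strategies for
#' imbalanced data, and [confusion_at()] computes the confusion statistics at
#' a fixed cutoff.
#'
#' @name benchmark
NULL

check_records <- function(records, require_both = TRUE) {
  records <- as_tibble(records)
  needed <- c("label", "score")
  if (!all(needed %in% names(records))) {
    abort("records need columns 'label' and 'score'")
  }
  if (!all(records$label %in% c("binder", "non-binder"))) {
    abort("label must be 'binder' or 'non-binder'")
  }
  if (any(!is.finite(records$score))) abort("all records must be scored")
  if (require_both &&
      (!any(records$label == "binder") || !any(records$label == "non-binder"))) {
    abort("records must contain at least one binder and one non-binder")
  }
  records
}

#' ROC curve points over all score thresholds
#'
#' One point per distinct score value used as cutoff (predicted positive =
#' `score <= threshold`), plus the trivial `(0, 0)` endpoint; the highest
#' threshold is always `(1, 1)`.
#'
#' @param records Interaction-record tibble (see [benchmark]).
#' @return A `roc_curve` tibble: `threshold`, `tpr`, `fpr`, `precision`,
#'   `recall`, ordered by threshold, with binder/non-binder counts stored as
#'   attributes.
#' @export
roc_points <- function(records) {
  records <- check_records(records)
  pos <- records$score[records$label == "binder"]
  neg <- records$score[records$label == "non-binder"]
  thr <- sort(unique(records$score))
  pts <- tibble(
    threshold = c(-Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(pos <= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(neg <= t), numeric(1)))
  )
  tp <- pts$tpr * length(pos)
  fp <- pts$fpr * length(neg)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  # precision at the zero-prediction endpoint: carried back from the first
  # real point (standard PR-curve convention; no interpolation scheme is
  # uniquely defined there)
  if (is.na(prec[1]) && length(prec) > 1) prec[1] <- prec[2]
  pts$precision <- prec
  pts$recall <- pts$tpr
  attr(pts, "n_binder") <- length(pos)
  attr(pts, "n_nonbinder") <- length(neg)
  class(pts) <- c("roc_curve", class(pts))
  pts
}

#' Precision-recall curve points
#'
#' Same threshold sweep as [roc_points()], reported as (recall, precision).
#'
#' @inheritParams roc_points
#' @return A `pr_curve` tibble: `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(records) {
  pts <- roc_points(records)
  out <- pts[, c("threshold", "recall", "precision")]
  attr(out, "n_binder") <- attr(pts, "n_binder")
  attr(out, "n_nonbinder") <- attr(pts, "n_nonbinder")
  class(out) <- c("pr_curve", setdiff(class(out), "roc_curve"))
  out
}

trapezoid <- function(x, y) {
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Area under the ROC or PR curve
#'
#' Trapezoidal area. For the ROC curve this equals the Mann-Whitney pair
#' statistic (probability a binder scores below a non-binder, ties counting
#' one half): 1 is a perfect predictor, 0.5 a random one.
#'
#' @inheritParams roc_points
#' @param curve `"roc"` (default) or `"pr"`.
#' @return A single number in `[0, 1]`.
#' @examples
#' rec <- tibble::tibble(
#'   label = c("binder", "binder", "binder", "non-binder", "non-binder"),
#'   score = c(-5, -4, -2, -3, -1))
#' auc(rec)       # 5/6
#' @export
auc <- function(records, curve = c("roc", "pr")) {
  curve <- match.arg(curve)
  if (curve == "roc") {
    pts <- roc_points(records)
    trapezoid(pts$fpr, pts$tpr)
  } else {
    pts <- pr_points(records)
    trapezoid(pts$recall, pts$precision)
  }
}

#' Balanced-resampling AUC for imbalanced score sets
#'
#' Real negative data are typically far scarcer than binders, so a single
#' AUC on the full set can mislead. Two balancing strategies are provided:
#' \describe{
#'   \item{`"equal-sample"`}{draw `n_subsets` random balanced subsamples of
#'     `min(n_binder, n_nonbinder)` records per class and average the
#'     per-subset AUCs.}
#'   \item{`"binder-partition"`}{shuffle the majority binders once and split
#'     them into `ceiling(n_binder / n_nonbinder)` disjoint subsets of
#'     near-equal size, pair each subset with all non-binders, and average
#'     the per-subset AUCs.}
#' }
#' With equal class sizes both modes reduce to the plain [auc()].
#'
#' @inheritParams roc_points
#' @param mode `"equal-sample"` or `"binder-partition"`.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param n_subsets Number of balanced subsamples in equal-sample mode
#'   (default 100).
#' @return An `auc_result`: list with `roc_auc`, `pr_auc` (means over
#'   subsets), `n_binder`, `n_nonbinder`, `n_subsets` and `per_subset`
#'   (tibble of per-subset AUCs). Has [tidy()] and [glance()] methods.
#' @export
balanced_resample_auc <- function(records,
                                  mode = c("equal-sample", "binder-partition"),
                                  seed = 1L, n_subsets = 100L) {
  mode <- match.arg(mode)
  records <- check_records(records)
  bind <- records[records$label == "binder", , drop = FALSE]
  nonb <- records[records$label == "non-binder", , drop = FALSE]
  nb <- nrow(bind)
  nn <- nrow(nonb)

  subsets <- withr::with_seed(seed, {
    if (mode == "equal-sample") {
      m <- min(nb, nn)
      map(seq_len(n_subsets), function(i) {
        bind_rows(bind[sample.int(nb, m), ], nonb[sample.int(nn, m), ])
      })
    } else {
      k <- max(1L, ceiling(nb / nn))
      groups <- split(sample.int(nb), rep_len(seq_len(k), nb))
      map(groups, function(g) bind_rows(bind[g, ], nonb))
    }
  })

  per <- bind_rows(imap(subsets, function(s, i) {
    tibble(subset = as.integer(i),
           n_binder = sum(s$label == "binder"),
           n_nonbinder = sum(s$label == "non-binder"),
           roc_auc = auc(s, "roc"), pr_auc = auc(s, "pr"))
  }))
  structure(
    list(roc_auc = mean(per$roc_auc), pr_auc = mean(per$pr_auc),
         n_binder = nb, n_nonbinder = nn, n_subsets = nrow(per),
         per_subset = per, mode = mode, seed = seed),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf(
    "<auc_result> %s: ROC-AUC %.3f, PR-AUC %.3f (%d subset%s; %d binders, %d non-binders)\n",
    x$mode, x$roc_auc, x$pr_auc, x$n_subsets,
    if (x$n_subsets == 1) "" else "s", x$n_binder, x$n_nonbinder))
  invisible(x)
}

#' @export
tidy.auc_result <- function(x, ...) x$per_subset

#' @export
glance.auc_result <- function(x, ...) {
  tibble(roc_auc = x$roc_auc, pr_auc = x$pr_auc, n_binder = x$n_binder,
         n_nonbinder = x$n_nonbinder, n_subsets = x$n_subsets, mode = x$mode)
}

#' Confusion statistics at a score cutoff
#'
#' Predicted positive = `score <= threshold`. Derived statistics follow the
#' standard definitions: sensitivity (recall) `= TP/(TP+FN)`, FPR
#' `= FP/(FP+TN)`, specificity `= 1 - FPR`, PPV (precision) `= TP/(TP+FP)`,
#' accuracy `= (TP+TN)/total` (all reported as percentages) and F1
#' `= 2*precision*recall/(precision+recall)` (as a fraction).
#'
#' @inheritParams roc_points
#' @param threshold Score cutoff for the binder call (default -2.11).
#' @return A `confusion_stats` object (counts plus the derived statistics);
#'   [tidy()] returns the statistics as a long tibble, [glance()] as one row.
#' @export
confusion_at <- function(records, threshold = -2.11) {
  records <- check_records(records)
  pos <- records$label == "binder"
  called <- records$score <= threshold
  confusion_stats(tp = sum(pos & called), fp = sum(!pos & called),
                  tn = sum(!pos & !called), fn = sum(pos & !called),
                  threshold = threshold)
}

#' @rdname confusion_at
#' @param tp,fp,tn,fn Confusion counts.
#' @export
confusion_stats <- function(tp, fp, tn, fn, threshold = NA_real_) {
  sens <- 100 * tp / (tp + fn)
  fpr <- 100 * fp / (fp + tn)
  spec <- 100 - fpr
  ppv <- 100 * tp / (tp + fp)
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  p <- ppv / 100
  r <- sens / 100
  f1 <- if (is.finite(p) && is.finite(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold,
         sensitivity = sens, specificity = spec, fpr = fpr, ppv = ppv,
         accuracy = acc, f1 = f1),
    class = "confusion_stats"
  )
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion_stats> threshold %s\n",
              format(x$threshold)))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  sensitivity %.2f%%  specificity %.2f%%  FPR %.2f%%  PPV %.2f%%  accuracy %.2f%%  F1 %.2f\n",
    x$sensitivity, x$specificity, x$fpr, x$ppv, x$accuracy, x$f1))
  invisible(x)
}

#' @export
tidy.confusion_stats <- function(x, ...) {
  tibble(
    statistic = c("sensitivity_pct", "specificity_pct", "fpr_pct", "ppv_pct",
                  "accuracy_pct", "f1"),
    value = c(x$sensitivity, x$specificity, x$fpr, x$ppv, x$accuracy, x$f1)
  )
}

#' @export
glance.confusion_stats <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
         sensitivity = x$sensitivity, specificity = x$specificity,
         fpr = x$fpr, ppv = x$ppv, accuracy = x$accuracy, f1 = x$f1,
         threshold = x$threshold)
}

#' Select domains with enough data for benchmarking
#'
#' Keeps domains with at least `min_binder` binder and `min_nonbinder`
#' non-binder peptides; domains with fewer in either class give unstable
#' curves and are excluded from benchmark summaries.
#'
#' @param per_domain_counts Tibble with columns `domain` (or `pdz_id`),
#'   `n_binder`, `n_nonbinder`.
#' @param min_binder,min_nonbinder Minimum class counts (default 5 each).
#' @return Character vector of domain ids passing the filter.
#' @export
filter_benchmark_domains <- function(per_domain_counts, min_binder = 5,
                                     min_nonbinder = 5) {
  tbl <- as_tibble(per_domain_counts)
  idcol <- intersect(c("domain", "pdz_id"), names(tbl))[1]
  if (is.na(idcol)) abort("counts table needs a 'domain' or 'pdz_id' column")
  if (!all(c("n_binder", "n_nonbinder") %in% names(tbl))) {
    abort("counts table needs 'n_binder' and 'n_nonbinder' columns")
  }
  tbl[[idcol]][tbl$n_binder >= min_binder & tbl$n_nonbinder >= min_nonbinder]
}

#' Summarise a per-domain AUC table
#'
#' Arithmetic means of per-domain ROC and PR AUCs, rounded to 2 decimals.
#'
#' @param auc_table Tibble with columns `roc_auc` and `pr_auc`.
#' @return One-row tibble: `mean_roc_auc`, `mean_pr_auc`, `n_domains`.
#' @export
summarize_auc_table <- function(auc_table) {
  tbl <- as_tibble(auc_table)
  if (!all(c("roc_auc", "pr_auc") %in% names(tbl))) {
    abort("AUC table needs 'roc_auc' and 'pr_auc' columns")
  }
  tibble(mean_roc_auc = round(mean(tbl$roc_auc), 2),
         mean_pr_auc = round(mean(tbl$pr_auc), 2),
         n_domains = nrow(tbl))
}

#' Packaged benchmark reference tables
#'
#' `benchmark_table1()` returns the per-domain benchmark of 43 human PDZ
#' domains with real negative interaction data: ROC-AUC, PR-AUC and class
#' counts per domain. `benchmark_table2()` returns the confusion statistics
#' reported at the -2.11 score cutoff on a balanced binder/non-binder set.
#' Both ship as plain TSV transcriptions under `inst/extdata/`.
#'
#' @return Tibbles (see Description).
#' @export
benchmark_table1 <- function() {
  as_tibble(read.delim(system.file("extdata", "table1_benchmark_auc.tsv",
                                   package = "pdzthread", mustWork = TRUE)))
}

#' @rdname benchmark_table1
#' @export
benchmark_table2 <- function() {
  as_tibble(read.delim(system.file("extdata", "table2_confusion_stats.tsv",
                                   package = "pdzthread", mustWork = TRUE)))
}
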