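#' Confusion counts for a binary screening task
#'
#' @param truth,pred Equal-length vectors of 0/1 labels, 1 = severe /
#'   positive.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0,
            all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
  confusion_counts(tp = sum(truth == 1 & pred == 1),
                   fp = sum(truth == 0 & pred == 1),
                   tn = sum(truth == 0 & pred == 0),
                   fn = sum(truth == 1 & pred == 0))
}

#' @rdname confusion
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Screening metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(FP+TN), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), F1 = harmonic mean of PPV (precision) and sensitivity
#' (recall). A metric whose denominator is zero is returned as `NA` with a
#' warning naming it, rather than an error.
#'
#' @param counts A [confusion_counts()].
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `f1`.
#' @examples
#' binary_metrics(confusion_counts(tp = 8, fn = 0, fp = 4, tn = 99))
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate <- function(num, den, what) {
    if (den == 0) {
      warning("undefined metric (zero denominator): ", what, call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- rate(counts$tp, counts$tp + counts$fn, "sensitivity")
  spec <- rate(counts$tn, counts$fp + counts$tn, "specificity")
  ppv <- rate(counts$tp, counts$tp + counts$fp, "ppv")
  npv <- rate(counts$tn, counts$tn + counts$fn, "npv")
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) {
    warning("undefined metric (zero denominator): f1", call. = FALSE)
    NA_real_
  } else 2 * ppv * sens / (ppv + sens)
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over the unique score
#' thresholds, which equals the Mann-Whitney probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth 0/1 labels of the same length.
#' @return AUC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("undefined metric: AUC needs both classes", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # group tied scores so ties get trapezoid (half) credit
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from Beta quantiles; the lower bound is 0 when `x = 0`
#' and the upper bound 1 when `x = n`.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n, level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Seeded percentile bootstrap CI for an arbitrary metric
#'
#' Resamples cases with replacement and returns the percentile interval of
#' the metric over the resamples. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param metric Function of `(truth, x)` returning a scalar.
#' @param truth 0/1 labels.
#' @param x Predictions or scores aligned with `truth`.
#' @param reps Bootstrap replicates, default 2000.
#' @param seed Integer seed.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_metric_ci <- function(metric, truth, x, reps = 2000, seed = 1,
                                level = 0.95) {
  stopifnot(length(truth) == length(x), reps >= 1)
  n <- length(truth)
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      metric(truth[idx], x[idx])
    }, numeric(1))
  })
  alpha <- 1 - level
  q <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Metrics report for case-level verdicts
#'
#' Tabulates sensitivity, specificity, PPV, NPV, F1 and AUC with
#' Clopper-Pearson intervals for the four proportions, mirroring the usual
#' screening-performance table.
#'
#' @param truth 0/1 ground-truth severity labels.
#' @param pred 0/1 predicted labels.
#' @param scores Optional numeric severity scores for the AUC (e.g. the
#'   binary-head probabilities); AUC omitted when absent.
#' @param level Confidence level for the intervals.
#' @return A data frame with columns `metric`, `value`, `lower`, `upper`.
#' @export
metrics_report <- function(truth, pred, scores = NULL, level = 0.95) {
  cc <- confusion(truth, pred)
  m <- binary_metrics(cc)
  num <- c(sensitivity = cc$tp, specificity = cc$tn, ppv = cc$tp,
           npv = cc$tn)
  den <- c(sensitivity = cc$tp + cc$fn, specificity = cc$fp + cc$tn,
           ppv = cc$tp + cc$fp, npv = cc$tn + cc$fn)
  rows <- lapply(names(num), function(k) {
    ci <- if (den[[k]] > 0) clopper_pearson(num[[k]], den[[k]], level) else
      c(lower = NA_real_, upper = NA_real_)
    data.frame(metric = k, value = m[[k]], lower = ci[["lower"]],
               upper = ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(metric = "f1", value = m[["f1"]],
                               lower = NA_real_, upper = NA_real_))
  if (!is.null(scores)) {
    out <- rbind(out, data.frame(metric = "auc",
                                 value = roc_auc(scores, truth),
                                 lower = NA_real_, upper = NA_real_))
  }
  rownames(out) <- NULL
  out
}
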