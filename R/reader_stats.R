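#' Bang's blinding index for one trial arm
#'
#' Arm-wise index (correct - incorrect) / n where n counts correct,
#' incorrect and don't-know guesses; 0 indicates perfect blinding, -1 or 1
#' complete unblinding. The CI is a seeded percentile bootstrap over the
#' trinomial tally.
#'
#' @param correct,incorrect,dont_know Nonnegative guess counts of the arm.
#' @param boot_reps Bootstrap replicates for the CI; default 2000.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level, default 0.95.
#' @return List with `index`, `lower`, `upper`, `n`.
#' @examples
#' bang_blinding_index(30, 20, 50, seed = 1)
#' @export
bang_blinding_index <- function(correct, incorrect, dont_know,
                                boot_reps = 2000, seed = 1, level = 0.95) {
  stopifnot(correct >= 0, incorrect >= 0, dont_know >= 0)
  n <- correct + incorrect + dont_know
  if (n == 0) stop("empty tally", call. = FALSE)
  idx <- (correct - incorrect) / n
  p <- c(correct, incorrect, dont_know) / n
  vals <- with_seed(seed, {
    draws <- stats::rmultinom(boot_reps, n, p)
    (draws[1, ] - draws[2, ]) / n
  })
  alpha <- 1 - level
  q <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(index = idx, lower = q[1], upper = q[2], n = n)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement (po - pe) / (1 - pe) with the
#' marginal-product expected agreement.
#'
#' @param a,b Equal-length label vectors (any atomic type).
#' @return Kappa in \[-1, 1\]; `NA` with a warning when both raters are
#'   constant and identical (pe = 1).
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  lev <- union(unique(a), unique(b))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    warning("kappa undefined: expected agreement is 1 (constant raters)",
            call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard Fleiss (1971) estimator from an items-by-categories count
#' matrix; each row must sum to the constant number of raters.
#'
#' @param m Matrix of counts, rows = items, columns = categories.
#' @return Kappa; `NA` with a warning when chance agreement is 1.
#' @export
fleiss_kappa <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2, all(m >= 0))
  raters <- rowSums(m)
  if (length(unique(raters)) != 1) {
    stop("every item must be rated by the same number of raters",
         call. = FALSE)
  }
  r <- raters[1]
  if (r < 2) stop("need at least two raters", call. = FALSE)
  n <- nrow(m)
  p_i <- (rowSums(m^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / (n * r)
  pe <- sum(p_j^2)
  if (pe >= 1) {
    warning("kappa undefined: expected agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (p_bar - pe) / (1 - pe)
}

#' Difference of two proportions with Wald CI and Pearson chi-square
#'
#' Reports p1 - p2 with a Wald interval
#' `diff +/- z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)` (a Newcombe score
#' interval is available via `method`) and the two-sided Pearson chi-square
#' test (df = 1, no continuity correction) on the underlying 2x2 table.
#'
#' @param x1,n1 Successes and trials of arm 1.
#' @param x2,n2 Successes and trials of arm 2.
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` (default) or `"newcombe"` for the interval.
#' @return List with `diff`, `lower`, `upper`, `chi2`, `p`.
#' @examples
#' two_proportion_diff(42, 757, 158, 762)
#' @export
two_proportion_diff <- function(x1, n1, x2, n2, level = 0.95,
                                method = c("wald", "newcombe")) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  method <- match.arg(method)
  p1 <- x1 / n1; p2 <- x2 / n2
  diff <- p1 - p2
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    lower <- diff - z * se
    upper <- diff + z * se
  } else {
    wilson <- function(x, n) {
      ph <- x / n
      c((ph + z^2 / (2 * n) - z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))) /
          (1 + z^2 / n),
        (ph + z^2 / (2 * n) + z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))) /
          (1 + z^2 / n))
    }
    w1 <- wilson(x1, n1); w2 <- wilson(x2, n2)
    lower <- diff - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2)
    upper <- diff + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2)
  }
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
  }
  list(diff = diff, lower = lower, upper = upper, chi2 = chi2, p = p)
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE` exposing
#' the one-sided directional alternatives used for timing comparisons.
#'
#' @param a,b Numeric samples.
#' @param tail `"two.sided"`, `"less"` (mean of `a` smaller) or
#'   `"greater"`.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b, tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = tail)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are mid-ranked under
#' ties; `W` is the sum of ranks of the positive differences. The p-value
#' is exact (full enumeration of all sign patterns, valid with ties) for up
#' to 12 nonzero differences and a normal approximation with tie-corrected
#' variance (no continuity correction) beyond that.
#'
#' @param diffs Paired differences.
#' @param tail `"two.sided"`, `"greater"` (positive shift) or `"less"`.
#' @return List with `W`, `p`, `n` (nonzero differences), `exact`.
#' @export
wilcoxon_signed_rank <- function(diffs,
                                 tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    warning("undefined test: all differences are zero", call. = FALSE)
    return(list(W = NA_real_, p = NA_real_, n = 0L, exact = NA))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12) {
    # exact: enumerate all 2^n assignments of signs to the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_ge <- mean(w_all >= W)
    p_le <- mean(w_all <= W)
    p <- switch(tail, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(W = W, p = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sigma2)
  p <- switch(tail,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(W = W, p = min(1, p), n = n, exact = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values, capped at 1.
#' @export
benjamini_hochberg <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Reader-trial report
#'
#' Summarises a blinded randomized reader trial: per-arm Bang blinding
#' indices with bootstrap CIs and the two-proportion comparisons of the
#' outcome tallies.
#'
#' @param guesses Data frame with columns `arm`, `correct`, `incorrect`,
#'   `dont_know` (one row per arm).
#' @param outcomes Data frame with columns `outcome`, `x1`, `n1`, `x2`,
#'   `n2` (one comparison per row; arm 1 vs arm 2).
#' @param seed Seed for the blinding-index bootstrap.
#' @param level Confidence level.
#' @return List with data frames `blinding` and `comparisons`.
#' @export
trial_report <- function(guesses, outcomes, seed = 1, level = 0.95) {
  blinding <- do.call(rbind, lapply(seq_len(nrow(guesses)), function(i) {
    g <- guesses[i, ]
    bi <- bang_blinding_index(g$correct, g$incorrect, g$dont_know,
                              seed = seed + i, level = level)
    data.frame(arm = g$arm, index = bi$index, lower = bi$lower,
               upper = bi$upper, n = bi$n)
  }))
  comparisons <- do.call(rbind, lapply(seq_len(nrow(outcomes)), function(i) {
    o <- outcomes[i, ]
    d <- two_proportion_diff(o$x1, o$n1, o$x2, o$n2, level = level)
    data.frame(outcome = o$outcome, p1 = o$x1 / o$n1, p2 = o$x2 / o$n2,
               diff = d$diff, lower = d$lower, upper = d$upper,
               chi2 = d$chi2, p = d$p)
  }))
  list(blinding = blinding, comparisons = comparisons)
}
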