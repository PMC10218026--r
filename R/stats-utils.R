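#' One-sample t test with Cohen's d
#'
#' Standard one-sample t test of `values` against `null_mean`, reporting the
#' t statistic, exact t-distribution p value, and Cohen's d computed as
#' `(mean(values) - null_mean) / sd(values)`. Used in the pipeline to test
#' latency-window classification accuracies against the empirical chance
#' level estimated from the shuffled-label (null) decoding.
#'
#' @param values numeric vector, length >= 2.
#' @param null_mean hypothesized mean (default 0).
#' @param tails 1 or 2. One-tailed tests are in the direction of the observed
#'   mean difference? No: one-tailed means upper tail (`mean > null_mean`).
#' @return object of class `sd_ttest`: list with `t`, `df`, `p`, `cohens_d`,
#'   `mean_diff`, `tails`, `type`.
#' @export
one_sample_t <- function(values, null_mean = 0, tails = 2) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 2, tails %in% c(1, 2))
  if (stats::sd(values) == 0) {
    stop("one_sample_t: zero variance in `values`")
  }
  alt <- if (tails == 1) "greater" else "two.sided"
  tt <- stats::t.test(values, mu = null_mean, alternative = alt)
  structure(list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    cohens_d = (mean(values) - null_mean) / stats::sd(values),
    mean_diff = mean(values) - null_mean,
    tails = tails,
    type = "one_sample"
  ), class = "sd_ttest")
}

#' Paired t test with Cohen's d
#'
#' Paired t test of `a` versus `b`; Cohen's d is the mean of the pairwise
#' differences divided by their standard deviation.
#'
#' @param a,b paired numeric vectors of equal length (n >= 2).
#' @param tails 1 (upper tail of `a - b`) or 2.
#' @return `sd_ttest` object as in [one_sample_t()].
#' @export
paired_t <- function(a, b, tails = 2) {
  stopifnot(length(a) == length(b))
  d <- as.numeric(a) - as.numeric(b)
  if (length(d) < 2) stop("paired_t: need at least 2 pairs")
  if (stats::sd(d) == 0) stop("paired_t: zero variance in the differences")
  res <- one_sample_t(d, null_mean = 0, tails = tails)
  res$type <- "paired"
  res
}

#' @export
print.sd_ttest <- function(x, ...) {
  cat(sprintf("%s t test: t(%g) = %.3f, p = %.4g (%d-tailed), d = %.3f\n",
              x$type, x$df, x$t, x$p, x$tails, x$cohens_d))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p values, returning
#' the adjusted p values ("adj-p") and rejection flags at level `q`.
#'
#' @param p_values numeric vector of raw p values in \[0, 1\].
#' @param q FDR level used for the rejection flags (default 0.05).
#' @return list with `p_raw`, `p_adjusted`, `q`, `rejected` (logical).
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0) stop("bh_adjust: empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  list(p_raw = p, p_adjusted = adj, q = q, rejected = adj < q)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' Minimum sample size for a one-sample / paired t test
#'
#' Smallest n (>= 2) at which a t test with df = n - 1 and noncentrality
#' d * sqrt(n) reaches the requested power, computed exactly from the
#' noncentral t distribution. With a standardized effect size of d = 0.55,
#' alpha = 0.05 one-tailed and power 0.9 this gives n = 30, the sample-size
#' basis of the study design the package emulates.
#'
#' @param effect_d standardized effect size (Cohen's d), > 0.
#' @param alpha significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param tails 1 or 2.
#' @param n_max search cap (error if power is not reached by `n_max`).
#' @return integer sample size.
#' @export
min_sample_size <- function(effect_d, alpha = 0.05, power = 0.9, tails = 1,
                            n_max = 1e5) {
  stopifnot(effect_d > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  for (n in 2:n_max) {
    if (t_test_power(n, effect_d, alpha, tails) >= power) return(as.integer(n))
  }
  stop("min_sample_size: requested power not reached by n_max = ", n_max)
}

# Exact power of a one-sample t test at sample size n.
t_test_power <- function(n, effect_d, alpha, tails) {
  df <- n - 1
  ncp <- effect_d * sqrt(n)
  if (tails == 1) {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
  }
}
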