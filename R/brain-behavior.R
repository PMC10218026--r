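#' Mixed-model regression of behavioral effect on decoding accuracy
#'
#' Fits `effect ~ ca + (1 | subject)`. With a single observation per
#' subject — the usual situation, one effect index and one latency-window
#' accuracy per subject — the random-intercept variance is unidentifiable
#' and the model degrades gracefully to the ordinary least-squares solution;
#' the slope, t, p and (marginal) R-squared then equal the simple-regression
#' ones. With repeated observations per subject the model is fit with
#' `lmerTest::lmer` (Satterthwaite p values) and the marginal R-squared
#' (fixed-effect variance over total variance) is reported.
#'
#' @param effects per-observation behavioral effect (%).
#' @param cas per-observation classification accuracy.
#' @param subjects subject identifier per observation (default: one
#'   observation per subject).
#' @return an `sd_lme_stat` list: `slope`, `se`, `t`, `p`, `r_squared`,
#'   `n_subjects`, `method` ("ols" or "lmer").
#' @export
fit_effect_ca_lme <- function(effects, cas, subjects = seq_along(effects)) {
  stopifnot(length(effects) == length(cas), length(effects) == length(subjects))
  if (length(unique(subjects)) < 3) {
    stop("fit_effect_ca_lme: need at least 3 subjects")
  }
  if (stats::sd(cas) == 0) {
    stop("fit_effect_ca_lme: zero variance in classification accuracy")
  }
  one_per_subject <- max(table(subjects)) == 1
  if (one_per_subject) {
    fit <- stats::lm(effects ~ cas)
    sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
    co <- sm$coefficients
    structure(list(slope = co[2, 1], se = co[2, 2], t = co[2, 3],
                   p = co[2, 4], r_squared = sm$r.squared,
                   n_subjects = length(unique(subjects)), method = "ols"),
              class = "sd_lme_stat")
  } else {
    df <- data.frame(eff = effects, ca = cas, subj = factor(subjects))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(eff ~ ca + (1 | subj), data = df)))
    co <- stats::coef(summary(fit))
    vf <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    r2_marg <- vf / (vf + sum(vc$vcov))
    structure(list(slope = co["ca", "Estimate"], se = co["ca", "Std. Error"],
                   t = co["ca", "t value"], p = co["ca", "Pr(>|t|)"],
                   r_squared = r2_marg,
                   n_subjects = length(unique(subjects)), method = "lmer"),
              class = "sd_lme_stat")
  }
}

#' @export
print.sd_lme_stat <- function(x, ...) {
  cat(sprintf("effect ~ ca [%s, n = %d]: slope = %.3f, t = %.3f, p = %.4g, R2 = %.3f\n",
              x$method, x$n_subjects, x$slope, x$t, x$p, x$r_squared))
  invisible(x)
}

# Closed-form simple-regression t for one observation per subject; used by
# the permutation loop where refitting via lm() would dominate the runtime.
ols_t <- function(y, x) {
  n <- length(y)
  r <- suppressWarnings(stats::cor(y, x))
  if (!is.finite(r)) return(0)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Per-window regression of behavioral effect on accuracy
#'
#' Applies [fit_effect_ca_lme()] independently at each window of a
#' subjects-by-windows accuracy matrix. No multiplicity correction is
#' applied here; contiguity and the cluster permutation handle it.
#'
#' @param effects per-subject behavioral effect (%).
#' @param ca_windows subjects x windows matrix of accuracies.
#' @param window_starts optional window start times (ms) for labeling.
#' @return data frame with one row per window: `window_start`, `slope`,
#'   `se`, `t`, `p`, `r_squared`, `n_subjects`.
#' @export
lme_timecourse <- function(effects, ca_windows, window_starts = NULL) {
  ca_windows <- as.matrix(ca_windows)
  stopifnot(length(effects) == nrow(ca_windows))
  nw <- ncol(ca_windows)
  if (is.null(window_starts)) window_starts <- seq_len(nw)
  stopifnot(length(window_starts) == nw)
  rows <- lapply(seq_len(nw), function(w) {
    if (stats::sd(ca_windows[, w]) == 0) {
      # saturated or empty window: no regression is defined there
      return(data.frame(window_start = window_starts[w], slope = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        r_squared = NA_real_, n_subjects = nrow(ca_windows)))
    }
    st <- fit_effect_ca_lme(effects, ca_windows[, w])
    data.frame(window_start = window_starts[w], slope = st$slope, se = st$se,
               t = st$t, p = st$p, r_squared = st$r_squared,
               n_subjects = st$n_subjects)
  })
  do.call(rbind, rows)
}

#' Find clusters of consecutive significant windows
#'
#' Maximal runs of consecutive windows with `p < alpha` of length at least
#' `min_len` (default 2: an isolated significant window never forms a
#' cluster).
#'
#' @param p_values per-window p values, in grid order.
#' @param alpha significance threshold (default 0.05).
#' @param min_len minimum run length (default 2).
#' @param window_starts optional window start times (ms).
#' @param t_values optional per-window t statistics; if given, each
#'   cluster records `min_abs_t`, the permutation threshold.
#' @return list of `sd_cluster` objects with fields `windows` (indices),
#'   `window_starts`, `length`, `min_abs_t`, `alpha`, `min_len`.
#' @export
find_clusters <- function(p_values, alpha = 0.05, min_len = 2,
                          window_starts = NULL, t_values = NULL) {
  stopifnot(min_len >= 1, all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  if (is.null(window_starts)) window_starts <- seq_along(p_values)
  sig <- !is.na(p_values) & p_values < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] && runs$lengths[i] >= min_len) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1]] <- structure(list(
        windows = idx,
        window_starts = window_starts[idx],
        length = length(idx),
        min_abs_t = if (is.null(t_values)) NA_real_ else min(abs(t_values[idx])),
        alpha = alpha, min_len = min_len
      ), class = "sd_cluster")
    }
  }
  out
}

#' Cluster-based permutation test of a brain-behavior cluster
#'
#' Evaluates the robustness of a cluster of consecutive significant windows
#' against a shuffled-data null. Per permutation, the behavioral effects
#' are shuffled across subjects and the accuracy distribution is shuffled
#' independently across subjects within each cluster window; the regression
#' is refit at every cluster window and the permutation counts as a success
#' if it produces at least `cluster$length` contiguous windows whose |t|
#' reaches the actual cluster's minimum |t|. The p value uses the add-one
#' estimator `(successes + 1) / (n_perm + 1)`, so it is never exactly 0.
#'
#' @param cluster an `sd_cluster` from [find_clusters()] (with `min_abs_t`).
#' @param effects per-subject behavioral effect (%).
#' @param ca_windows subjects x windows accuracy matrix (full grid; the
#'   cluster's `windows` index into its columns).
#' @param n_perm number of permutations (>= 100; 10,000 for final
#'   inference).
#' @param seed integer seed.
#' @return the cluster with `perm_p` and `n_perm` fields added.
#' @export
cluster_permutation_test <- function(cluster, effects, ca_windows,
                                     n_perm = 10000, seed = 1) {
  stopifnot(inherits(cluster, "sd_cluster"))
  if (n_perm < 100) stop("cluster_permutation_test: n_perm must be >= 100")
  if (cluster$length < cluster$min_len) {
    stop("cluster_permutation_test: degenerate cluster")
  }
  if (!is.finite(cluster$min_abs_t)) {
    stop("cluster_permutation_test: cluster lacks min_abs_t; pass t_values ",
         "to find_clusters()")
  }
  ca_windows <- as.matrix(ca_windows)
  n <- length(effects)
  stopifnot(nrow(ca_windows) == n)
  ca_cl <- ca_windows[, cluster$windows, drop = FALSE]
  nw <- ncol(ca_cl)
  set.seed(seed)
  # standardized columns: correlation survives permutation of entries
  ze <- as.vector(scale(effects))
  zc <- scale(ca_cl)
  successes <- 0L
  for (p in seq_len(n_perm)) {
    e_p <- ze[sample.int(n)]
    tvals <- vapply(seq_len(nw), function(w) {
      x <- zc[sample.int(n), w]
      r <- sum(e_p * x) / (n - 1)
      r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
      r * sqrt(n - 2) / sqrt(1 - r^2)
    }, numeric(1))
    sig <- abs(tvals) >= cluster$min_abs_t
    if (any(sig)) {
      runs <- rle(sig)
      if (max(runs$lengths[runs$values]) >= cluster$length) {
        successes <- successes + 1L
      }
    }
  }
  cluster$perm_p <- (successes + 1) / (n_perm + 1)
  cluster$n_perm <- n_perm
  cluster
}

#' @export
print.sd_cluster <- function(x, ...) {
  cat(sprintf("Cluster: %d windows (%s ms), min |t| = %.3f%s\n",
              x$length,
              paste(range(x$window_starts), collapse = ".."),
              x$min_abs_t,
              if (!is.null(x$perm_p))
                sprintf(", perm p = %.4g (%d permutations)", x$perm_p, x$n_perm)
              else ""))
  invisible(x)
}
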