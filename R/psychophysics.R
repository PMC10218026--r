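#' Fit a lapse-corrected cumulative Gaussian psychometric function
#'
#' Maximum-likelihood fit of the proportion of "probe greater" responses as
#' a function of probe magnitude, under the model
#' `psi(x) = lapse/2 + (1 - lapse) * Phi((x - mu)/sigma)`. The lapse
#' (finger-error) rate is fixed (default 0.05, split equally between floor
#' and ceiling) rather than estimated. The PSE is `mu` (the median of the
#' cumulative Gaussian), the JND is the probe distance between the 50% and
#' 75% points of the lapse-corrected curve, and the Weber fraction is
#' JND/PSE.
#'
#' @param levels probe magnitudes (>= 3 distinct values).
#' @param k_chose_probe number of "probe greater" responses per level.
#' @param n_total number of trials per level.
#' @param lapse fixed lapse rate in \[0, 1).
#' @return an `sd_psyfit` list: `mu`, `sigma`, `lapse`, `pse`, `jnd`, `wf`,
#'   `loglik`, `converged`, `boundary`, `n_trials`.
#' @export
fit_psychometric <- function(levels, k_chose_probe, n_total, lapse = 0.05) {
  levels <- as.numeric(levels)
  k <- as.numeric(k_chose_probe)
  n <- as.numeric(n_total)
  stopifnot(length(levels) == length(k), length(levels) == length(n),
            lapse >= 0, lapse < 1)
  if (length(unique(levels)) < 3) {
    stop("fit_psychometric: need at least 3 distinct probe levels")
  }
  if (any(k > n) || any(k < 0)) stop("fit_psychometric: k must lie in [0, n]")

  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    psi <- lapse / 2 + (1 - lapse) * stats::pnorm((levels - mu) / sigma)
    psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
    -sum(k * log(psi) + (n - k) * log(1 - psi))
  }

  degenerate <- sum(k) == 0 || sum(k) == sum(n)
  rng <- diff(range(levels))
  # crude start: level closest to 50% responding, quarter-range slope
  prop <- ifelse(n > 0, k / n, 0.5)
  mu0 <- levels[which.min(abs(prop - 0.5))]
  start <- c(mu0, log(rng / 4))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  boundary <- mu < min(levels) || mu > max(levels)
  converged <- opt$convergence == 0 && !degenerate && is.finite(opt$value)

  fit <- structure(list(
    mu = mu, sigma = sigma, lapse = lapse, pse = mu,
    jnd = NA_real_, wf = NA_real_, loglik = -opt$value,
    converged = converged, boundary = boundary,
    n_trials = sum(n)
  ), class = "sd_psyfit")
  if (converged) {
    fit$jnd <- jnd_from_fit(fit)
    fit$wf <- fit$jnd / fit$pse
  }
  fit
}

#' @export
print.sd_psyfit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit (%d trials): PSE = %.3f, sigma = %.3f, JND = %.3f, WF = %.4f%s\n",
    x$n_trials, x$pse, x$sigma, x$jnd, x$wf,
    if (!x$converged) " [NOT CONVERGED]" else if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Just-noticeable difference from a psychometric fit
#'
#' Probe-magnitude distance between the 50% and 75% response points read off
#' the lapse-corrected curve: `sigma * z` with
#' `Phi(z) = (0.75 - lapse/2) / (1 - lapse)`.
#'
#' @param fit an `sd_psyfit` from [fit_psychometric()] (must have converged).
#' @return JND in probe units.
#' @export
jnd_from_fit <- function(fit) {
  stopifnot(inherits(fit, "sd_psyfit"))
  if (!fit$converged) stop("jnd_from_fit: fit did not converge")
  fit$sigma * stats::qnorm((0.75 - fit$lapse / 2) / (1 - fit$lapse))
}

#' Normalized serial-dependence effect index
#'
#' `((pse_high - pse_low) / pse_low) * 100`: the percent change in perceived
#' reference magnitude between high- and low-magnitude inducer trials.
#' Positive values indicate an attractive bias.
#'
#' @param pse_low PSE with a low-magnitude inducer (> 0).
#' @param pse_high PSE with a high-magnitude inducer.
#' @return effect index in percent.
#' @export
serial_dependence_index <- function(pse_low, pse_high) {
  if (any(pse_low <= 0)) {
    stop("serial_dependence_index: pse_low must be positive")
  }
  (pse_high - pse_low) / pse_low * 100
}

#' Trial-level logistic regression of responses on probe and inducers
#'
#' Binomial GLM (logit link) of the per-trial binary response, recoded so
#' that 1 = "reference greater", on the probe magnitude and the three
#' inducer magnitudes, all coded as ratios to the corresponding reference
#' magnitude (16 dots / 200 ms / 6 px). With this coding a positive inducer
#' coefficient means an attractive effect: a larger inducer increases the
#' probability of judging the reference as greater. Trials without a
#' response are excluded.
#'
#' @param table an Experiment-1-style `sd_trial_table` with responses.
#' @return an `sd_betas` list: data frame `coefficients` (term, beta, se,
#'   p), plus `converged` and `n_trials`.
#' @export
trial_regression <- function(table) {
  stopifnot(inherits(table, "sd_trial_table"))
  if (table$experiment[1] != 1L) stop("trial_regression: needs a discrimination-task table")
  tab <- table[!is.na(table$response), , drop = FALSE]
  if (nrow(tab) == 0) stop("trial_regression: no non-missing responses")
  ref <- .sd_reference[[tab$task[1]]]
  df <- data.frame(
    ref_greater = 1L - tab$response,
    probe = tab$probe_magnitude / ref,
    numerosity = tab$inducer_numerosity / .sd_reference[["numerosity"]],
    duration = tab$inducer_duration / .sd_reference[["duration"]],
    size = tab$inducer_dot_size / .sd_reference[["size"]]
  )
  fit <- withCallingHandlers(
    stats::glm(ref_greater ~ probe + numerosity + duration + size,
               family = stats::binomial(), data = df),
    warning = function(w) invokeRestart("muffleWarning")
  )
  sm <- summary(fit)$coefficients
  separated <- !fit$converged ||
    any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
  structure(list(
    coefficients = data.frame(
      term = rownames(sm), beta = sm[, 1], se = sm[, 2], p = sm[, 4],
      row.names = NULL),
    converged = !separated,
    n_trials = nrow(df)
  ), class = "sd_betas")
}

#' Psychometric fits and effect index split by inducer level
#'
#' Splits the trials of a discrimination-task table by the low vs high level
#' of the named inducer dimension (marginalizing over the other dimensions),
#' fits each split with [fit_psychometric()], and computes the normalized
#' effect index from the two PSEs.
#'
#' @param table an Experiment-1-style `sd_trial_table` with responses.
#' @param dimension "numerosity", "duration" or "size".
#' @param lapse fixed lapse rate passed to the fits.
#' @return list with `fit_low`, `fit_high` and `effect` (fields `eff`,
#'   `pse_low`, `pse_high`, `dimension`, `task`).
#' @export
effects_by_inducer <- function(table, dimension, lapse = 0.05) {
  stopifnot(inherits(table, "sd_trial_table"))
  if (!dimension %in% .sd_dimensions) {
    stop("effects_by_inducer: unknown dimension '", dimension, "'")
  }
  if (table$experiment[1] != 1L) stop("effects_by_inducer: needs a discrimination-task table")
  col <- c(numerosity = "inducer_numerosity", duration = "inducer_duration",
           size = "inducer_dot_size")[[dimension]]
  levels <- .sd_inducer_levels_exp1[[dimension]]
  tab <- table[!is.na(table$response), , drop = FALSE]
  fit_split <- function(level) {
    sub <- tab[tab[[col]] == level, , drop = FALSE]
    agg <- stats::aggregate(response ~ probe_magnitude, data = sub,
                            FUN = function(r) c(k = sum(r), n = length(r)))
    if (nrow(agg) < 3) {
      stop("effects_by_inducer: fewer than 3 probe levels in the ",
           if (level == min(levels)) "low" else "high", " split")
    }
    fit_psychometric(agg$probe_magnitude, agg$response[, "k"],
                     agg$response[, "n"], lapse = lapse)
  }
  fit_low <- fit_split(min(levels))
  fit_high <- fit_split(max(levels))
  list(
    fit_low = fit_low, fit_high = fit_high,
    effect = list(
      eff = serial_dependence_index(fit_low$pse, fit_high$pse),
      pse_low = fit_low$pse, pse_high = fit_high$pse,
      dimension = dimension, task = table$task[1]
    )
  )
}
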