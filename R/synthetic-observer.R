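#' Parameters of a biased Bernoulli observer
#'
#' Describes a two-alternative forced-choice observer whose point of
#' subjective equality (PSE) is shifted by the magnitude of the preceding
#' (inducer) stimulus. On each trial the PSE is
#' `pse_base + sum over dimensions of (sign/2) * bias`, where sign is +1 when
#' the inducer level on that dimension is high and -1 when it is low, so a
#' positive bias is attractive: a high inducer makes the reference appear
#' larger, pushing the PSE up by `bias/2` (and down by the same amount for a
#' low inducer), for a total high-minus-low PSE separation of `bias`.
#'
#' @param pse_base baseline PSE in probe units (defaults to the task
#'   reference when used through [simulate_cohort()]).
#' @param sigma psychometric slope parameter (probe units, > 0).
#' @param lapse stimulus-independent error probability in \[0, 1\].
#' @param bias_numerosity,bias_duration,bias_size signed PSE separation
#'   (probe units) attributable to each inducer dimension.
#' @return an `sd_observer` parameter list.
#' @export
observer_params <- function(pse_base = 16, sigma = 2, lapse = 0.05,
                            bias_numerosity = 0, bias_duration = 0,
                            bias_size = 0) {
  stopifnot(sigma > 0, lapse >= 0, lapse <= 1,
            is.finite(bias_numerosity), is.finite(bias_duration),
            is.finite(bias_size))
  structure(list(
    pse_base = pse_base, sigma = sigma, lapse = lapse,
    bias = c(numerosity = bias_numerosity, duration = bias_duration,
             size = bias_size)
  ), class = "sd_observer")
}

#' Simulate observer responses on a discrimination design
#'
#' Draws each binary response from a lapse-corrected cumulative Gaussian
#' observer: `P(probe greater) = lapse/2 + (1 - lapse) *
#' Phi((probe - pse_trial) / sigma)`, with the trial PSE shifted by half the
#' per-dimension bias according to the inducer level (high: +bias/2,
#' low: -bias/2). Response 1 codes "probe greater (more numerous / longer /
#' bigger)".
#'
#' @param table an Experiment-1-style `sd_trial_table` (must have probes).
#' @param obs [observer_params()].
#' @param seed integer seed for the Bernoulli draws.
#' @return the table with the `response` column filled in.
#' @export
simulate_responses <- function(table, obs, seed = 1) {
  stopifnot(inherits(table, "sd_trial_table"), inherits(obs, "sd_observer"))
  if (table$experiment[1] != 1L) {
    stop("simulate_responses: passive designs have no probe to respond to")
  }
  pse <- trial_pse(table, obs)
  p <- obs$lapse / 2 +
    (1 - obs$lapse) * stats::pnorm((table$probe_magnitude - pse) / obs$sigma)
  set.seed(seed)
  table$response <- as.integer(stats::runif(nrow(table)) < p)
  table
}

trial_pse <- function(table, obs) {
  sgn <- function(x, levels) ifelse(x == max(levels), 1, -1)
  obs$pse_base +
    sgn(table$inducer_numerosity, .sd_inducer_levels_exp1$numerosity) *
      obs$bias[["numerosity"]] / 2 +
    sgn(table$inducer_duration, .sd_inducer_levels_exp1$duration) *
      obs$bias[["duration"]] / 2 +
    sgn(table$inducer_dot_size, .sd_inducer_levels_exp1$size) *
      obs$bias[["size"]] / 2
}

# PSE separation (probe units) that produces a given normalized
# serial-dependence effect (percent) around pse_base with symmetric shifts:
# eff = 100 * bias / (pse_base - bias/2).
bias_from_effect <- function(eff_percent, pse_base) {
  pse_base * eff_percent / 100 / (1 + eff_percent / 200)
}
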