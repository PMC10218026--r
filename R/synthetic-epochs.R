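#' Parameters of the multichannel evoked-epoch simulator
#'
#' Describes synthetic stimulus-locked epochs: a class-independent evoked
#' template shared by all trials, a latency-localized, spatially patterned
#' component whose sign follows the binarized past-magnitude label of each
#' dimension, and temporally autocorrelated, spatially mixed noise.
#'
#' @param n_channels number of channels (default 32).
#' @param sampling_rate Hz (default 250).
#' @param epoch_start,epoch_end epoch span in ms relative to stimulus onset
#'   (defaults -200 and 700; must straddle 0).
#' @param evoked_template function of time (ms) returning the
#'   class-independent evoked amplitude; the default is a damped sequence of
#'   Gaussian deflections starting after stimulus onset.
#' @param signal_windows list of windows, each a list with `start`, `end`
#'   (ms) and `amplitude`, a named vector giving the within-window signal
#'   amplitude for the dimensions `numerosity`, `duration`, `size` (missing
#'   names mean 0). Default: one 50-250 ms window of unit amplitude on all
#'   three dimensions.
#' @param signal_topography `n_channels x 3` matrix of unit-norm channel
#'   weight vectors (columns named by dimension); by default a random
#'   orthonormal triple drawn from `seed`.
#' @param noise_sd marginal noise standard deviation per channel.
#' @param noise_ar1 lag-1 temporal autocorrelation of the noise in \[0, 1).
#' @param seed integer seed controlling the topography, spatial mixing and
#'   noise draws.
#' @return an `sd_eeg_params` parameter list.
#' @export
eeg_sim_params <- function(n_channels = 32, sampling_rate = 250,
                           epoch_start = -200, epoch_end = 700,
                           evoked_template = NULL, signal_windows = NULL,
                           signal_topography = NULL, noise_sd = 1,
                           noise_ar1 = 0.9, seed = 1) {
  stopifnot(n_channels >= 2, sampling_rate > 0,
            epoch_start < 0, epoch_end > 0,
            noise_sd >= 0, noise_ar1 >= 0, noise_ar1 < 1)
  if (is.null(evoked_template)) {
    evoked_template <- function(t) {
      ifelse(t > 0,
             4 * exp(-((t - 110) / 50)^2) - 3 * exp(-((t - 210) / 70)^2) +
               1.5 * exp(-((t - 420) / 150)^2),
             0)
    }
  }
  if (is.null(signal_windows)) {
    signal_windows <- list(list(start = 50, end = 250,
                                amplitude = c(numerosity = 1, duration = 1,
                                              size = 1)))
  }
  for (w in signal_windows) {
    stopifnot(is.numeric(w$start), is.numeric(w$end), w$start < w$end)
    if (any(w$amplitude < 0)) stop("eeg_sim_params: signal amplitudes must be >= 0")
    if (w$start < epoch_start || w$end > epoch_end) {
      stop("eeg_sim_params: signal window ", w$start, "-", w$end,
           " ms lies outside the epoch span")
    }
  }
  if (is.null(signal_topography)) {
    set.seed(seed)
    signal_topography <- matrix(stats::rnorm(n_channels * 3), n_channels, 3)
    if (n_channels >= 3) {
      signal_topography <- qr.Q(qr(signal_topography))
    } else {
      signal_topography <- sweep(signal_topography, 2,
                                 sqrt(colSums(signal_topography^2)), "/")
    }
    colnames(signal_topography) <- .sd_dimensions
  }
  stopifnot(nrow(signal_topography) == n_channels,
            ncol(signal_topography) == 3)
  nrm <- sqrt(colSums(signal_topography^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("eeg_sim_params: topography columns must have unit norm")
  }
  structure(list(
    n_channels = n_channels, sampling_rate = sampling_rate,
    epoch_start = epoch_start, epoch_end = epoch_end,
    evoked_template = evoked_template, signal_windows = signal_windows,
    signal_topography = signal_topography, noise_sd = noise_sd,
    noise_ar1 = noise_ar1, seed = as.integer(seed)
  ), class = "sd_eeg_params")
}

new_epoch_set <- function(data, time_ms, sampling_rate, channel_labels,
                          trial_meta) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(time_ms),
            dim(data)[1] == nrow(trial_meta))
  structure(list(data = data, time_ms = time_ms,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 trial_meta = trial_meta),
            class = "sd_epochs")
}

#' @export
print.sd_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples (%g..%g ms @ %g Hz)\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms),
              x$sampling_rate))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial
#' @param epochs an `sd_epochs` object.
#' @param idx trial indices to keep.
#' @return the subsetted `sd_epochs` object.
#' @export
subset_epochs <- function(epochs, idx) {
  new_epoch_set(epochs$data[idx, , , drop = FALSE], epochs$time_ms,
                epochs$sampling_rate, epochs$channel_labels,
                epochs$trial_meta[idx, , drop = FALSE])
}

#' Simulate stimulus-locked multichannel epochs
#'
#' Each epoch is the sum of (i) the class-independent evoked template
#' (weighted per channel by fixed gains), (ii) for each magnitude dimension
#' a component `sign(past level) * subject_amplitude * window amplitude *
#' topography`, nonzero only inside the configured signal windows, where the
#' sign is +1 for a high past level, -1 for a low one and 0 for an
#' intermediate or undefined one, and (iii) AR(1) noise mixed across
#' channels by a random matrix. The time axis spans exactly
#' `epoch_start..epoch_end` at the configured sampling rate. The draw is
#' fully determined by `eeg$seed`.
#'
#' @param table an `sd_trial_table` carrying past-magnitude labels (either
#'   experiment).
#' @param eeg [eeg_sim_params()].
#' @param subject_amplitude scalar scaling of the past-magnitude signal for
#'   this subject (0 gives pure-noise epochs).
#' @return an `sd_epochs` object; `trial_meta` holds the past labels.
#' @export
simulate_epochs <- function(table, eeg, subject_amplitude = 1) {
  stopifnot(inherits(table, "sd_trial_table"), inherits(eeg, "sd_eeg_params"))
  labs <- past_labels(table)
  time_ms <- seq(eeg$epoch_start, eeg$epoch_end, by = 1000 / eeg$sampling_rate)
  n_time <- length(time_ms)
  n_tr <- nrow(table)
  n_ch <- eeg$n_channels

  set.seed(eeg$seed)
  gains <- stats::runif(n_ch, 0.5, 1.5)
  mixing <- matrix(stats::rnorm(n_ch * n_ch), n_ch, n_ch)
  mixing <- mixing / sqrt(rowSums(mixing^2))  # unit rows: marginal sd preserved

  template <- eeg$evoked_template(time_ms)
  base <- outer(gains, template)  # channels x time

  # signed class labels per dimension: +1 high, -1 low, 0 intermediate/NA
  lvl <- list(numerosity = .sd_levels_exp2$numerosity,
              duration = .sd_levels_exp2$duration,
              size = .sd_levels_exp2$size)
  past_cols <- c(numerosity = "past_numerosity", duration = "past_duration",
                 size = "past_dot_size")
  sgn <- sapply(.sd_dimensions, function(d) {
    x <- labs[[past_cols[[d]]]]
    s <- ifelse(is.na(x), 0, ifelse(x == max(lvl[[d]]), 1,
                                    ifelse(x == min(lvl[[d]]), -1, 0)))
    as.numeric(s)
  })  # trials x 3

  # signal time profile per dimension: amplitude inside each window
  profile <- matrix(0, 3, n_time, dimnames = list(.sd_dimensions, NULL))
  for (w in eeg$signal_windows) {
    in_w <- time_ms >= w$start & time_ms < w$end
    for (d in .sd_dimensions) {
      a <- if (d %in% names(w$amplitude)) w$amplitude[[d]] else 0
      profile[d, in_w] <- profile[d, in_w] + a
    }
  }

  data <- array(0, dim = c(n_tr, n_ch, n_time))
  innov_sd <- eeg$noise_sd * sqrt(1 - eeg$noise_ar1^2)
  for (tr in seq_len(n_tr)) {
    innov <- matrix(stats::rnorm(n_ch * n_time, sd = innov_sd), n_time, n_ch)
    ar <- stats::filter(innov, eeg$noise_ar1, method = "recursive")
    noise <- mixing %*% t(ar)  # channels x time
    sig <- matrix(0, n_ch, n_time)
    for (j in seq_along(.sd_dimensions)) {
      if (sgn[tr, j] != 0) {
        sig <- sig + (sgn[tr, j] * subject_amplitude) *
          outer(eeg$signal_topography[, j], profile[j, ])
      }
    }
    data[tr, , ] <- base + sig + noise
  }
  meta <- cbind(labs, table[, c("subject", "block", "trial", "task"),
                            drop = FALSE])
  new_epoch_set(data, time_ms, eeg$sampling_rate,
                paste0("ch", seq_len(n_ch)), meta)
}

#' Coupling between subject signal amplitude and behavioral effect
#'
#' Generative counterpart of the brain-behavior link: a subject's behavioral
#' serial-dependence effect (percent) is `intercept + slope * amplitude +
#' noise`, where `amplitude` is the subject's past-magnitude signal
#' amplitude, drawn from a normal distribution truncated at zero.
#'
#' @param slope behavioral effect (%) per unit subject amplitude.
#' @param intercept baseline effect (%).
#' @param noise_sd residual SD of the effect (%), >= 0.
#' @param amplitude_mean,amplitude_sd distribution of per-subject amplitude.
#' @return an `sd_coupling` parameter list.
#' @export
coupling_params <- function(slope = 0, intercept = 0, noise_sd = 1,
                            amplitude_mean = 1, amplitude_sd = 0.3) {
  stopifnot(noise_sd >= 0, amplitude_sd >= 0)
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd),
            class = "sd_coupling")
}

#' Simulate a cohort with a known brain-behavior coupling
#'
#' For each subject: draw a signal amplitude from the coupling's amplitude
#' distribution (truncated at 0), set the true behavioral effect to
#' `intercept + slope * amplitude + noise`, convert that effect into the
#' observer's PSE bias on the task dimension, then generate a randomized
#' discrimination design, observer responses, and epochs whose
#' past-magnitude signal is scaled by the subject's amplitude. All
#' per-subject seeds are derived from `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param obs base [observer_params()]; the task-dimension bias is
#'   overwritten per subject by the coupling.
#' @param eeg [eeg_sim_params()]; the seed field is re-derived per subject.
#' @param coupling [coupling_params()].
#' @param seed master integer seed.
#' @param task task dimension carrying the behavioral coupling.
#' @param n_reps_per_cell design size knob (default 10 -> 400 trials).
#' @return list of per-subject bundles: `trial_table`, `epochs`,
#'   `effect_true` (%), `amplitude`, `observer`; plus attribute `task`.
#' @export
simulate_cohort <- function(n_subjects, obs, eeg, coupling, seed = 1,
                            task = "numerosity", n_reps_per_cell = 10) {
  stopifnot(n_subjects >= 2, inherits(obs, "sd_observer"),
            inherits(eeg, "sd_eeg_params"), inherits(coupling, "sd_coupling"))
  task <- match.arg(task, .sd_dimensions)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, n_subjects * 3)
  amplitude <- pmax(0, stats::rnorm(n_subjects, coupling$amplitude_mean,
                                    coupling$amplitude_sd))
  effect_true <- coupling$intercept + coupling$slope * amplitude +
    stats::rnorm(n_subjects, 0, coupling$noise_sd)

  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    obs_i <- obs
    obs_i$bias[[task]] <- bias_from_effect(effect_true[i], obs$pse_base)
    tab <- generate_design_exp1(task, n_reps_per_cell = n_reps_per_cell,
                                seed = sub_seeds[3 * i - 2])
    tab$subject <- i
    tab <- simulate_responses(tab, obs_i, seed = sub_seeds[3 * i - 1])
    eeg_i <- eeg
    eeg_i$seed <- sub_seeds[3 * i]
    epochs <- simulate_epochs(tab, eeg_i, subject_amplitude = amplitude[i])
    out[[i]] <- list(trial_table = tab, epochs = epochs,
                     effect_true = effect_true[i], amplitude = amplitude[i],
                     observer = obs_i)
  }
  attr(out, "task") <- task
  out
}
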