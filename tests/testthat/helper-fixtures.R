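# Shared fixtures and independent oracles used across the suite.

# Exhaustive grid-search MLE for the lapse-corrected cumulative Gaussian;
# independent of the optim-based fit it checks.
grid_mle_psy <- function(levels, k, n, lapse, mus, sigmas) {
  best <- c(mu = NA, sigma = NA)
  best_ll <- -Inf
  for (mu in mus) {
    for (s in sigmas) {
      psi <- lapse / 2 + (1 - lapse) * pnorm((levels - mu) / s)
      psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
      ll <- sum(k * log(psi) + (n - k) * log(1 - psi))
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(mu = mu, sigma = s)
      }
    }
  }
  best
}

# Brute-force Benjamini-Hochberg step-up adjustment straight from the
# definition: p_(i) * m / i, enforced monotone from the top.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, p[o] * m / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Small epoch fixture: a discrimination design with a past-numerosity
# signal of the given amplitude inside `window` (ms), low channel count so
# decoding tests stay fast.
make_test_epochs <- function(n_reps = 2, amplitude = 0, n_channels = 4,
                             window = c(100, 300), seed = 11,
                             epoch_start = -200, epoch_end = 500,
                             noise_sd = 1) {
  tab <- generate_design_exp1("numerosity", n_reps_per_cell = n_reps,
                              seed = seed)
  eeg <- eeg_sim_params(
    n_channels = n_channels, sampling_rate = 100,
    epoch_start = epoch_start, epoch_end = epoch_end,
    signal_windows = list(list(start = window[1], end = window[2],
                               amplitude = c(numerosity = 1))),
    noise_sd = noise_sd, seed = seed + 1)
  simulate_epochs(tab, eeg, subject_amplitude = amplitude)
}

fast_decoding_params <- function(seed = 1, ...) {
  decoding_params(pseudo_k = 2, n_pseudo_per_class = 5, n_iterations = 2,
                  n_keep = 3, seed = seed, ...)
}
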