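test_that("discrimination design is a balanced randomized factorial", {
  for (task in c("numerosity", "size")) {
    tab <- generate_design_exp1(task, n_reps_per_cell = 10, seed = 1)
    expect_equal(nrow(tab), 400)
    combo <- paste(tab$inducer_numerosity, tab$inducer_duration,
                   tab$inducer_dot_size)
    expect_true(all(table(combo) == 50))
    expect_setequal(unique(tab$probe_magnitude), probe_levels(task))
    cell <- paste(combo, tab$probe_magnitude)
    expect_true(all(table(cell) == 10))
  }
  # seeded reproducibility
  a <- generate_design_exp1("duration", 3, seed = 9)
  b <- generate_design_exp1("duration", 3, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_design_exp1("duration", 3, seed = 10)))
  expect_error(generate_design_exp1("orientation", 10, 1), "unknown task")
})

test_that("passive stream has the stated counts, catch rate and past labels", {
  tab <- generate_design_exp2(n_blocks = 8, reps_per_combo = 80,
                              catch_per_block = 10, seed = 2)
  expect_equal(nrow(tab), 2160)
  combo <- paste(tab$numerosity, tab$duration, tab$dot_size)
  expect_true(all(table(combo) == 80))
  expect_equal(length(unique(combo)), 27)
  expect_equal(sum(tab$is_catch), 80)
  expect_equal(mean(tab$is_catch), 10 / 270, tolerance = 1e-12)
  expect_true(all(tab$contrast[tab$is_catch] == 0.7))
  expect_true(all(tab$contrast[!tab$is_catch] == 1))
  # past labels are the previous trial's magnitudes within a block
  in_block <- which(tab$usable_past)
  expect_equal(tab$past_numerosity[in_block], tab$numerosity[in_block - 1])
  expect_equal(tab$past_duration[in_block], tab$duration[in_block - 1])
  firsts <- which(!tab$usable_past)
  expect_equal(firsts, seq(1, 2160, by = 270))
  expect_true(all(is.na(tab$past_numerosity[firsts])))

  small <- generate_design_exp2(1, 1, 0, seed = 3)
  expect_equal(nrow(small), 27)
  expect_equal(anyDuplicated(paste(small$numerosity, small$duration,
                                   small$dot_size)), 0)
  expect_error(generate_design_exp2(n_blocks = 7, reps_per_combo = 80, 10, 1),
               "split evenly")
})

test_that("observer responses follow the biased psychometric model", {
  tab <- generate_design_exp1("numerosity", 10, seed = 4)
  # degenerate-slope limit: deterministic step at pse_base
  obs0 <- observer_params(pse_base = 16, sigma = 1e-9, lapse = 0)
  r <- simulate_responses(tab, obs0, seed = 5)
  off <- r$probe_magnitude != 16
  expect_equal(r$response[off], as.integer(r$probe_magnitude[off] > 16))
  # unbiased observer: effect index ~ 0
  obs_null <- observer_params(pse_base = 16, sigma = 2, lapse = 0.05)
  rn <- simulate_responses(tab, obs_null, seed = 6)
  eb <- effects_by_inducer(rn, "numerosity")
  expect_lt(abs(eb$effect$eff), 3)
  # passive design has no probe
  expect_error(simulate_responses(generate_design_exp2(1, 2, 0, 1), obs_null),
               "no probe")
})

test_that("generative PSE separation is recovered by the split fits", {
  # one 400-trial session estimates the separation with SD ~0.8 probe units,
  # so the +-0.5 recovery band is asserted on the mean over 10 observers
  obs <- observer_params(pse_base = 16, sigma = 2, lapse = 0.05,
                         bias_numerosity = 1.6)
  seps <- sapply(1:10, function(s) {
    tab <- generate_design_exp1("numerosity", 10, seed = s)
    r <- simulate_responses(tab, obs, seed = s + 100)
    eb <- effects_by_inducer(r, "numerosity")
    eb$effect$pse_high - eb$effect$pse_low
  })
  expect_equal(mean(seps), 1.6, tolerance = 0.5 / 1.6)
})

test_that("simulated epochs have the exact time grid and a clean null", {
  ep <- make_test_epochs(n_reps = 2, amplitude = 0, epoch_start = -200,
                         epoch_end = 700)
  expect_equal(min(ep$time_ms), -200)
  expect_equal(max(ep$time_ms), 700)
  expect_equal(diff(ep$time_ms)[1], 10)  # 100 Hz fixture
  # zero amplitude: per-channel class mean difference is noise-level
  cls <- sort_epochs_by_past(ep, "numerosity")
  md <- apply(cls$low$data, 2, mean) - apply(cls$high$data, 2, mean)
  expect_lt(max(abs(md)), 4 / sqrt(80 * 91 / 10))
  # seeded determinism: identical call, identical array
  ep2 <- make_test_epochs(n_reps = 2, amplitude = 0, epoch_start = -200,
                          epoch_end = 700)
  expect_identical(ep$data, ep2$data)
  # signal window outside epoch span is rejected at construction
  expect_error(
    eeg_sim_params(n_channels = 4, epoch_start = -200, epoch_end = 500,
                   signal_windows = list(list(start = 400, end = 800,
                                              amplitude = c(numerosity = 1)))),
    "outside the epoch span")
})

test_that("cohort bundles carry consistent ground truth", {
  cohort <- simulate_cohort(
    2, observer_params(), eeg_sim_params(n_channels = 4, sampling_rate = 100),
    coupling_params(slope = 10, intercept = 2, noise_sd = 0.5), seed = 3,
    n_reps_per_cell = 1)
  expect_length(cohort, 2)
  for (s in cohort) {
    expect_s3_class(s$trial_table, "sd_trial_table")
    expect_s3_class(s$epochs, "sd_epochs")
    expect_true(is.finite(s$effect_true))
    expect_gte(s$amplitude, 0)
    # the observer bias encodes the true effect around pse_base
    pse_base <- s$observer$pse_base
    b <- s$observer$bias[["numerosity"]]
    eff_implied <- (b / (pse_base - b / 2)) * 100
    expect_equal(eff_implied, s$effect_true, tolerance = 1e-8)
  }
  expect_error(simulate_cohort(1, observer_params(),
                               eeg_sim_params(n_channels = 4),
                               coupling_params(), seed = 1))
})
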