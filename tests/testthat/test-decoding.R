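test_that("sliding-window grid and averaging follow the window contract", {
  g <- window_grid(-200, 700, length = 100, step = 20)
  expect_length(g$starts, 41)
  expect_equal(g$starts[1:3], c(-200, -180, -160))
  expect_equal(tail(g$starts, 1), 600)

  ep <- make_test_epochs(n_reps = 1, amplitude = 0)
  # constant-valued epoch: every windowed feature equals the constant
  ep$data[] <- 3.25
  gg <- grid_for_epochs(ep)
  f <- window_average(ep, gg)
  expect_true(all(abs(f - 3.25) < 1e-12))
  # single-sample windows reproduce the raw samples
  g1 <- window_grid(min(ep$time_ms), max(ep$time_ms) + 10,
                    length = 10, step = 10)
  ep$data[] <- rnorm(length(ep$data))
  f1 <- window_average(ep, g1)
  expect_equal(f1[5, 2, 7], ep$data[5, 2, 7])
})

test_that("pseudo-trial averaging partitions disjointly and discards remainder", {
  arr <- array(rnorm(40 * 3 * 2), c(40, 3, 2))
  p <- make_pseudotrials(arr, k = 10, seed = 5)
  expect_equal(dim(p), c(4, 3, 2))
  # oracle: direct averaging over the same partition
  set.seed(5)
  ord <- sample.int(40)
  for (g in 1:4) {
    idx <- ord[((g - 1) * 10 + 1):(g * 10)]
    expect_equal(p[g, , ], apply(arr[idx, , ], c(2, 3), mean))
  }
  # remainder discard: 39 trials, k = 10 -> 3 pseudo-trials
  expect_equal(dim(make_pseudotrials(arr[1:39, , , drop = FALSE], 10, 1))[1], 3)
  # k = 1: original trials in permuted order
  p1 <- make_pseudotrials(arr, 1, seed = 2)
  expect_equal(dim(p1)[1], 40)
  expect_equal(apply(p1, 1, sum)[order(apply(p1, 1, sum))],
               apply(arr, 1, sum)[order(apply(arr, 1, sum))])
  expect_error(make_pseudotrials(arr[1:5, , , drop = FALSE], 10),
               "fewer than k")
})

test_that("channel selection ranks by training-set F with index tie-breaks", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(n * 10, sd = 0.5), n, 10)
  y <- rep(c("a", "b"), each = n / 2)
  x[y == "b", 3] <- x[y == "b", 3] + 3
  x[y == "b", 7] <- x[y == "b", 7] + 3
  sel <- select_channels(x, y, 2)
  expect_setequal(sel, c(3, 7))
  # oracle: two-sample t^2 ranking picks the same channels
  t2 <- sapply(1:10, function(j) t.test(x[y == "a", j], x[y == "b", j],
                                        var.equal = TRUE)$statistic^2)
  expect_setequal(order(-t2)[1:2], sel)
  # no-op selection and deterministic tie-break on identical classes
  expect_equal(select_channels(x[, 1:5], y, 5), 1:5)
  xc <- matrix(1, n, 6)  # zero variance everywhere -> F = 0, ties by index
  expect_equal(select_channels(xc, y, 3), 1:3)
})

test_that("decoding finds an injected signal at its latency and not before", {
  ep <- make_test_epochs(n_reps = 3, amplitude = 4, n_channels = 4,
                         window = c(100, 300), seed = 13)
  cls <- sort_epochs_by_past(ep, "numerosity")
  g <- grid_for_epochs(ep)
  dp <- decoding_params(pseudo_k = 3, n_pseudo_per_class = 8,
                        n_iterations = 4, n_keep = 3, seed = 2)
  dec <- decode_timecourse(cls$low, cls$high, g, dp)
  expect_true(all(dec$ca_per_window >= 0 & dec$ca_per_window <= 1))
  expect_equal(dec$ca_per_window, colMeans(dec$per_iteration_ca))
  expect_gt(window_mean_ca(dec, 100, 300), 0.95)
  expect_lt(abs(window_mean_ca(dec, -200, 0) - 0.5), 0.2)
  # centroid-classifier oracle agrees that the signal window separates
  f <- window_average(ep, g)
  w_in <- which(g$starts >= 100 & g$starts + g$length <= 300)[1]
  lab <- ep$trial_meta$past_numerosity
  m_lo <- colMeans(f[lab == 12, , w_in])
  m_hi <- colMeans(f[lab == 24, , w_in])
  pred_hi <- apply(f[, , w_in], 1, function(v) {
    sum((v - m_hi)^2) < sum((v - m_lo)^2)
  })
  expect_gt(mean(pred_hi == (lab == 24)), 0.95)
  # seeded determinism
  dec2 <- decode_timecourse(cls$low, cls$high, g, dp)
  expect_identical(dec$per_iteration_ca, dec2$per_iteration_ca)
})

test_that("leave-one-out folds match an independent hand enumeration", {
  # tiny instance: 4 pseudo-trials per class, 2 channels, k = 2, 1 iteration
  ep <- make_test_epochs(n_reps = 1, amplitude = 1.5, n_channels = 2,
                         window = c(0, 300), seed = 17,
                         epoch_start = -100, epoch_end = 300)
  cls <- sort_epochs_by_past(ep, "numerosity")  # 20 trials per class
  g <- window_grid(-100, 300, length = 100, step = 100)
  dp <- decoding_params(pseudo_k = 5, n_pseudo_per_class = 4,
                        n_iterations = 1, n_keep = 2, seed = 41)
  dec <- decode_timecourse(cls$low, cls$high, g, dp)

  # independent enumeration of the same iteration, mirroring the seeded
  # partition then exhaustively looping folds and windows
  f0 <- window_average(cls$low, g)
  f1 <- window_average(cls$high, g)
  set.seed(42)  # seed + iteration index
  avg_groups <- function(f, ord, k, np) {
    out <- array(NA_real_, c(np, dim(f)[2], dim(f)[3]))
    for (gi in seq_len(np)) {
      idx <- ord[((gi - 1) * k + 1):(gi * k)]
      out[gi, , ] <- apply(f[idx, , , drop = FALSE], c(2, 3), mean)
    }
    out
  }
  p0 <- avg_groups(f0, sample.int(dim(f0)[1]), 5, 4)
  p1 <- avg_groups(f1, sample.int(dim(f1)[1]), 5, 4)
  nw <- length(g$starts)
  correct <- matrix(0, 4, nw)
  for (f in 1:4) {
    for (w in seq_len(nw)) {
      xtr <- rbind(p0[-f, , w], p1[-f, , w])
      ytr <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
      mu <- colMeans(xtr); s <- apply(xtr, 2, sd); s[s == 0] <- 1
      xs <- scale(xtr, mu, s)
      fit <- e1071::svm(xs, ytr, kernel = "linear", cost = 1, scale = FALSE)
      xte <- scale(rbind(p0[f, , w], p1[f, , w]), mu, s)
      pred <- as.character(predict(fit, xte))
      correct[f, w] <- mean(pred == c("low", "high"))
    }
  }
  expect_equal(dec$ca_per_window, colMeans(correct), tolerance = 1e-12)
})

test_that("shuffled-label decoding stays at chance even with strong signal", {
  ep <- make_test_epochs(n_reps = 3, amplitude = 4, n_channels = 4,
                         window = c(100, 300), seed = 19)
  cls <- sort_epochs_by_past(ep, "numerosity")
  g <- window_grid(-200, 500, length = 100, step = 50)
  dp <- decoding_params(pseudo_k = 3, n_pseudo_per_class = 8,
                        n_iterations = 6, n_keep = 3, seed = 5)
  nul <- null_decode_timecourse(cls$low, cls$high, g, dp)
  expect_true(nul$is_null)
  expect_lt(abs(mean(nul$ca_per_window) - 0.5), 0.1)
  # determinism of the null path too
  nul2 <- null_decode_timecourse(cls$low, cls$high, g, dp)
  expect_identical(nul$per_iteration_ca, nul2$per_iteration_ca)
})

test_that("temporal generalization diagonal equals the timecourse decoding", {
  ep <- make_test_epochs(n_reps = 2, amplitude = 2, n_channels = 3,
                         window = c(0, 400), seed = 23,
                         epoch_start = -100, epoch_end = 400)
  cls <- sort_epochs_by_past(ep, "numerosity")
  g <- window_grid(-100, 400, length = 100, step = 100)
  dp <- decoding_params(pseudo_k = 4, n_pseudo_per_class = 5,
                        n_iterations = 2, n_keep = 3, seed = 7)
  dec <- decode_timecourse(cls$low, cls$high, g, dp)
  tgm <- temporal_generalization(cls$low, cls$high, g, dp)
  expect_equal(diag(tgm$ca), dec$ca_per_window, tolerance = 1e-12)
  # a temporally sustained pattern generalizes off the diagonal
  sig <- g$starts >= 0 & g$starts + g$length <= 400
  expect_gt(mean(tgm$ca[sig, sig]), 0.75)
})

test_that("latency-window averaging uses full containment", {
  g <- window_grid(-200, 700, length = 100, step = 20)
  ca <- rep(0.6, 41)
  fake <- structure(list(ca_per_window = ca, grid = g), class = "sd_decoding")
  expect_equal(window_mean_ca(fake, 50, 200), 0.6)
  # exactly the windows starting at 60, 80, 100 ms qualify for 50-200 ms
  keep <- g$starts >= 50 & g$starts + 100 <= 200
  expect_equal(g$starts[keep], c(60, 80, 100))
  ca2 <- seq_along(g$starts) / 41
  fake2 <- structure(list(ca_per_window = ca2, grid = g),
                     class = "sd_decoding")
  expect_equal(window_mean_ca(fake2, 50, 200), mean(ca2[keep]))
  expect_error(window_mean_ca(fake, 50, 100), "no window fully contained")
})

test_that("class sorting marginalizes other dimensions and drops intermediates", {
  ep <- make_test_epochs(n_reps = 2, amplitude = 0)
  cls <- sort_epochs_by_past(ep, "numerosity")
  # balanced factorial: equal class sizes, other dimensions marginalized
  expect_equal(dim(cls$low$data)[1], dim(cls$high$data)[1])
  expect_setequal(unique(cls$low$trial_meta$past_duration), c(140, 280))
  # passive stream: intermediate past levels excluded
  tab2 <- generate_design_exp2(1, 2, 0, seed = 3)
  eeg <- eeg_sim_params(n_channels = 3, sampling_rate = 100,
                        epoch_start = -100, epoch_end = 300,
                        signal_windows = list(list(start = 0, end = 200,
                                                   amplitude = c(numerosity = 1))))
  ep2 <- simulate_epochs(tab2, eeg, 0)
  cls2 <- sort_epochs_by_past(ep2, "duration")
  expect_setequal(unique(cls2$low$trial_meta$past_duration), 140)
  expect_setequal(unique(cls2$high$trial_meta$past_duration), 280)
  expect_error(sort_epochs_by_past(ep, "contrast"), "unknown dimension")
})
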