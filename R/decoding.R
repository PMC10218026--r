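#' Sliding-window grid over an epoch
#'
#' Windows of fixed length placed every `step` ms, indexed by their start
#' time; the last window is the latest one that still fits inside the span.
#' The canonical grid over a -200..700 ms epoch with 100 ms windows and
#' 20 ms steps has 41 windows starting at -200, -180, ..., 600 ms.
#'
#' @param t_min,t_max epoch span in ms.
#' @param length window length in ms (default 100).
#' @param step window step in ms (default 20).
#' @return an `sd_window_grid` list with `starts`, `length`, `step`.
#' @export
window_grid <- function(t_min, t_max, length = 100, step = 20) {
  stopifnot(length > 0, step > 0, t_max - t_min >= length)
  structure(list(starts = seq(t_min, t_max - length, by = step),
                 length = length, step = step),
            class = "sd_window_grid")
}

#' Default grid for an epoch set
#' @param epochs an `sd_epochs` object.
#' @param length,step window length and step in ms.
#' @return an `sd_window_grid` spanning the epoch.
#' @export
grid_for_epochs <- function(epochs, length = 100, step = 20) {
  window_grid(min(epochs$time_ms), max(epochs$time_ms), length, step)
}

#' Split epochs into low/high past-magnitude classes
#'
#' Partitions an epoch set by the binarized past-magnitude label of one
#' dimension (low vs high extreme level), marginalizing all other
#' dimensions. Trials whose past level on that dimension is intermediate or
#' undefined (e.g., the first trial of a passive-stream block) are excluded.
#'
#' @param epochs an `sd_epochs` object.
#' @param dimension "numerosity", "duration" or "size".
#' @return list with `low` and `high` `sd_epochs` subsets.
#' @export
sort_epochs_by_past <- function(epochs, dimension) {
  stopifnot(inherits(epochs, "sd_epochs"))
  if (!dimension %in% .sd_dimensions) {
    stop("sort_epochs_by_past: unknown dimension '", dimension, "'")
  }
  col <- c(numerosity = "past_numerosity", duration = "past_duration",
           size = "past_dot_size")[[dimension]]
  lv <- .sd_levels_exp2[[dimension]]
  x <- epochs$trial_meta[[col]]
  usable <- epochs$trial_meta$usable_past & !is.na(x)
  low_idx <- which(usable & x == min(lv))
  high_idx <- which(usable & x == max(lv))
  if (length(low_idx) == 0 || length(high_idx) == 0) {
    stop("sort_epochs_by_past: empty class after filtering on ", dimension)
  }
  list(low = subset_epochs(epochs, low_idx),
       high = subset_epochs(epochs, high_idx))
}

#' Average epoch activity in sliding windows
#'
#' For every trial and channel, the mean amplitude over the samples whose
#' timestamps fall in `[start, start + length)` of each window.
#'
#' @param epochs an `sd_epochs` object.
#' @param grid an `sd_window_grid` valid for the epoch span.
#' @return numeric array, trials x channels x windows.
#' @export
window_average <- function(epochs, grid) {
  stopifnot(inherits(epochs, "sd_epochs"), inherits(grid, "sd_window_grid"))
  t <- epochs$time_ms
  d <- dim(epochs$data)
  nw <- length(grid$starts)
  out <- array(NA_real_, c(d[1], d[2], nw))
  for (w in seq_len(nw)) {
    in_w <- t >= grid$starts[w] & t < grid$starts[w] + grid$length
    if (!any(in_w)) stop("window_average: window ", grid$starts[w],
                         " ms contains no samples")
    sub <- epochs$data[, , in_w, drop = FALSE]
    out[, , w] <- rowMeans(sub, dims = 2)
  }
  out
}

#' Average random groups of trials into pseudo-trials
#'
#' Within each class, trials are randomly partitioned (disjointly) into
#' groups of exactly `k`; leftover trials are discarded and each group is
#' averaged into one pseudo-trial. With `k = 1` the pseudo-trials are the
#' original trials in permuted order.
#'
#' @param features trials x channels x windows array (one class).
#' @param k trials per pseudo-trial (>= 1; class must have >= k trials).
#' @param seed integer seed for the random partition.
#' @param n_keep optional cap on the number of pseudo-trials kept.
#' @return pseudo-trials x channels x windows array.
#' @export
make_pseudotrials <- function(features, k, seed = NULL, n_keep = NULL) {
  stopifnot(length(dim(features)) == 3, k >= 1)
  n <- dim(features)[1]
  if (n < k) stop("make_pseudotrials: class has ", n, " trials, fewer than k = ", k)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n)
  n_groups <- n %/% k
  if (!is.null(n_keep)) n_groups <- min(n_groups, n_keep)
  out <- array(NA_real_, c(n_groups, dim(features)[2], dim(features)[3]))
  for (g in seq_len(n_groups)) {
    idx <- ord[((g - 1) * k + 1):(g * k)]
    out[g, , ] <- colMeans(features[idx, , , drop = FALSE], dims = 1)
  }
  out
}

#' Select the most class-informative channels by univariate ANOVA
#'
#' Per channel, a one-way ANOVA F statistic of the (window-averaged)
#' feature against the class labels, computed on the training set only;
#' the `n_keep` channels with the largest F are returned, ties broken in
#' favor of the lower channel index. Zero-variance channels get F = 0.
#'
#' @param train_features trials x channels matrix (training fold).
#' @param labels class labels (length = rows of `train_features`).
#' @param n_keep number of channels to keep.
#' @return sorted integer vector of selected channel indices.
#' @export
select_channels <- function(train_features, labels, n_keep) {
  stopifnot(is.matrix(train_features), nrow(train_features) == length(labels),
            n_keep >= 1, n_keep <= ncol(train_features))
  f <- channel_f_stats(train_features, labels)
  sort(order(-f)[seq_len(n_keep)])
}

# Vectorized one-way ANOVA F per column; 0 where within-group variance is 0
# or F is otherwise undefined.
channel_f_stats <- function(x, labels) {
  g <- as.factor(labels)
  n <- nrow(x)
  k <- nlevels(g)
  grand <- colMeans(x)
  ss_b <- numeric(ncol(x))
  ss_w <- numeric(ncol(x))
  for (lv in levels(g)) {
    xg <- x[g == lv, , drop = FALSE]
    m <- colMeans(xg)
    ss_b <- ss_b + nrow(xg) * (m - grand)^2
    ss_w <- ss_w + colSums(sweep(xg, 2, m)^2)
  }
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  f[!is.finite(f)] <- 0
  f
}

#' Decoding parameters
#'
#' @param pseudo_k trials averaged per pseudo-trial; `NULL` selects
#'   `min(20, floor(n_min_class / n_pseudo_per_class))` clipped to
#'   \[10, 20\], emulating a 10-20 trial average adapted to the available
#'   data.
#' @param n_pseudo_per_class pseudo-trials per class entering the
#'   leave-one-out cross-validation (default 10).
#' @param n_iterations resampling iterations; the final accuracy is their
#'   mean (default 30).
#' @param n_keep channels retained by the training-set ANOVA (default 5).
#' @param seed master seed; iteration i uses `seed + i` so every iteration
#'   is independently reproducible.
#' @return an `sd_decoding_params` list.
#' @export
decoding_params <- function(pseudo_k = NULL, n_pseudo_per_class = 10,
                            n_iterations = 30, n_keep = 5, seed = 1) {
  stopifnot(is.null(pseudo_k) || pseudo_k >= 1, n_pseudo_per_class >= 2,
            n_iterations >= 1, n_keep >= 1)
  structure(list(pseudo_k = pseudo_k,
                 n_pseudo_per_class = n_pseudo_per_class,
                 n_iterations = n_iterations, n_keep = n_keep,
                 seed = as.integer(seed)),
            class = "sd_decoding_params")
}

resolve_pseudo_k <- function(params, n0, n1) {
  if (!is.null(params$pseudo_k)) return(params$pseudo_k)
  k <- min(20, (min(n0, n1)) %/% params$n_pseudo_per_class)
  min(20, max(10, k))
}

#' Time-resolved leave-one-out SVM decoding of past-stimulus class
#'
#' For each of `n_iterations` resampling iterations: trials of each class
#' are window-averaged, randomly grouped into pseudo-trials, and classified
#' window by window with a linear support vector machine (C = 1) under
#' leave-one-pseudo-trial-out cross-validation (one pseudo-trial per class
#' held out per fold). Channel selection (top `n_keep` by training-set
#' ANOVA F) and feature z-scoring are computed on the training fold only.
#' Per-window accuracy is the fraction of held-out pseudo-trials classified
#' correctly across folds; the final estimate is the mean over iterations.
#'
#' @param epochs0,epochs1 `sd_epochs` subsets for the two classes (e.g.,
#'   from [sort_epochs_by_past()]).
#' @param grid an `sd_window_grid`.
#' @param params an [decoding_params()] list.
#' @param null_labels if `TRUE`, training labels are shuffled within every
#'   fold (the shuffled-label empirical-chance analysis).
#' @return an `sd_decoding` result: `ca_per_window`, `per_iteration_ca`
#'   (iterations x windows), `grid`, `pseudo_k`, `n_pseudo_per_class`,
#'   `n_iterations`, `n_selected_channels`, `is_null`, `seed`.
#' @export
decode_timecourse <- function(epochs0, epochs1, grid,
                              params = decoding_params(),
                              null_labels = FALSE) {
  stopifnot(inherits(epochs0, "sd_epochs"), inherits(epochs1, "sd_epochs"),
            inherits(grid, "sd_window_grid"),
            inherits(params, "sd_decoding_params"))
  f0 <- window_average(epochs0, grid)
  f1 <- window_average(epochs1, grid)
  k <- resolve_pseudo_k(params, dim(f0)[1], dim(f1)[1])
  if (dim(f0)[1] < 2 * k || dim(f1)[1] < 2 * k) {
    stop("decode_timecourse: fewer than 2 pseudo-trials per class ",
         "(k = ", k, ", classes of ", dim(f0)[1], " and ", dim(f1)[1], ")")
  }
  nw <- length(grid$starts)
  per_iter <- matrix(NA_real_, params$n_iterations, nw)
  for (it in seq_len(params$n_iterations)) {
    set.seed(params$seed + it)
    np <- min(params$n_pseudo_per_class, dim(f0)[1] %/% k, dim(f1)[1] %/% k)
    p0 <- make_pseudotrials(f0, k, n_keep = np)
    p1 <- make_pseudotrials(f1, k, n_keep = np)
    per_iter[it, ] <- loo_accuracy(p0, p1, params$n_keep, null_labels)
  }
  structure(list(
    ca_per_window = colMeans(per_iter), per_iteration_ca = per_iter,
    grid = grid, pseudo_k = k,
    n_pseudo_per_class = min(params$n_pseudo_per_class,
                             dim(f0)[1] %/% k, dim(f1)[1] %/% k),
    n_iterations = params$n_iterations,
    n_selected_channels = params$n_keep,
    is_null = null_labels, seed = params$seed
  ), class = "sd_decoding")
}

# Leave-one-pseudo-trial-out (paired across classes) linear-SVM accuracy per
# window. Assumes the RNG state set by the caller; the only RNG use is the
# per-fold training-label shuffle of the null analysis.
loo_accuracy <- function(p0, p1, n_keep, null_labels) {
  np <- dim(p0)[1]
  nw <- dim(p0)[3]
  n_keep <- min(n_keep, dim(p0)[2])
  correct <- matrix(0, np, nw)
  y_full <- factor(rep(c("low", "high"), each = np - 1),
                   levels = c("low", "high"))
  for (f in seq_len(np)) {
    perm <- if (null_labels) sample.int(2 * (np - 1)) else seq_len(2 * (np - 1))
    for (w in seq_len(nw)) {
      xtr <- rbind(p0[-f, , w, drop = TRUE], p1[-f, , w, drop = TRUE])
      if (np == 2) xtr <- rbind(matrix(p0[-f, , w], nrow = 1),
                                matrix(p1[-f, , w], nrow = 1))
      ytr <- y_full[perm]
      sel <- select_channels(xtr, ytr, n_keep)
      mdl <- train_scaled_svm(xtr[, sel, drop = FALSE], ytr)
      xte <- rbind(p0[f, sel, w], p1[f, sel, w])
      pred <- predict_scaled_svm(mdl, xte)
      correct[f, w] <- sum(pred == c("low", "high")) / 2
    }
  }
  colMeans(correct)
}

train_scaled_svm <- function(xtr, ytr) {
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2, stats::sd)
  sd[sd == 0] <- 1
  xs <- sweep(sweep(xtr, 2, mu), 2, sd, "/")
  fit <- e1071::svm(xs, ytr, kernel = "linear", cost = 1, scale = FALSE)
  list(fit = fit, mu = mu, sd = sd)
}

predict_scaled_svm <- function(mdl, xte) {
  xs <- sweep(sweep(xte, 2, mdl$mu), 2, mdl$sd, "/")
  as.character(stats::predict(mdl$fit, xs))
}

#' Shuffled-label (null) decoding
#'
#' Identical to [decode_timecourse()] except that the training labels are
#' permuted before classification, destroying the class information. The
#' resulting accuracies estimate the empirical chance level against which
#' the actual decoding is tested.
#'
#' @inheritParams decode_timecourse
#' @return an `sd_decoding` result with `is_null = TRUE`.
#' @export
null_decode_timecourse <- function(epochs0, epochs1, grid,
                                   params = decoding_params()) {
  decode_timecourse(epochs0, epochs1, grid, params, null_labels = TRUE)
}

#' @export
print.sd_decoding <- function(x, ...) {
  cat(sprintf(
    "%secoding: %d windows, %d iterations, k = %d, %d pseudo-trials/class; mean CA = %.3f\n",
    if (x$is_null) "Null (shuffled-label) d" else "D",
    length(x$grid$starts), x$n_iterations, x$pseudo_k,
    x$n_pseudo_per_class, mean(x$ca_per_window)))
  invisible(x)
}

#' Plot a decoding timecourse
#' @param x an `sd_decoding` result.
#' @param ... passed to [plot()].
#' @export
plot.sd_decoding <- function(x, ...) {
  plot(x$grid$starts + x$grid$length / 2, x$ca_per_window, type = "l",
       xlab = "Window center (ms)", ylab = "Classification accuracy",
       ylim = range(c(0.4, 0.6, x$ca_per_window)), ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Temporal generalization matrix
#'
#' Trains the classifier on each window and tests it on every window, using
#' the same folds, channel selection and scaling as the diagonal analysis
#' (selection and scaling come from the training window's training fold and
#' are applied to the test window's held-out features). The diagonal equals
#' the [decode_timecourse()] output for the same seed.
#'
#' @inheritParams decode_timecourse
#' @return an `sd_tgm` list: `ca` (train x test windows), `grid`, `seed`.
#' @export
temporal_generalization <- function(epochs0, epochs1, grid,
                                    params = decoding_params()) {
  stopifnot(inherits(epochs0, "sd_epochs"), inherits(epochs1, "sd_epochs"))
  f0 <- window_average(epochs0, grid)
  f1 <- window_average(epochs1, grid)
  k <- resolve_pseudo_k(params, dim(f0)[1], dim(f1)[1])
  if (dim(f0)[1] < 2 * k || dim(f1)[1] < 2 * k) {
    stop("temporal_generalization: fewer than 2 pseudo-trials per class")
  }
  nw <- length(grid$starts)
  acc <- array(0, c(params$n_iterations, nw, nw))
  for (it in seq_len(params$n_iterations)) {
    set.seed(params$seed + it)
    np <- min(params$n_pseudo_per_class, dim(f0)[1] %/% k, dim(f1)[1] %/% k)
    p0 <- make_pseudotrials(f0, k, n_keep = np)
    p1 <- make_pseudotrials(f1, k, n_keep = np)
    n_keep <- min(params$n_keep, dim(p0)[2])
    y_full <- factor(rep(c("low", "high"), each = np - 1),
                     levels = c("low", "high"))
    for (f in seq_len(np)) {
      for (w in seq_len(nw)) {
        xtr <- rbind(matrix(p0[-f, , w], ncol = dim(p0)[2]),
                     matrix(p1[-f, , w], ncol = dim(p1)[2]))
        sel <- select_channels(xtr, y_full, n_keep)
        mdl <- train_scaled_svm(xtr[, sel, drop = FALSE], y_full)
        # test on every window's held-out features, same channels/scaling
        xte <- rbind(t(p0[f, sel, , drop = TRUE]),
                     t(p1[f, sel, , drop = TRUE]))
        if (length(sel) == 1) xte <- cbind(c(p0[f, sel, ], p1[f, sel, ]))
        pred <- predict_scaled_svm(mdl, xte)
        truth <- rep(c("low", "high"), each = nw)
        acc[it, w, ] <- acc[it, w, ] +
          (as.numeric(pred[1:nw] == "low") +
             as.numeric(pred[nw + 1:nw] == "high")) / 2
      }
    }
    acc[it, , ] <- acc[it, , ] / np
  }
  structure(list(ca = apply(acc, c(2, 3), mean), grid = grid,
                 seed = params$seed),
            class = "sd_tgm")
}

#' Mean accuracy over a latency window
#'
#' Mean of the per-window classification accuracies over the windows whose
#' full extent `[start, start + length)` lies inside `[t_start, t_end]`
#' (full-containment rule). On the canonical 41-window grid the 50-200 ms
#' interval selects exactly the windows starting at 60, 80 and 100 ms.
#'
#' @param result an `sd_decoding` result.
#' @param t_start,t_end latency interval in ms.
#' @return scalar mean accuracy.
#' @export
window_mean_ca <- function(result, t_start, t_end) {
  stopifnot(inherits(result, "sd_decoding"))
  g <- result$grid
  keep <- g$starts >= t_start & (g$starts + g$length) <= t_end
  if (!any(keep)) {
    stop("window_mean_ca: no window fully contained in [", t_start, ", ",
         t_end, "] ms")
  }
  mean(result$ca_per_window[keep])
}
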