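# Canonical magnitude levels. The reference stimulus is constant at 16 dots,
# 200 ms, 6 px; inducer/past levels bracket it symmetrically on each dimension.
.sd_reference <- c(numerosity = 16, duration = 200, size = 6)

.sd_inducer_levels_exp1 <- list(
  numerosity = c(12, 24),
  duration = c(140, 280),
  size = c(4, 8)
)

.sd_levels_exp2 <- list(
  numerosity = c(12, 16, 24),
  duration = c(140, 200, 280),
  size = c(4, 6, 8)
)

.sd_probe_levels <- list(
  numerosity = c(8, 12, 16, 24, 32),
  duration = c(100, 140, 200, 280, 400),
  size = c(3, 4, 6, 8, 12)
)

.sd_dimensions <- c("numerosity", "duration", "size")

#' Reference magnitudes and canonical level sets
#'
#' The constant reference stimulus is 16 dots / 200 ms / 6 px. Inducer levels
#' in the discrimination experiment are 12/24 dots, 140/280 ms, 4/8 px; the
#' passive-stream experiment adds the intermediate (reference) level on every
#' dimension.
#'
#' @return named numeric vector of reference magnitudes.
#' @export
reference_magnitudes <- function() .sd_reference

#' Probe levels for a task
#' @param task one of "numerosity", "duration", "size".
#' @return numeric vector of the 5 probe magnitudes for that task.
#' @export
probe_levels <- function(task) {
  task <- match.arg(task, .sd_dimensions)
  .sd_probe_levels[[task]]
}

new_trial_table <- function(df, experiment) {
  df$experiment <- experiment
  class(df) <- c("sd_trial_table", "data.frame")
  df
}

#' Generate a discrimination-task (Experiment-1-style) trial design
#'
#' Full factorial of the 2 x 2 x 2 inducer magnitudes (numerosity 12/24 dots,
#' duration 140/280 ms, dot size 4/8 px) crossed with the five task-specific
#' probe levels, each cell repeated `n_reps_per_cell` times, in randomized
#' order. The default of 10 repetitions gives the canonical 400-trial session
#' (10 blocks of 40 trials).
#'
#' @param task "numerosity", "duration" or "size"; selects the probe levels.
#' @param n_reps_per_cell repetitions of each inducer x probe cell (>= 1).
#' @param seed integer seed for the trial-order randomization.
#' @return an `sd_trial_table` data frame with one row per trial.
#' @export
generate_design_exp1 <- function(task, n_reps_per_cell = 10, seed = 1) {
  if (!is.character(task) || length(task) != 1 || !task %in% .sd_dimensions) {
    stop("generate_design_exp1: unknown task label '", paste(task, collapse = ","),
         "'; must be one of ", paste(.sd_dimensions, collapse = ", "))
  }
  stopifnot(n_reps_per_cell >= 1)
  cells <- expand.grid(
    inducer_numerosity = .sd_inducer_levels_exp1$numerosity,
    inducer_duration = .sd_inducer_levels_exp1$duration,
    inducer_dot_size = .sd_inducer_levels_exp1$size,
    probe_magnitude = .sd_probe_levels[[task]],
    KEEP.OUT.ATTRS = FALSE
  )
  df <- cells[rep(seq_len(nrow(cells)), times = n_reps_per_cell), , drop = FALSE]
  set.seed(seed)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  block_size <- 40L
  df <- data.frame(
    subject = NA_integer_,
    block = ((seq_len(n) - 1L) %/% block_size) + 1L,
    trial = seq_len(n),
    task = task,
    df,
    is_catch = FALSE,
    contrast = 1,
    response = NA_integer_
  )
  new_trial_table(df, experiment = 1L)
}

#' Generate a passive magnitude-stream (Experiment-2-style) trial design
#'
#' A stream of single stimuli drawn from the 3 x 3 x 3 factorial of
#' numerosity (12/16/24 dots), duration (140/200/280 ms), and dot size
#' (4/6/8 px), each combination repeated `reps_per_combo` times and the
#' stream split into `n_blocks` blocks. `catch_per_block` trials in each
#' block are flagged as low-contrast catch (oddball) trials (contrast 0.7 of
#' standard). Every trial carries the previous trial's magnitudes as its
#' past-magnitude labels; the first trial of each block has no usable past.
#' The defaults (8 blocks, 80 reps, 10 catch/block) give the canonical
#' 2,160-trial session with a 10/270 = 3.7% catch rate.
#'
#' @param n_blocks number of blocks the stream is split into.
#' @param reps_per_combo repetitions of each of the 27 magnitude combinations.
#' @param catch_per_block low-contrast catch trials per block.
#' @param seed integer seed for stream order and catch placement.
#' @return an `sd_trial_table` data frame with one row per trial.
#' @export
generate_design_exp2 <- function(n_blocks = 8, reps_per_combo = 80,
                                 catch_per_block = 10, seed = 1) {
  stopifnot(n_blocks >= 1, reps_per_combo >= 1, catch_per_block >= 0)
  n_total <- 27L * reps_per_combo
  if (n_total %% n_blocks != 0) {
    stop("generate_design_exp2: ", n_total, " trials cannot be split evenly ",
         "into ", n_blocks, " blocks")
  }
  per_block <- n_total %/% n_blocks
  if (catch_per_block > per_block) {
    stop("generate_design_exp2: catch_per_block exceeds trials per block")
  }
  combos <- expand.grid(
    numerosity = .sd_levels_exp2$numerosity,
    duration = .sd_levels_exp2$duration,
    dot_size = .sd_levels_exp2$size,
    KEEP.OUT.ATTRS = FALSE
  )
  df <- combos[rep(seq_len(nrow(combos)), times = reps_per_combo), , drop = FALSE]
  set.seed(seed)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  block <- ((seq_len(n_total) - 1L) %/% per_block) + 1L
  is_catch <- logical(n_total)
  if (catch_per_block > 0) {
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      is_catch[sample(idx, catch_per_block)] <- TRUE
    }
  }
  first_of_block <- c(TRUE, diff(block) != 0)
  past <- function(x) c(NA, x[-length(x)])
  df <- data.frame(
    subject = NA_integer_,
    block = block,
    trial = seq_len(n_total),
    task = "passive",
    df,
    past_numerosity = past(df$numerosity),
    past_duration = past(df$duration),
    past_dot_size = past(df$dot_size),
    is_catch = is_catch,
    contrast = ifelse(is_catch, 0.7, 1),
    usable_past = !first_of_block,
    response = NA_integer_
  )
  df$past_numerosity[first_of_block] <- NA
  df$past_duration[first_of_block] <- NA
  df$past_dot_size[first_of_block] <- NA
  new_trial_table(df, experiment = 2L)
}

#' @export
print.sd_trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, experiment %d, task(s): %s\n",
              nrow(x), x$experiment[1], paste(unique(x$task), collapse = ", ")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

# Past-magnitude labels for either experiment. For the discrimination design
# the preceding (inducer) magnitudes are the past labels of the reference
# epoch; for the passive stream they are the previous trial's magnitudes.
past_labels <- function(table) {
  if (table$experiment[1] == 1L) {
    data.frame(
      past_numerosity = table$inducer_numerosity,
      past_duration = table$inducer_duration,
      past_dot_size = table$inducer_dot_size,
      usable_past = TRUE
    )
  } else {
    data.frame(
      past_numerosity = table$past_numerosity,
      past_duration = table$past_duration,
      past_dot_size = table$past_dot_size,
      usable_past = table$usable_past
    )
  }
}
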