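#' Assemble and validate a full pipeline configuration
#'
#' Bundles every parameter of an end-to-end run: cohort size, observer,
#' epoch simulator, brain-behavior coupling, decoding settings, latency
#' windows, test batteries and the cluster permutation. All parameters are
#' validated here, before any stage runs; the master seed is mandatory.
#'
#' @param n_subjects cohort size (>= 3 so the group stats are defined).
#' @param task task condition ("numerosity", "duration" or "size").
#' @param dimensions past-magnitude dimensions to decode (subset of the
#'   three; defaults to the task dimension).
#' @param observer,eeg,coupling parameter objects (see
#'   [observer_params()], [eeg_sim_params()], [coupling_params()]).
#' @param decoding an [decoding_params()] list.
#' @param n_reps_per_cell design size per subject (10 -> 400 trials).
#' @param window_length,window_step decoding grid in ms.
#' @param latency_windows named list of `c(start, end)` ms intervals over
#'   which accuracies are averaged for the group tests (defaults: early
#'   50-200 ms, late 500-650 ms).
#' @param alpha,min_len cluster-forming threshold and minimum run length.
#' @param n_perm cluster permutations (default 1000; use 10000 for final
#'   inference).
#' @param fdr_q FDR level for the latency-window test battery.
#' @param seed master seed (mandatory, integer).
#' @param export_epochs also write each subject's epochs under the run
#'   directory (large text files; default FALSE).
#' @return an `sd_run_config` list.
#' @export
run_config <- function(n_subjects = 10, task = "numerosity",
                       dimensions = task,
                       observer = observer_params(),
                       eeg = eeg_sim_params(n_channels = 8),
                       coupling = coupling_params(),
                       decoding = decoding_params(),
                       n_reps_per_cell = 10,
                       window_length = 100, window_step = 20,
                       latency_windows = list(early = c(50, 200),
                                              late = c(500, 650)),
                       alpha = 0.05, min_len = 2, n_perm = 1000,
                       fdr_q = 0.05, seed = NULL, export_epochs = FALSE) {
  if (is.null(seed)) stop("run_config: a master seed is mandatory")
  task <- match.arg(task, .sd_dimensions)
  stopifnot(n_subjects >= 3, all(dimensions %in% .sd_dimensions),
            inherits(observer, "sd_observer"), inherits(eeg, "sd_eeg_params"),
            inherits(coupling, "sd_coupling"),
            inherits(decoding, "sd_decoding_params"),
            n_perm >= 100, alpha > 0, alpha < 1, min_len >= 1)
  for (lw in latency_windows) stopifnot(length(lw) == 2, lw[1] < lw[2])
  structure(list(
    n_subjects = n_subjects, task = task, dimensions = dimensions,
    observer = observer, eeg = eeg, coupling = coupling,
    decoding = decoding, n_reps_per_cell = n_reps_per_cell,
    window_length = window_length, window_step = window_step,
    latency_windows = latency_windows, alpha = alpha, min_len = min_len,
    n_perm = n_perm, fdr_q = fdr_q, seed = as.integer(seed),
    export_epochs = export_epochs
  ), class = "sd_run_config")
}

stage_msg <- function(run_dir, stage, t0) {
  message(sprintf("[%s] %s (%.1f s)", basename(run_dir), stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full simulate / fit-behavior / decode / link pipeline
#'
#' Stages: (1) simulate a cohort with known ground truth; (2) fit each
#' subject's psychometric functions per inducer split, compute the
#' serial-dependence index and the trial-level regression; (3) run the
#' actual and shuffled-label decoding per subject and dimension; (4) group
#' level: latency-window accuracy tables with one-sample t tests against
#' the empirical null mean (FDR-adjusted within each latency window), the
#' per-window effect-on-accuracy regression, cluster formation, and the
#' cluster permutation test. Every stage writes its outputs as CSV/JSON
#' files under `out_dir`, and a manifest records every seed and parameter,
#' so any stage can be re-run or swapped for real recordings in the same
#' formats.
#'
#' @param config an [run_config()] object.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results: `behavior`
#'   (per-subject data frame), `ca_windows` (per dimension: actual/null
#'   subjects x windows matrices), `latency_tests`, `lme`, `clusters`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "sd_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())

  cohort <- simulate_cohort(config$n_subjects, config$observer, config$eeg,
                            config$coupling, seed = config$seed,
                            task = config$task,
                            n_reps_per_cell = config$n_reps_per_cell)
  stage_msg(out_dir, "simulate: cohort generated", t0)

  # ---- behavior ----
  beh_rows <- list()
  for (i in seq_along(cohort)) {
    tab <- cohort[[i]]$trial_table
    write_trial_table(tab, file.path(out_dir, sprintf("trials_s%02d.csv", i)))
    reg <- trial_regression(tab)
    get_beta <- function(term) reg$coefficients$beta[reg$coefficients$term == term]
    for (dm in config$dimensions) {
      eb <- effects_by_inducer(tab, dm)
      beh_rows[[length(beh_rows) + 1]] <- data.frame(
        subject = i, task = config$task, dimension = dm,
        pse_low = eb$effect$pse_low, pse_high = eb$effect$pse_high,
        jnd = mean(c(eb$fit_low$jnd, eb$fit_high$jnd)),
        wf = mean(c(eb$fit_low$wf, eb$fit_high$wf)),
        eff = eb$effect$eff, effect_true = cohort[[i]]$effect_true,
        beta_probe = get_beta("probe"),
        beta_numerosity = get_beta("numerosity"),
        beta_duration = get_beta("duration"),
        beta_size = get_beta("size"),
        regression_converged = reg$converged
      )
    }
  }
  behavior <- do.call(rbind, beh_rows)
  utils::write.csv(behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)
  stage_msg(out_dir, "fit-behavior: psychometric fits and effect indices", t0)

  # ---- decoding ----
  grid <- window_grid(config$eeg$epoch_start, config$eeg$epoch_end,
                      config$window_length, config$window_step)
  ca_windows <- list()
  ca_rows <- list()
  for (dm in config$dimensions) {
    act <- matrix(NA_real_, config$n_subjects, length(grid$starts))
    nul <- matrix(NA_real_, config$n_subjects, length(grid$starts))
    for (i in seq_along(cohort)) {
      if (config$export_epochs) {
        write_epochs(cohort[[i]]$epochs,
                     file.path(out_dir, sprintf("epochs_s%02d", i)))
      }
      cls <- sort_epochs_by_past(cohort[[i]]$epochs, dm)
      dp <- config$decoding
      dp$seed <- config$decoding$seed + 1000L * i
      act[i, ] <- decode_timecourse(cls$low, cls$high, grid, dp)$ca_per_window
      nul[i, ] <- null_decode_timecourse(cls$low, cls$high, grid,
                                         dp)$ca_per_window
      ca_rows[[length(ca_rows) + 1]] <- data.frame(
        subject = i, dimension = dm, is_null = c(FALSE, TRUE),
        rbind(act[i, ], nul[i, ]))
    }
    ca_windows[[dm]] <- list(actual = act, null = nul)
  }
  ca_long <- do.call(rbind, ca_rows)
  names(ca_long)[-(1:3)] <- paste0("w_", grid$starts)
  utils::write.csv(ca_long, file.path(out_dir, "ca_windows.csv"),
                   row.names = FALSE)
  stage_msg(out_dir, "decode: actual and null timecourses", t0)

  # ---- group: latency-window tests ----
  lat_rows <- list()
  for (lw_name in names(config$latency_windows)) {
    lw <- config$latency_windows[[lw_name]]
    keep <- grid$starts >= lw[1] & (grid$starts + grid$length) <= lw[2]
    pvals <- c()
    for (dm in config$dimensions) {
      ca_act <- rowMeans(ca_windows[[dm]]$actual[, keep, drop = FALSE])
      ca_nul <- rowMeans(ca_windows[[dm]]$null[, keep, drop = FALSE])
      tt <- one_sample_t(ca_act, null_mean = mean(ca_nul))
      lat_rows[[length(lat_rows) + 1]] <- data.frame(
        latency = lw_name, dimension = dm, ca = mean(ca_act),
        null_ca = mean(ca_nul), t = tt$t, df = tt$df, p = tt$p,
        cohens_d = tt$cohens_d)
      pvals <- c(pvals, tt$p)
    }
    # FDR within each latency-window battery
    idx <- (length(lat_rows) - length(config$dimensions) + 1):length(lat_rows)
    adj <- bh_adjust(pvals, q = config$fdr_q)
    for (j in seq_along(idx)) {
      lat_rows[[idx[j]]]$adj_p <- adj$p_adjusted[j]
      lat_rows[[idx[j]]]$significant <- adj$rejected[j]
    }
  }
  latency_tests <- do.call(rbind, lat_rows)
  utils::write.csv(latency_tests, file.path(out_dir, "latency_tests.csv"),
                   row.names = FALSE)
  stage_msg(out_dir, "link: latency-window tests", t0)

  # ---- group: per-window regression + clusters ----
  lme_all <- list()
  clusters_all <- list()
  for (dm in config$dimensions) {
    eff <- behavior$eff[behavior$dimension == dm]
    lt <- lme_timecourse(eff, ca_windows[[dm]]$actual,
                         window_starts = grid$starts)
    lt$dimension <- dm
    lme_all[[dm]] <- lt
    cls <- find_clusters(lt$p, alpha = config$alpha, min_len = config$min_len,
                         window_starts = grid$starts, t_values = lt$t)
    cls <- lapply(cls, function(cl) {
      cluster_permutation_test(cl, eff, ca_windows[[dm]]$actual,
                               n_perm = config$n_perm,
                               seed = config$seed + 77L)
    })
    clusters_all[[dm]] <- cls
  }
  lme_df <- do.call(rbind, lme_all)
  utils::write.csv(lme_df, file.path(out_dir, "lme_timecourse.csv"),
                   row.names = FALSE)
  cl_rows <- list()
  for (dm in names(clusters_all)) {
    for (cl in clusters_all[[dm]]) {
      cl_rows[[length(cl_rows) + 1]] <- data.frame(
        dimension = dm, start_ms = min(cl$window_starts),
        end_ms = max(cl$window_starts) + config$window_length,
        n_windows = cl$length, min_abs_t = cl$min_abs_t,
        perm_p = cl$perm_p, n_perm = cl$n_perm)
    }
  }
  cl_df <- if (length(cl_rows)) do.call(rbind, cl_rows) else
    data.frame(dimension = character(), start_ms = numeric(),
               end_ms = numeric(), n_windows = integer(),
               min_abs_t = numeric(), perm_p = numeric(),
               n_perm = integer())
  utils::write.csv(cl_df, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cl_df, file.path(out_dir, "clusters.json"),
                       dataframe = "rows", digits = NA)
  stage_msg(out_dir, "link: per-window regression and cluster permutation", t0)

  manifest <- list(
    package = "serialdep",
    seed = config$seed,
    n_subjects = config$n_subjects, task = config$task,
    dimensions = config$dimensions,
    n_reps_per_cell = config$n_reps_per_cell,
    eeg = list(n_channels = config$eeg$n_channels,
               sampling_rate = config$eeg$sampling_rate,
               epoch_start = config$eeg$epoch_start,
               epoch_end = config$eeg$epoch_end,
               noise_sd = config$eeg$noise_sd,
               noise_ar1 = config$eeg$noise_ar1,
               seed = config$eeg$seed),
    observer = list(pse_base = config$observer$pse_base,
                    sigma = config$observer$sigma,
                    lapse = config$observer$lapse,
                    bias = as.list(config$observer$bias)),
    coupling = unclass(config$coupling),
    decoding = unclass(config$decoding),
    window_length = config$window_length, window_step = config$window_step,
    latency_windows = config$latency_windows,
    alpha = config$alpha, min_len = config$min_len, n_perm = config$n_perm,
    fdr_q = config$fdr_q,
    files = c("behavior.csv", "ca_windows.csv", "latency_tests.csv",
              "lme_timecourse.csv", "clusters.csv", "clusters.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_msg(out_dir, "done", t0)

  invisible(list(behavior = behavior, ca_windows = ca_windows,
                 latency_tests = latency_tests, lme = lme_df,
                 clusters = clusters_all, manifest = manifest,
                 grid = grid))
}

#' Summarize a completed pipeline run
#'
#' Reads the files written by [run_pipeline()] and produces a
#' human-readable summary: mean serial-dependence effect per (task,
#' dimension), latency-window accuracies with their tests, and the cluster
#' listing. Errors with an explicit list of missing artifacts if the run is
#' incomplete. Re-running it on the same directory gives the same report.
#'
#' @param run_dir directory of a completed run.
#' @return an `sd_report` list: `effects`, `latency_tests`, `clusters`,
#'   `manifest`.
#' @export
make_report <- function(run_dir) {
  needed <- c("manifest.json", "behavior.csv", "latency_tests.csv",
              "clusters.csv")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing)) {
    stop("make_report: missing artifacts in ", run_dir, ": ",
         paste(missing, collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  behavior <- utils::read.csv(file.path(run_dir, "behavior.csv"))
  latency <- utils::read.csv(file.path(run_dir, "latency_tests.csv"))
  clusters <- utils::read.csv(file.path(run_dir, "clusters.csv"))
  effects <- do.call(rbind, lapply(
    split(behavior, list(behavior$task, behavior$dimension), drop = TRUE),
    function(g) data.frame(task = g$task[1], dimension = g$dimension[1],
                           mean_eff = mean(g$eff),
                           sem_eff = stats::sd(g$eff) / sqrt(nrow(g)),
                           mean_wf = mean(g$wf), n = nrow(g))))
  rownames(effects) <- NULL
  structure(list(effects = effects, latency_tests = latency,
                 clusters = clusters, manifest = manifest),
            class = "sd_report")
}

#' @export
print.sd_report <- function(x, ...) {
  cat("== Serial-dependence run report ==\n")
  cat(sprintf("Subjects: %d, task: %s, seed: %d\n\n",
              x$manifest$n_subjects, x$manifest$task, x$manifest$seed))
  cat("Behavioral effect index (%) by task and dimension:\n")
  print(x$effects, digits = 3)
  cat("\nLatency-window decoding vs empirical null:\n")
  print(x$latency_tests, digits = 3)
  cat("\nClusters (effect ~ accuracy):\n")
  if (nrow(x$clusters) == 0) cat("  none\n") else print(x$clusters, digits = 3)
  invisible(x)
}
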