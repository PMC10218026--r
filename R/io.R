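#' Write / read a trial table as CSV
#'
#' Plain CSV with one row per trial and a documented header (the table's
#' own column names, including the `experiment` tag column used to restore
#' the object on read).
#'
#' @param table an `sd_trial_table`.
#' @param path file path (`.csv` or `.tsv`; the extension picks the
#'   separator).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "sd_trial_table"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"experiment" %in% names(df)) {
    stop("read_trial_table: missing 'experiment' column in ", path)
  }
  class(df) <- c("sd_trial_table", "data.frame")
  df
}

#' Write / read an epoch set as a plain-text directory
#'
#' Serializes an `sd_epochs` object to a directory containing `meta.json`
#' (sampling rate, channel labels, dimensions), `time_ms.tsv`,
#' `trial_meta.tsv`, and `data.tsv` (one row per trial x channel, columns
#' `trial`, `channel`, then one column per sample). Text-based so the files
#' are portable and diffable; note they are several times larger than a
#' binary container.
#'
#' @param epochs an `sd_epochs` object.
#' @param dir directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "sd_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  jsonlite::write_json(
    list(sampling_rate = epochs$sampling_rate,
         channel_labels = epochs$channel_labels,
         n_trials = d[1], n_channels = d[2], n_samples = d[3]),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(time_ms = epochs$time_ms),
                     file.path(dir, "time_ms.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(epochs$trial_meta, file.path(dir, "trial_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  idx <- expand.grid(channel = seq_len(d[2]), trial = seq_len(d[1]))
  out <- cbind(trial = idx$trial, channel = idx$channel, flat)
  utils::write.table(out, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  time_ms <- utils::read.table(file.path(dir, "time_ms.tsv"),
                               header = TRUE)$time_ms
  trial_meta <- utils::read.table(file.path(dir, "trial_meta.tsv"),
                                  header = TRUE, sep = "\t")
  raw <- as.matrix(utils::read.table(file.path(dir, "data.tsv"), sep = "\t"))
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  ord <- order(raw[, 1], raw[, 2])
  vals <- raw[ord, -(1:2), drop = FALSE]
  data <- aperm(array(t(vals), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  new_epoch_set(data, time_ms, meta$sampling_rate, meta$channel_labels,
                trial_meta)
}
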