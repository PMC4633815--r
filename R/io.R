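#' Write an epoched dataset to disk
#'
#' The epoched container is a directory holding a documented binary layout:
#' `data.bin` (little-endian float64, sample-fastest order: sample within
#' channel within trial), a `meta.json` sidecar (dimensions, channel names,
#' sampling rate, time axis, subject id) and `labels.tsv` (one row per
#' trial). The full session design is stored alongside as `design.tsv` plus
#' `design.json` (the design-spec constants), so a read round-trips both the
#' epochs and the design.
#'
#' @param epochs an `epoch_set`
#' @param design the matching `session_design` (optional)
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_synthetic_dataset <- function(epochs, design = NULL, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con), add = TRUE)
  # trial-major, then channel, then sample
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  meta <- list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
               srate_hz = epochs$srate_hz, times_ms = epochs$times,
               channel_names = epochs$channel_names,
               subject_id = epochs$subject_id,
               layout = "float64-le sample-fastest")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(epochs$labels, file.path(path, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(design)) {
    utils::write.table(design$trials, file.path(path, "design.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(subject_id = design$subject_id, seed = design$seed,
           spec = unclass(design$spec)),
      file.path(path, "design.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an epoched dataset written by [write_synthetic_dataset()]
#'
#' @param path container directory
#' @return list with `epochs` (an `epoch_set`) and `design` (a
#'   `session_design`, or NULL if none was stored)
#' @export
read_synthetic_dataset <- function(path) {
  meta_f <- file.path(path, "meta.json")
  if (!file.exists(meta_f))
    stop("read_synthetic_dataset: missing ", meta_f, call. = FALSE)
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  n <- meta$n_trials * meta$n_channels * meta$n_samples
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(raw) != n)
    stop("read_synthetic_dataset: data.bin truncated (", length(raw),
         " of ", n, " values)", call. = FALSE)
  dat <- aperm(array(raw, dim = c(meta$n_samples, meta$n_channels,
                                  meta$n_trials)), c(3, 2, 1))
  labels <- utils::read.delim(file.path(path, "labels.tsv"))
  epochs <- structure(
    list(data = dat, channel_names = meta$channel_names,
         srate_hz = meta$srate_hz, times = meta$times_ms, labels = labels,
         subject_id = meta$subject_id),
    class = "epoch_set")
  design <- NULL
  dj <- file.path(path, "design.json")
  if (file.exists(dj)) {
    dmeta <- jsonlite::read_json(dj, simplifyVector = TRUE)
    spec <- dmeta$spec
    class(spec) <- "design_spec"
    design <- structure(
      list(subject_id = dmeta$subject_id, spec = spec, seed = dmeta$seed,
           familiarization = NULL,
           trials = utils::read.delim(file.path(path, "design.tsv"))),
      class = "session_design")
  }
  list(epochs = epochs, design = design)
}

# absolute target-onset times (s) for each test trial, trials back-to-back
# within a block, feedback + inter-block gap between blocks
trial_target_onsets_s <- function(design, start_s = 2) {
  spec <- design$spec
  span_s <- (spec$forward_mask_ms + spec$backward_mask_total_ms) / 1000
  gap_s <- (spec$feedback_duration_ms + spec$interblock_interval_ms) / 1000
  tr <- design$trials
  idx_in_block <- stats::ave(seq_len(nrow(tr)), tr$block, FUN = seq_along)
  block_start <- start_s + (tr$block - 1) * (spec$block_size * span_s + gap_s)
  block_start + (idx_in_block - 1) * span_s + spec$forward_mask_ms / 1000
}

#' Export a continuous recording with an events table
#'
#' Renders the session as one continuous multichannel recording (epochs
#' placed at their session timeline positions over a 1/f background) and
#' writes it as `continuous.bin` (float64-le, channel-major per sample) with
#' a `meta.json` sidecar plus a BIDS-flavoured `events.tsv` (columns
#' `onset_s`, `duration_s`, `trial_type`, `block`, `duration_ms`,
#' `lookaway`), one row per test trial, `onset_s` the target onset.
#'
#' @param epochs an `epoch_set` (one epoch per design trial, in design order)
#' @param design the matching `session_design`
#' @param path directory to create
#' @return `path`, invisibly
#' @export
write_continuous_dataset <- function(epochs, design, path) {
  stopifnot(nrow(epochs$labels) == nrow(design$trials))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  srate <- epochs$srate_hz
  onsets_s <- trial_target_onsets_s(design)
  total_s <- max(onsets_s) + 3
  n_samp <- ceiling(total_s * srate)
  n_ch <- length(epochs$channel_names)
  cont <- matrix(0, n_ch, n_samp)
  # place each epoch: its first sample sits 37 samples before the event
  ev_samp <- round(onsets_s * srate) + 1L  # 1-based sample of target onset
  n_ep_s <- length(epochs$times)
  for (i in seq_len(nrow(design$trials))) {
    idx <- (ev_samp[i] - 37L):(ev_samp[i] - 37L + n_ep_s - 1L)
    cont[, idx] <- epochs$data[i, , ]
  }
  con <- file(file.path(path, "continuous.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(cont), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(n_channels = n_ch, n_samples = n_samp, srate_hz = srate,
         channel_names = epochs$channel_names,
         layout = "float64-le channel-fastest"),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  events <- data.frame(
    onset_s = onsets_s,
    duration_s = design$trials$duration_ms / 1000,
    trial_type = condition_label(design$trials),
    block = design$trials$block,
    duration_ms = design$trials$duration_ms,
    lookaway = epochs$labels$lookaway
  )
  utils::write.table(events, file.path(path, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a continuous recording written by [write_continuous_dataset()]
#'
#' @param path directory
#' @return list with `data` (channels x samples matrix), `srate_hz`,
#'   `channel_names`, and `events` (data.frame)
#' @export
read_continuous_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(path, "continuous.bin"), "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
                 size = 8, endian = "little")
  if (length(raw) != meta$n_channels * meta$n_samples)
    stop("read_continuous_dataset: continuous.bin truncated", call. = FALSE)
  ev_f <- file.path(path, "events.tsv")
  events <- if (file.exists(ev_f)) utils::read.delim(ev_f) else NULL
  list(data = matrix(raw, meta$n_channels, meta$n_samples),
       srate_hz = meta$srate_hz, channel_names = meta$channel_names,
       events = events)
}
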