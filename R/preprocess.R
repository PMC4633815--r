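#' Preprocessing configuration
#'
#' All numeric constants of the infant EEG cleaning chain. Rejection
#' comparisons are strict at the thresholds: a channel is flagged only if
#' its voltage *exceeds* +/-400 uV (or its 10-sample local deviation exceeds
#' 400 uV), and a trial is rejected only if *more than* 35% of channels are
#' contaminated.
#'
#' @param srate_hz sampling rate (250)
#' @param hp_hz,lp_hz high-/low-pass cutoffs (0.2 and 20 Hz); zero-phase
#'   order-2 Butterworth each
#' @param epoch_window_ms epoch limits relative to target onset
#' @param abs_voltage_reject_uv absolute-voltage channel threshold (400)
#' @param local_deviation_uv peak-to-peak threshold in the sliding window
#' @param local_deviation_window_samples sliding-window length (10 samples)
#' @param bad_channel_trial_fraction trial-rejection fraction (0.35)
#' @param smoothing_threshold_uv temporal-smoothing threshold (120)
#' @param smoothing_window_samples moving-average window for smoothing (5)
#' @param interp_k number of nearest good electrodes for interpolation (4)
#' @param baseline_window_ms baseline interval, half-open at onset
#' @param min_trials_per_condition subject-exclusion floor (2)
#' @return object of class `preproc_config`
#' @export
preproc_config <- function(srate_hz = 250, hp_hz = 0.2, lp_hz = 20,
                           epoch_window_ms = c(-150, 1700),
                           abs_voltage_reject_uv = 400,
                           local_deviation_uv = 400,
                           local_deviation_window_samples = 10L,
                           bad_channel_trial_fraction = 0.35,
                           smoothing_threshold_uv = 120,
                           smoothing_window_samples = 5L,
                           interp_k = 4L,
                           baseline_window_ms = c(-150, 0),
                           min_trials_per_condition = 2L) {
  cfg <- as.list(environment())
  class(cfg) <- "preproc_config"
  if (cfg$hp_hz >= cfg$lp_hz)
    stop("preproc_config: `hp_hz` must be below `lp_hz`", call. = FALSE)
  if (any(c(cfg$abs_voltage_reject_uv, cfg$local_deviation_uv,
            cfg$smoothing_threshold_uv) <= 0))
    stop("preproc_config: thresholds must be positive", call. = FALSE)
  if (cfg$bad_channel_trial_fraction <= 0 || cfg$bad_channel_trial_fraction >= 1)
    stop("preproc_config: `bad_channel_trial_fraction` must lie in (0, 1)",
         call. = FALSE)
  cfg
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean is exactly zero afterwards.
#'
#' @param data channels x samples matrix
#' @return matrix of the same shape
#' @export
rereference_to_average <- function(data) {
  if (nrow(data) < 2)
    stop("rereference_to_average: need at least 2 channels", call. = FALSE)
  sweep(data, 2, colMeans(data))
}

#' Zero-phase band-pass filter
#'
#' Order-2 Butterworth high-pass and low-pass responses applied with zero
#' phase: the segment is reflection-padded, Fourier-transformed, multiplied
#' by the squared Butterworth magnitude response (the gain a
#' forward-backward IIR pass would have, with none of its edge transients —
#' important for 0.2 Hz high-passing of short epochs), and cropped back.
#' Component peak latencies are preserved exactly. Passband gain is ~1
#' between 1 and 15 Hz; a 40 Hz tone is attenuated to 0.059; DC is removed.
#'
#' @param data channels x samples matrix
#' @param cfg a [preproc_config()]
#' @return filtered matrix
#' @export
bandpass_filter <- function(data, cfg = preproc_config()) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  n <- ncol(data)
  if (n < 24)
    stop("bandpass_filter: segment too short for the filter warm-up (",
         n, " samples)", call. = FALSE)
  # reflect >= 0.5 s at each edge, total length 2-3-5-smooth for the FFT
  pad_min <- min(n - 1, cfg$srate_hz %/% 2)
  m <- stats::nextn(n + 2L * pad_min)
  if (m - n > 2L * (n - 1L)) m <- n + 2L * pad_min  # reflection can't exceed n-1
  padl <- (m - n) %/% 2
  padr <- m - n - padl
  idx <- c((padl + 1):2, seq_len(n), (n - 1):(n - padr))
  ext <- data[, idx, drop = FALSE]
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * cfg$srate_hz / m
  # |H|^2 of order-2 Butterworth HP and LP cascades (zero phase)
  gain <- ((f / cfg$hp_hz)^4 / (1 + (f / cfg$hp_hz)^4)) *
    (1 / (1 + (f / cfg$lp_hz)^4))
  gain[f == 0] <- 0
  flt <- Re(t(stats::mvfft(stats::mvfft(t(ext)) * gain, inverse = TRUE))) / m
  out <- flt[, padl + seq_len(n), drop = FALSE]
  dimnames(out) <- dimnames(data)
  out
}

#' Cut epochs from a continuous recording
#'
#' Epochs span the canonical 462-sample axis; for an event at (1-based)
#' sample `s` the epoch starts at sample `s - 37` (the -150 ms edge mapped
#' by flooring 37.5 samples, per the package's axis convention). Events too
#' close to the recording edge are skipped with a warning.
#'
#' @param continuous channels x samples matrix
#' @param events data.frame with `onset_s` (target onsets, seconds) and any
#'   label columns (`trial_type`, `block`, `duration_ms`, `lookaway`, ...)
#' @param cfg a [preproc_config()]
#' @param channel_names channel labels for the resulting `epoch_set`
#' @return an `epoch_set`
#' @export
segment_epochs <- function(continuous, events, cfg = preproc_config(),
                           channel_names = NULL) {
  times <- epoch_times(cfg$srate_hz, cfg$epoch_window_ms[1],
                       cfg$epoch_window_ms[2])
  n_s <- length(times)
  pre <- floor(-cfg$epoch_window_ms[1] * cfg$srate_hz / 1000)  # 37
  ev_samp <- round(events$onset_s * cfg$srate_hz) + 1L
  first <- ev_samp - pre
  ok <- first >= 1L & (first + n_s - 1L) <= ncol(continuous)
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; skipped")
  keep <- which(ok)
  n_ch <- nrow(continuous)
  dat <- array(0, dim = c(length(keep), n_ch, n_s))
  for (j in seq_along(keep)) {
    i <- keep[j]
    dat[j, , ] <- continuous[, first[i]:(first[i] + n_s - 1L)]
  }
  labels <- events[keep, setdiff(names(events), "onset_s"), drop = FALSE]
  rownames(labels) <- NULL
  if (is.null(channel_names)) channel_names <- paste0("E", seq_len(n_ch))
  structure(list(data = dat, channel_names = channel_names,
                 srate_hz = cfg$srate_hz, times = times, labels = labels,
                 subject_id = NULL),
            class = "epoch_set")
}

# subset an epoch_set by trial index
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx, , drop = FALSE]
  rownames(epochs$labels) <- NULL
  epochs
}

#' Reject look-away trials
#'
#' Drops every epoch whose `lookaway` QC flag is set (gaze was coded away
#' from the screen during the trial).
#'
#' @param epochs an `epoch_set` with a `lookaway` label column
#' @return filtered `epoch_set`; attribute `n_rejected` carries the count
#' @export
reject_lookaway <- function(epochs) {
  la <- as.logical(epochs$labels$lookaway)
  out <- subset_epochs(epochs, which(!la))
  attr(out, "n_rejected") <- sum(la)
  out
}

#' Flag contaminated channels in one epoch
#'
#' A channel is contaminated if its absolute voltage exceeds the +/-400 uV
#' threshold at any sample, or if its peak-to-peak range within any
#' 10-sample sliding window exceeds 400 uV ("local deviation").
#'
#' @param epoch channels x samples matrix
#' @param cfg a [preproc_config()]
#' @return logical vector, one flag per channel
#' @export
detect_bad_channels <- function(epoch, cfg = preproc_config()) {
  bad_abs <- apply(abs(epoch), 1, max) > cfg$abs_voltage_reject_uv
  w <- cfg$local_deviation_window_samples
  n <- ncol(epoch)
  if (n >= w) {
    # running max/min over the window via shifted pmax/pmin reductions
    hi <- epoch[, 1:(n - w + 1), drop = FALSE]
    lo <- hi
    for (k in 1:(w - 1)) {
      shift <- epoch[, (1 + k):(n - w + 1 + k), drop = FALSE]
      hi <- pmax(hi, shift)
      lo <- pmin(lo, shift)
    }
    bad_dev <- apply(hi - lo, 1, max) > cfg$local_deviation_uv
  } else {
    bad_dev <- rep(FALSE, nrow(epoch))
  }
  bad_abs | bad_dev
}

#' Interpolate contaminated channels
#'
#' Replaces each flagged channel with the inverse-distance-weighted mean of
#' its `k` nearest unflagged electrodes (3-D montage positions). Unflagged
#' channels are returned bit-identical.
#'
#' @param epoch channels x samples matrix
#' @param mask logical vector of contaminated channels
#' @param montage electrode table ([synthetic_montage()]); row order must
#'   match the epoch's channels
#' @param k number of good neighbours to combine (default 4)
#' @return epoch with flagged channels replaced
#' @export
interpolate_channels <- function(epoch, mask, montage, k = 4L) {
  if (!any(mask)) return(epoch)
  if (all(mask))
    stop("interpolate_channels: all channels flagged; reject the trial ",
         "instead", call. = FALSE)
  pos <- as.matrix(montage[, c("x", "y", "z")])
  good <- which(!mask)
  for (ch in which(mask)) {
    d <- sqrt(rowSums((pos[good, , drop = FALSE] -
                         matrix(pos[ch, ], length(good), 3, byrow = TRUE))^2))
    nn <- good[order(d)[seq_len(min(k, length(good)))]]
    wts <- 1 / pmax(d[order(d)[seq_len(min(k, length(good)))]], 1e-9)
    wts <- wts / sum(wts)
    epoch[ch, ] <- colSums(epoch[nn, , drop = FALSE] * wts)
  }
  epoch
}

#' Reject trials with too many contaminated channels
#'
#' A trial survives only if its contaminated-channel fraction is at most
#' the configured 35%; strictly more is rejected.
#'
#' @param epochs an `epoch_set`
#' @param masks list of per-epoch logical channel masks
#' @param cfg a [preproc_config()]
#' @return filtered `epoch_set`; attributes `n_rejected` and `kept` (index)
#' @export
reject_bad_trials <- function(epochs, masks, cfg = preproc_config()) {
  frac <- vapply(masks, mean, numeric(1))
  keep <- which(frac <= cfg$bad_channel_trial_fraction)
  out <- subset_epochs(epochs, keep)
  attr(out, "n_rejected") <- length(masks) - length(keep)
  attr(out, "kept") <- keep
  out
}

#' Temporal smoothing of high-amplitude excursions
#'
#' Samples whose absolute voltage exceeds the +/-120 uV threshold are
#' replaced by a local moving average (default 5 samples, edges reflected)
#' of the signal clipped to the threshold; all other samples are untouched.
#' The replacement magnitude never exceeds the threshold, so the operation
#' is exactly idempotent, and local deviations are damped without touching
#' the rest of the signal.
#'
#' @param epoch channels x samples matrix
#' @param cfg a [preproc_config()]
#' @return smoothed epoch
#' @export
smooth_high_amplitude <- function(epoch, cfg = preproc_config()) {
  thr <- cfg$smoothing_threshold_uv
  over <- abs(epoch) > thr
  if (!any(over)) return(epoch)
  w <- cfg$smoothing_window_samples
  half <- w %/% 2
  clipped <- pmin(pmax(epoch, -thr), thr)
  n <- ncol(epoch)
  # reflected-edge moving average along time, vectorised over channels
  ext <- clipped[, c(rev(seq_len(half) + 1L), seq_len(n),
                     n - seq_len(half)), drop = FALSE]
  csum <- cbind(0, t(apply(ext, 1, cumsum)))
  sm <- (csum[, (w + 1):(n + w), drop = FALSE] -
           csum[, 1:n, drop = FALSE]) / w
  epoch[over] <- sm[over]
  epoch
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and epoch, the mean over the pre-stimulus
#' interval (samples with timestamps in `[-150, 0)` ms — half-open at
#' target onset).
#'
#' @param epochs an `epoch_set` (or a single channels x samples matrix with
#'   a `times` argument)
#' @param cfg a [preproc_config()]
#' @param times time axis when `epochs` is a bare matrix
#' @return same type as input, baseline-corrected
#' @export
baseline_correct <- function(epochs, cfg = preproc_config(), times = NULL) {
  bl <- cfg$baseline_window_ms
  correct_one <- function(m, tms) {
    idx <- which(tms >= bl[1] & tms < bl[2])
    m - rowMeans(m[, idx, drop = FALSE])
  }
  if (is.matrix(epochs)) return(correct_one(epochs, times))
  for (i in seq_len(dim(epochs$data)[1]))
    epochs$data[i, , ] <- correct_one(epochs$data[i, , ], epochs$times)
  epochs
}

#' Run the full preprocessing chain
#'
#' Stages, in order: average re-reference, zero-phase band-pass filtering,
#' (for continuous input) epoch segmentation, look-away rejection,
#' per-epoch contaminated-channel detection and interpolation, rejection of
#' trials with >35% contaminated channels, +/-120 uV temporal smoothing,
#' and baseline correction. The +/-400 uV screen runs once per epoch,
#' before interpolation, in a single pass.
#'
#' A subject lacking at least `min_trials_per_condition` surviving trials in
#' any of the six category x cue conditions is flagged `excluded`.
#'
#' @param dataset an `epoch_set`, or a list with `data`, `srate_hz`,
#'   `channel_names`, `events` as from [read_continuous_dataset()]
#' @param cfg a [preproc_config()]
#' @param montage electrode table matching the channels
#' @return list with `epochs` (cleaned `epoch_set`) and `qc` (a `qc_report`:
#'   per-stage counts, per-epoch bad-channel lists, interpolation log,
#'   smoothed-sample count, surviving counts per condition, `excluded` flag)
#' @export
run_preprocessing <- function(dataset, cfg = preproc_config(),
                              montage = synthetic_montage()) {
  if (inherits(dataset, "epoch_set")) {
    epochs <- dataset
    for (i in seq_len(dim(epochs$data)[1])) {
      ep <- rereference_to_average(epochs$data[i, , ])
      epochs$data[i, , ] <- bandpass_filter(ep, cfg)
    }
  } else {
    cont <- rereference_to_average(dataset$data)
    cont <- bandpass_filter(cont, cfg)
    epochs <- segment_epochs(cont, dataset$events, cfg,
                             channel_names = dataset$channel_names)
    if (!is.null(dataset$events$trial_type) && is.null(epochs$labels$cue)) {
      parts <- strsplit(as.character(epochs$labels$trial_type), ".",
                        fixed = TRUE)
      epochs$labels$category <- vapply(parts, `[`, "", 1)
      epochs$labels$cue <- vapply(parts, `[`, "", 2)
    }
  }
  n_generated <- dim(epochs$data)[1]

  if (is.null(epochs$labels$lookaway)) epochs$labels$lookaway <- FALSE
  epochs <- reject_lookaway(epochs)
  n_lookaway <- attr(epochs, "n_rejected")

  masks <- lapply(seq_len(dim(epochs$data)[1]), function(i)
    detect_bad_channels(epochs$data[i, , ], cfg))
  interp_log <- lapply(masks, function(m) epochs$channel_names[m])
  for (i in seq_len(dim(epochs$data)[1])) {
    if (any(masks[[i]]) && !all(masks[[i]]))
      epochs$data[i, , ] <- interpolate_channels(epochs$data[i, , ],
                                                 masks[[i]], montage,
                                                 cfg$interp_k)
  }
  epochs <- reject_bad_trials(epochs, masks, cfg)
  n_bad <- attr(epochs, "n_rejected")
  kept <- attr(epochs, "kept")

  n_smoothed <- 0L
  for (i in seq_len(dim(epochs$data)[1])) {
    before <- epochs$data[i, , ]
    after <- smooth_high_amplitude(before, cfg)
    n_smoothed <- n_smoothed + sum(abs(before) > cfg$smoothing_threshold_uv)
    epochs$data[i, , ] <- after
  }
  epochs <- baseline_correct(epochs, cfg)

  conds <- c("face.valid", "face.nocue", "face.invalid",
             "flower.valid", "flower.nocue", "flower.invalid")
  surv <- table(factor(condition_label(epochs$labels), levels = conds))
  excluded <- any(surv < cfg$min_trials_per_condition)

  qc <- structure(list(
    subject_id = epochs$subject_id,
    n_generated = n_generated,
    n_lookaway_rejected = n_lookaway,
    n_trials_rejected = n_bad,
    n_surviving = dim(epochs$data)[1],
    surviving_per_condition = stats::setNames(as.integer(surv), conds),
    bad_channels_per_epoch = interp_log[kept],
    n_samples_smoothed = n_smoothed,
    excluded = excluded
  ), class = "qc_report")
  list(epochs = epochs, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report", if (!is.null(x$subject_id)) x$subject_id else "", "\n")
  cat("  generated:", x$n_generated,
      "| look-away:", x$n_lookaway_rejected,
      "| artifact-rejected:", x$n_trials_rejected,
      "| surviving:", x$n_surviving, "\n")
  print(x$surviving_per_condition)
  if (x$excluded) cat("  SUBJECT EXCLUDED (<2 trials in some condition)\n")
  invisible(x)
}
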