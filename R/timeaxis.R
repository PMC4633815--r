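#' Canonical epoch time axis
#'
#' Epochs are cut from -150 ms to +1700 ms around target onset at 250 Hz.
#' Because 1850 ms is not an integer multiple of the 4 ms sampling step, the
#' canonical axis holds 462 samples at \eqn{t_k = -150 + 4k} ms,
#' \eqn{k = 0, \dots, 461} (last sample 1694 ms). All window-to-sample
#' conversions in the package are inclusive on both ends at nearest-sample
#' resolution on this axis.
#'
#' @param srate_hz sampling rate in Hz (default 250)
#' @param tmin_ms,tmax_ms epoch limits in ms relative to target onset
#' @return numeric vector of sample times in ms
#' @export
epoch_times <- function(srate_hz = 250, tmin_ms = -150, tmax_ms = 1700) {
  step <- 1000 / srate_hz
  span <- tmax_ms - tmin_ms
  # inclusive end only when the span is an integer number of steps
  n <- if (span %% step == 0) span / step + 1L else floor(span / step)
  tmin_ms + step * (seq_len(n) - 1)
}

#' Map a time window to sample indices
#'
#' Returns the (1-based) indices of samples whose timestamps lie in
#' `[start_ms, end_ms]`, inclusive on both ends.
#'
#' @param times time axis in ms, as from [epoch_times()]
#' @param start_ms,end_ms window limits in ms
#' @return integer vector of indices
#' @export
window_indices <- function(times, start_ms, end_ms) {
  stopifnot(start_ms < end_ms)
  which(times >= start_ms & times <= end_ms)
}

#' Synthetic 128-electrode montage
#'
#' A synthetic stand-in for a high-density 128-electrode infant net: positions
#' are generated by a Fibonacci spiral over the upper hemisphere of a
#' unit sphere, so electrode density is approximately uniform over the scalp.
#' The nine occipito-temporal region-of-interest labels (TP9, P9, PO7, O1,
#' OZ, O2, PO8, P10, TP10) are assigned to the nine most posterior positions,
#' ordered left to right; remaining channels are named E1..E119. No
#' vendor coordinate file is used; geometry is synthetic but respects the
#' qualitative layout assumed by the ROI (a contiguous posterior cluster).
#'
#' @param n_channels number of electrodes (default 128)
#' @return data.frame with columns `name`, `x`, `y`, `z` (unit-sphere
#'   coordinates; +y is anterior, +z superior)
#' @export
synthetic_montage <- function(n_channels = 128) {
  stopifnot(n_channels >= 16)
  golden <- (1 + sqrt(5)) / 2
  k <- seq_len(n_channels)
  # upper hemisphere: z in (0, 1], azimuth by golden-angle increments
  z <- (k - 0.5) / n_channels
  r <- sqrt(1 - z^2)
  phi <- 2 * pi * k / golden
  pos <- data.frame(x = r * cos(phi), y = r * sin(phi), z = z)
  # nine most posterior (lowest y) electrodes form the ROI band
  roi_names <- c("TP9", "P9", "PO7", "O1", "OZ", "O2", "PO8", "P10", "TP10")
  ord <- order(pos$y)[1:9]
  ord <- ord[order(pos$x[ord])]  # left-to-right within the band
  nm <- rep(NA_character_, n_channels)
  nm[ord] <- roi_names
  nm[is.na(nm)] <- paste0("E", seq_len(n_channels - 9))
  data.frame(name = nm, pos, stringsAsFactors = FALSE)
}

#' Default occipito-temporal ROI electrode names
#' @export
roi_default_names <- function() {
  c("TP9", "P9", "PO7", "O1", "OZ", "O2", "PO8", "P10", "TP10")
}

# derive a per-subject RNG seed from a master seed; documented splitting rule
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.numeric(master_seed) + 10007 * as.numeric(subject_index)) %%
               .Machine$integer.max)
}
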