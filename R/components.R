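#' Occipito-temporal region of interest
#'
#' @param names electrode labels (default the nine occipito-temporal
#'   electrodes TP9, P9, PO7, O1, OZ, O2, PO8, P10, TP10)
#' @return object of class `roi_definition`
#' @export
roi_definition <- function(names = roi_default_names()) {
  if (length(names) == 0)
    stop("roi_definition: electrode list must be non-empty", call. = FALSE)
  structure(list(names = names), class = "roi_definition")
}

#' Component analysis windows
#'
#' The three windows used for amplitude extraction: the early positivity
#' ("P1", which folds in the putative N290) at 180-300 ms, the P400 at
#' 360-540 ms, and the late slow wave (LSW) at 860-1280 ms. Endpoints are
#' inclusive at nearest-sample resolution.
#'
#' @return data.frame with columns `component`, `start_ms`, `end_ms`,
#'   `polarity`
#' @export
component_windows <- function() {
  data.frame(
    component = c("P1", "P400", "LSW"),
    start_ms = c(180, 360, 860),
    end_ms = c(300, 540, 1280),
    polarity = c(1, 1, -1),
    stringsAsFactors = FALSE
  )
}

#' Average epochs into per-condition ERPs
#'
#' Simple arithmetic mean over surviving epochs for each of the six
#' category x cue cells. Cells with fewer than `min_trials` epochs are
#' flagged (`low_n` attribute) but still averaged if non-empty.
#'
#' @param epochs a cleaned `epoch_set`
#' @param min_trials flagging floor (default 2)
#' @return named list of channels x samples ERP matrices (one per non-empty
#'   condition), with attributes `n_trials` (named counts) and `low_n`
#' @export
average_epochs_by_condition <- function(epochs, min_trials = 2L) {
  cond <- condition_label(epochs$labels)
  out <- list()
  n_trials <- integer(0)
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    out[[cc]] <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    n_trials[cc] <- length(idx)
  }
  attr(out, "n_trials") <- n_trials
  attr(out, "low_n") <- names(n_trials)[n_trials < min_trials]
  out
}

#' ROI time series from an ERP
#'
#' Unweighted mean over the ROI channels.
#'
#' @param erp channels x samples matrix
#' @param roi a [roi_definition()]
#' @param channel_names labels matching the ERP's rows
#' @return numeric vector (one value per sample)
#' @export
roi_average <- function(erp, roi, channel_names) {
  idx <- match(roi$names, channel_names)
  if (anyNA(idx))
    stop("roi_average: ROI electrode(s) not in montage: ",
         paste(roi$names[is.na(idx)], collapse = ", "), call. = FALSE)
  colMeans(erp[idx, , drop = FALSE])
}

#' Mean amplitude in a component window
#'
#' Mean of the samples whose timestamps lie in `[start_ms, end_ms]`,
#' inclusive on both ends at nearest-sample resolution.
#'
#' @param series numeric vector (ROI time series)
#' @param window one row of [component_windows()] (or a list with
#'   `start_ms`, `end_ms`)
#' @param times time axis in ms
#' @return mean amplitude in uV
#' @export
extract_window_mean <- function(series, window, times = epoch_times()) {
  idx <- window_indices(times, window$start_ms, window$end_ms)
  mean(series[idx])
}

#' Build the subject x condition x component amplitude table
#'
#' For each subject's per-condition ERPs, averages the ROI channels and
#' extracts the three window-mean amplitudes. With `invert_lsw = TRUE`
#' (the default, as used for the omnibus ANOVA) LSW values are multiplied
#' by -1 so the negative component can be compared directly with the
#' positive ones; the flag is recorded in the `sign_inverted_lsw` attribute.
#'
#' @param erps_by_subject named list (one element per subject) of
#'   per-condition ERP lists from [average_epochs_by_condition()]
#' @param roi a [roi_definition()]
#' @param channel_names montage channel labels
#' @param windows data.frame as [component_windows()]
#' @param invert_lsw flip the LSW sign (default TRUE)
#' @param times epoch time axis
#' @return data.frame with columns `subject`, `category`, `cue`,
#'   `component`, `amplitude_uv`; attribute `sign_inverted_lsw`
#' @export
build_amplitude_table <- function(erps_by_subject, roi, channel_names,
                                  windows = component_windows(),
                                  invert_lsw = TRUE,
                                  times = epoch_times()) {
  rows <- list()
  for (subj in names(erps_by_subject)) {
    erps <- erps_by_subject[[subj]]
    for (cc in names(erps)) {
      series <- roi_average(erps[[cc]], roi, channel_names)
      parts <- strsplit(cc, ".", fixed = TRUE)[[1]]
      for (w in seq_len(nrow(windows))) {
        amp <- extract_window_mean(series, windows[w, ], times)
        if (invert_lsw && windows$component[w] == "LSW") amp <- -amp
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, category = parts[1], cue = parts[2],
          component = windows$component[w], amplitude_uv = amp,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sign_inverted_lsw") <- invert_lsw
  out
}

#' Suggest component windows from a collapsed grand average
#'
#' Exploratory helper: finds local extrema of the across-condition ROI
#' grand average (after target onset) whose magnitude reaches at least
#' `min_fraction` of the series maximum, and proposes a window of
#' `half_width_ms` around each. Never overrides configured windows.
#'
#' @param series collapsed grand-average ROI time series
#' @param times time axis in ms
#' @param min_fraction extremum-magnitude floor relative to the global max
#' @param half_width_ms half-width of each suggested window
#' @return data.frame with `center_ms`, `start_ms`, `end_ms`, `polarity`
#'   (empty for flat input)
#' @export
find_component_windows <- function(series, times = epoch_times(),
                                   min_fraction = 0.3, half_width_ms = 100) {
  post <- which(times > 0)
  s <- series[post]
  t_post <- times[post]
  n <- length(s)
  if (n < 3 || max(abs(s)) < 1e-12)
    return(data.frame(center_ms = numeric(0), start_ms = numeric(0),
                      end_ms = numeric(0), polarity = numeric(0)))
  interior <- 2:(n - 1)
  is_max <- s[interior] >= s[interior - 1] & s[interior] >= s[interior + 1] &
    s[interior] > 0
  is_min <- s[interior] <= s[interior - 1] & s[interior] <= s[interior + 1] &
    s[interior] < 0
  cand <- interior[(is_max | is_min) &
                     abs(s[interior]) >= min_fraction * max(abs(s))]
  if (length(cand) == 0)
    return(data.frame(center_ms = numeric(0), start_ms = numeric(0),
                      end_ms = numeric(0), polarity = numeric(0)))
  # merge plateau/adjacent candidates of the same sign within the half-width
  centers <- t_post[cand]
  pol <- sign(s[cand])
  keepers <- rep(TRUE, length(cand))
  for (i in seq_along(cand)[-1]) {
    j <- max(which(keepers[seq_len(i - 1)]))
    if (pol[i] == pol[j] && centers[i] - centers[j] < half_width_ms) {
      if (abs(s[cand[i]]) > abs(s[cand[j]])) keepers[j] <- FALSE
      else keepers[i] <- FALSE
    }
  }
  data.frame(center_ms = centers[keepers],
             start_ms = centers[keepers] - half_width_ms,
             end_ms = centers[keepers] + half_width_ms,
             polarity = pol[keepers])
}
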