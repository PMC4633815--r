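#' ERP component kernel specification
#'
#' Forward model for the three components the analysis extracts, each a
#' Gaussian bump in time (truncated at +/- 3 sigma) with a condition-dependent
#' amplitude and a posterior-focused spatial profile:
#'
#' * **P1** — early positivity (window 180–300 ms); amplified on valid trials.
#' * **P400** — mid-latency positivity (360–540 ms); larger for faces and for
#'   cued (valid or invalid) than no-cue trials.
#' * **LSW** — late slow wave, a sustained negativity (860–1280 ms); larger in
#'   magnitude for faces and for invalid (surprising) targets.
#'
#' Amplitudes are in microvolts at the spatial-profile maximum. The spatial
#' profile is a Gaussian falloff with distance from the occipital (ROI)
#' centroid, width `spatial_sigma` in unit-sphere distance.
#'
#' `subject_sd_uv` adds per-subject, per-component amplitude jitter (drawn
#' once per subject in [simulate_subject_epochs()]), giving realistic
#' between-subject variability for the group statistics.
#'
#' @param p1_center_ms,p1_sigma_ms,p1_base_uv P1 latency, width, base amplitude
#' @param p1_valid_offset_uv P1 amplitude increase on valid trials
#' @param p400_center_ms,p400_sigma_ms,p400_base_uv P400 parameters
#' @param p400_face_offset_uv,p400_cued_offset_uv P400 increases for faces
#'   and for cued trials
#' @param lsw_center_ms,lsw_sigma_ms,lsw_base_uv LSW parameters
#'   (`lsw_base_uv` must be negative: the LSW is a negativity)
#' @param lsw_face_offset_uv,lsw_invalid_offset_uv LSW (negative) offsets for
#'   faces and for invalid trials
#' @param spatial_sigma spatial profile width (unit-sphere distance)
#' @param subject_sd_uv s.d. of per-subject amplitude jitter per component
#' @return object of class `erp_kernel_spec`
#' @export
erp_kernel_spec <- function(p1_center_ms = 240, p1_sigma_ms = 25,
                            p1_base_uv = 6, p1_valid_offset_uv = 3,
                            p400_center_ms = 450, p400_sigma_ms = 40,
                            p400_base_uv = 5, p400_face_offset_uv = 2,
                            p400_cued_offset_uv = 2,
                            lsw_center_ms = 1070, lsw_sigma_ms = 90,
                            lsw_base_uv = -5, lsw_face_offset_uv = -2,
                            lsw_invalid_offset_uv = -3,
                            spatial_sigma = 0.6,
                            subject_sd_uv = 1) {
  spec <- as.list(environment())
  class(spec) <- "erp_kernel_spec"
  validate_kernel_spec(spec)
  spec
}

validate_kernel_spec <- function(k) {
  if (k$lsw_base_uv >= 0)
    stop("erp_kernel_spec: the LSW is a negativity; `lsw_base_uv` must be < 0",
         call. = FALSE)
  if (k$p1_base_uv < 0 || k$p400_base_uv < 0)
    stop("erp_kernel_spec: P1 and P400 are positivities; base amplitudes ",
         "must be >= 0", call. = FALSE)
  win <- list(p1 = c(180, 300), p400 = c(360, 540), lsw = c(860, 1280))
  ctr <- c(p1 = k$p1_center_ms, p400 = k$p400_center_ms, lsw = k$lsw_center_ms)
  for (nm in names(win)) {
    if (ctr[[nm]] < win[[nm]][1] || ctr[[nm]] > win[[nm]][2])
      stop("erp_kernel_spec: ", toupper(nm), " latency ", ctr[[nm]],
           " ms falls outside its analysis window [", win[[nm]][1], ", ",
           win[[nm]][2], "] ms", call. = FALSE)
  }
  invisible(k)
}

#' Noise and artifact specification
#'
#' Background activity is 1/f ("pink") Gaussian noise, synthesized per
#' channel by spectral shaping of white noise, scaled to a target RMS.
#' Artifacts are sporadic high-amplitude transients: with probability
#' `p_artifact` a trial receives an artifact; a "large" artifact (probability
#' `p_large_given_artifact`) hits enough channels above the 400-uV rejection
#' threshold that the trial fails the 35% contaminated-channel rule, while a
#' "small" artifact hits a few channels in a range straddling the 120 uV
#' smoothing and 400 uV rejection thresholds, exercising interpolation and
#' smoothing without losing the trial. Look-away behaviour is a Bernoulli
#' flag per trial.
#'
#' Defaults are calibrated to the study's bookkeeping: 90 test trials with
#' `p_lookaway = 22.2/90` and a large-artifact trial-rejection probability of
#' `0.25 * 0.25 = 0.0625` give an expected 63.6 surviving trials per subject.
#'
#' @param noise_rms_uv background RMS per channel in uV
#' @param noise_exponent 1/f power-spectrum exponent
#' @param p_artifact per-trial artifact probability
#' @param p_large_given_artifact probability an artifact is trial-fatal
#' @param small_channels,large_channels integer ranges of affected channels
#' @param small_amp_uv,large_amp_uv artifact peak-amplitude ranges (uV)
#' @param p_lookaway per-trial look-away probability
#' @return object of class `noise_artifact_spec`
#' @export
noise_artifact_spec <- function(noise_rms_uv = 10,
                                noise_exponent = 1,
                                p_artifact = 0.25,
                                p_large_given_artifact = 0.25,
                                small_channels = c(2L, 12L),
                                large_channels = c(48L, 90L),
                                small_amp_uv = c(150, 390),
                                large_amp_uv = c(420, 700),
                                p_lookaway = 22.2 / 90) {
  spec <- as.list(environment())
  class(spec) <- "noise_artifact_spec"
  for (p in c("p_artifact", "p_large_given_artifact", "p_lookaway")) {
    v <- spec[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("noise_artifact_spec: `", p, "` must be in [0, 1]", call. = FALSE)
  }
  if (any(c(spec$small_amp_uv, spec$large_amp_uv) <= 0))
    stop("noise_artifact_spec: amplitude ranges must be positive",
         call. = FALSE)
  spec
}

# Gaussian bump truncated at +/-3 sigma, unit peak
gauss_bump <- function(times, center, sigma) {
  g <- exp(-(times - center)^2 / (2 * sigma^2))
  g[abs(times - center) > 3 * sigma] <- 0
  g
}

# spatial weight per channel: Gaussian falloff from the ROI centroid
kernel_spatial_weights <- function(kspec, montage) {
  roi <- montage[montage$name %in% roi_default_names(), c("x", "y", "z")]
  ctr <- colMeans(roi)
  d2 <- (montage$x - ctr[1])^2 + (montage$y - ctr[2])^2 +
    (montage$z - ctr[3])^2
  exp(-d2 / (2 * kspec$spatial_sigma^2))
}

# component amplitudes (uV) for one trial's condition labels
component_amplitudes <- function(kspec, cue, category) {
  c(
    p1 = kspec$p1_base_uv + if (cue == "valid") kspec$p1_valid_offset_uv else 0,
    p400 = kspec$p400_base_uv +
      (category == "face") * kspec$p400_face_offset_uv +
      (cue != "nocue") * kspec$p400_cued_offset_uv,
    lsw = kspec$lsw_base_uv +
      (category == "face") * kspec$lsw_face_offset_uv +
      (cue == "invalid") * kspec$lsw_invalid_offset_uv
  )
}

#' Noise-free ERP waveform for one condition
#'
#' Deterministic forward model: the sum of the three component bumps with
#' condition-dependent amplitudes, projected over channels by the spatial
#' profile.
#'
#' @param kspec an [erp_kernel_spec()]
#' @param cue one of `"valid"`, `"invalid"`, `"nocue"`
#' @param category `"face"` or `"flower"`
#' @param montage electrode table from [synthetic_montage()]
#' @param times epoch time axis in ms, default [epoch_times()]
#' @param amp_jitter optional named numeric (`p1`, `p400`, `lsw`) added to
#'   the component amplitudes (per-subject variability)
#' @return channels x samples matrix in uV
#' @export
simulate_erp_kernel <- function(kspec, cue, category, montage,
                                times = epoch_times(), amp_jitter = NULL) {
  stopifnot(cue %in% c("valid", "invalid", "nocue"),
            category %in% c("face", "flower"))
  validate_kernel_spec(kspec)
  if (kspec$p1_center_ms < min(times) || kspec$lsw_center_ms > max(times))
    stop("simulate_erp_kernel: component latency outside the epoch",
         call. = FALSE)
  amp <- component_amplitudes(kspec, cue, category)
  if (!is.null(amp_jitter)) amp <- amp + amp_jitter[names(amp)]
  series <- amp[["p1"]] * gauss_bump(times, kspec$p1_center_ms, kspec$p1_sigma_ms) +
    amp[["p400"]] * gauss_bump(times, kspec$p400_center_ms, kspec$p400_sigma_ms) +
    amp[["lsw"]] * gauss_bump(times, kspec$lsw_center_ms, kspec$lsw_sigma_ms)
  w <- kernel_spatial_weights(kspec, montage)
  outer(w, series)
}

# 1/f Gaussian noise, channels x samples, via spectral shaping of white noise
pink_noise <- function(n_channels, n_samples, rms_uv, exponent, srate_hz = 250) {
  if (rms_uv <= 0) return(matrix(0, n_channels, n_samples))
  white <- matrix(stats::rnorm(n_channels * n_samples), n_samples, n_channels)
  k <- 0:(n_samples - 1)
  freqs <- pmin(k, n_samples - k) * srate_hz / n_samples  # symmetric FFT bins
  shape <- ifelse(freqs > 0, freqs^(-exponent / 2), 0)  # DC removed
  shaped <- Re(stats::mvfft(stats::mvfft(white) * shape, inverse = TRUE))
  # scale each channel to the target RMS; return channels x samples
  sds <- sqrt(colMeans(shaped^2))
  t(shaped) / sds * rms_uv
}

#' Simulate one subject's epoched EEG
#'
#' One epoch per design trial: condition kernel + 1/f background noise +
#' (possibly) an injected high-amplitude artifact transient. Look-away trials
#' are flagged in the QC labels (set `drop_lookaway = TRUE` to omit their
#' epochs instead). Per-subject component-amplitude jitter
#' (`kspec$subject_sd_uv`) is drawn once from the subject's seed, so the
#' whole array is reproducible given (design, specs, seed).
#'
#' @param design a [generate_session_design()] result
#' @param kspec an [erp_kernel_spec()]
#' @param nspec a [noise_artifact_spec()]
#' @param seed integer RNG seed for noise/artifact/look-away draws
#' @param montage electrode table (default [synthetic_montage()])
#' @param drop_lookaway omit epochs for look-away trials (default FALSE)
#' @return object of class `epoch_set`: list with `data`
#'   (trials x channels x samples array, uV), `channel_names`, `srate_hz`,
#'   `times`, and `labels` (data.frame: `block`, `trial`, `cue`, `category`,
#'   `duration_ms`, `lookaway`)
#' @export
simulate_subject_epochs <- function(design, kspec, nspec, seed,
                                    montage = synthetic_montage(),
                                    drop_lookaway = FALSE) {
  validate_kernel_spec(kspec)
  times <- epoch_times()
  n_ch <- nrow(montage)
  n_s <- length(times)
  trials <- design$trials
  set.seed(seed)

  amp_jitter <- stats::rnorm(3, 0, kspec$subject_sd_uv)
  names(amp_jitter) <- c("p1", "p400", "lsw")
  lookaway <- stats::runif(nrow(trials)) < nspec$p_lookaway
  if (drop_lookaway) {
    trials <- trials[!lookaway, , drop = FALSE]
    lookaway <- lookaway[!lookaway]
  }
  n_tr <- nrow(trials)

  # cache the six condition kernels (jittered) rather than recomputing
  kcache <- list()
  kernel_for <- function(cue, category) {
    key <- paste(cue, category)
    if (is.null(kcache[[key]]))
      kcache[[key]] <<- simulate_erp_kernel(kspec, cue, category, montage,
                                            times, amp_jitter)
    kcache[[key]]
  }

  dat <- array(0, dim = c(n_tr, n_ch, n_s))
  for (i in seq_len(n_tr)) {
    ep <- kernel_for(trials$cue[i], trials$category[i]) +
      pink_noise(n_ch, n_s, nspec$noise_rms_uv, nspec$noise_exponent)
    if (stats::runif(1) < nspec$p_artifact) {
      large <- stats::runif(1) < nspec$p_large_given_artifact
      rng_ch <- if (large) nspec$large_channels else nspec$small_channels
      rng_amp <- if (large) nspec$large_amp_uv else nspec$small_amp_uv
      n_aff <- min(sample(rng_ch[1]:rng_ch[2], 1), n_ch)
      chans <- sample(n_ch, n_aff)
      center <- stats::runif(1, min(times) + 100, max(times) - 100)
      bump <- gauss_bump(times, center, 20)
      amps <- stats::runif(n_aff, rng_amp[1], rng_amp[2]) *
        sample(c(-1, 1), n_aff, replace = TRUE)
      ep[chans, ] <- ep[chans, , drop = FALSE] + outer(amps, bump)
    }
    dat[i, , ] <- ep
  }

  labels <- trials[, c("block", "trial", "cue", "category", "duration_ms")]
  labels$lookaway <- lookaway
  rownames(labels) <- NULL
  structure(list(data = dat, channel_names = montage$name, srate_hz = 250,
                 times = times, labels = labels,
                 subject_id = design$subject_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("epoch_set:", d[1], "epochs x", d[2], "channels x", d[3], "samples @",
      x$srate_hz, "Hz\n")
  print(table(condition = condition_label(x$labels)))
  invisible(x)
}

#' Expected surviving-trial calibration check
#'
#' Fast count-level simulation (no waveforms): draws sessions, applies the
#' Bernoulli look-away and large-artifact trial-rejection models, and
#' returns the mean surviving count per condition across subjects. Used to
#' verify that the generator defaults track the per-condition calibration
#' targets.
#'
#' @param n_subjects number of simulated subjects
#' @param spec a [design_spec()]
#' @param nspec a [noise_artifact_spec()]
#' @param seed RNG seed
#' @return named numeric: mean surviving trials for each of the six
#'   category x cue conditions, plus `total`
#' @export
simulate_surviving_counts <- function(n_subjects = 100, spec = design_spec(),
                                      nspec = noise_artifact_spec(),
                                      seed = 1) {
  conds <- c("face.valid", "face.nocue", "face.invalid",
             "flower.valid", "flower.nocue", "flower.invalid")
  acc <- stats::setNames(numeric(6), conds)
  p_reject <- nspec$p_artifact * nspec$p_large_given_artifact
  for (s in seq_len(n_subjects)) {
    des <- generate_session_design(spec, seed = subject_seed(seed, s))
    set.seed(subject_seed(seed, s) + 1L)
    n <- nrow(des$trials)
    keep <- stats::runif(n) >= nspec$p_lookaway &
      stats::runif(n) >= p_reject
    tab <- table(factor(condition_label(des$trials[keep, ]), levels = conds))
    acc <- acc + as.numeric(tab)
  }
  out <- acc / n_subjects
  c(out, total = sum(out))
}

#' Printed per-condition calibration targets
#'
#' The mean artifact-free epoch counts per condition that the generator
#' defaults are calibrated against (overall mean 63.6 trials per subject).
#' @return named numeric vector of six means
#' @export
calibration_targets <- function() {
  c(face.valid = 15.82, face.nocue = 10.43, face.invalid = 5.43,
    flower.valid = 16.04, flower.nocue = 10.39, flower.invalid = 5.5)
}
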