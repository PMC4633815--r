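test_that("average re-referencing zeroes the channel mean at every sample", {
  x <- matrix(5, 4, 20)
  expect_true(all(rereference_to_average(x) == 0))
  set.seed(71)
  y <- matrix(rnorm(6 * 50), 6, 50)
  yr <- rereference_to_average(y)
  expect_true(all(abs(colMeans(yr)) < 1e-12))
  # two channels (a, b) -> ((a-b)/2, (b-a)/2)
  ab <- matrix(rnorm(2 * 30), 2, 30)
  r <- rereference_to_average(ab)
  expect_equal(r[1, ], (ab[1, ] - ab[2, ]) / 2)
  expect_equal(r[2, ], (ab[2, ] - ab[1, ]) / 2)
  expect_error(rereference_to_average(matrix(1, 1, 10)), "2 channels")
})

test_that("band-pass filter has the documented gain profile", {
  cfg <- preproc_config()
  tt <- seq(0, 9.996, by = 0.004)
  mid <- 500:2000
  # DC attenuated toward zero
  dc <- bandpass_filter(matrix(7, 1, length(tt)), cfg)
  expect_lt(max(abs(dc)), 1e-10)
  # 10 Hz passband ~unity, 40 Hz strongly attenuated (FFT amplitude oracle)
  fft_amp <- function(x, fr) {
    n <- length(x)
    2 * abs(fft(x))[round(fr * n * 0.004) + 1] / n
  }
  for (fr in c(10, 40)) {
    x <- sin(2 * pi * fr * tt)
    y <- bandpass_filter(matrix(x, 1), cfg)[1, ]
    ratio <- fft_amp(y[mid], fr) / fft_amp(x[mid], fr)
    if (fr == 10) expect_true(ratio > 0.9 && ratio < 1.1)
    else expect_lt(ratio, 0.2)
  }
  expect_error(bandpass_filter(matrix(0, 2, 10), cfg), "short")
})

test_that("epoch segmentation maps events to the canonical axis", {
  cfg <- preproc_config()
  n_ch <- 3
  cont <- matrix(rnorm(n_ch * 3000), n_ch)
  ev <- data.frame(onset_s = c(1, 6), trial_type = c("face.valid",
                                                     "flower.nocue"))
  eps <- segment_epochs(cont, ev, cfg)
  expect_equal(dim(eps$data), c(2, n_ch, 462))
  # event at sample s -> epoch first sample s - 37
  s <- round(1 * 250) + 1
  expect_equal(eps$data[1, , 1], cont[, s - 37])
  expect_equal(eps$data[1, , 462], cont[, s - 37 + 461])
  # zero events -> empty epoch set
  e0 <- segment_epochs(cont, data.frame(onset_s = numeric(0)), cfg)
  expect_equal(dim(e0$data)[1], 0)
  # events at the edge are skipped with a warning
  expect_warning(
    e1 <- segment_epochs(cont, data.frame(onset_s = c(0.05, 2)), cfg),
    "skipped")
  expect_equal(dim(e1$data)[1], 1)
})

test_that("look-away rejection filters exactly the flagged epochs", {
  dat <- array(seq_len(5 * 2 * 462), c(5, 2, 462))
  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  eps <- make_epoch_set(dat, labels = data.frame(
    block = 1, trial = 1:5, cue = "valid", category = "face",
    duration_ms = 100, lookaway = flags))
  out <- reject_lookaway(eps)
  expect_equal(attr(out, "n_rejected"), 2)
  expect_equal(out$data, dat[!flags, , , drop = FALSE])  # brute-force filter
  # all-false -> identity; all-true -> empty
  eps$labels$lookaway <- FALSE
  expect_equal(dim(reject_lookaway(eps)$data)[1], 5)
  eps$labels$lookaway <- TRUE
  expect_equal(dim(reject_lookaway(eps)$data)[1], 0)
})

test_that("bad-channel detection applies both voltage rules strictly", {
  cfg <- preproc_config()
  ep <- matrix(0, 4, 462)
  expect_equal(detect_bad_channels(ep, cfg), rep(FALSE, 4))
  # one sample at +401 uV -> flagged; at exactly 400 -> not (strict)
  ep[2, 100] <- 401
  ep[3, 200] <- 400
  expect_equal(detect_bad_channels(ep, cfg), c(FALSE, TRUE, FALSE, FALSE))
  # step 0 -> 401 within 10 samples, |v| <= 401: deviation rule fires
  ep2 <- matrix(0, 2, 462)
  ep2[1, 240:462] <- 401 / 2
  ep2[1, 1:239] <- -401 / 2  # step of 401 within any window straddling 239/240
  mask <- detect_bad_channels(ep2, cfg)
  expect_true(mask[1] && !mask[2])
  # brute-force sliding-window oracle on random data near threshold
  set.seed(72)
  ep3 <- matrix(rnorm(6 * 462, sd = 150), 6, 462)
  brute <- vapply(seq_len(6), function(ch) {
    v <- ep3[ch, ]
    pp <- vapply(1:(462 - 9), function(i) diff(range(v[i:(i + 9)])),
                 numeric(1))
    max(abs(v)) > 400 || max(pp) > 400
  }, logical(1))
  expect_equal(detect_bad_channels(ep3, cfg), brute)
})

test_that("interpolation replaces flagged channels by weighted neighbours", {
  ep <- matrix(rnorm(3 * 50), 3, 50)
  # empty mask -> bit-identical
  expect_identical(interpolate_channels(ep, rep(FALSE, 3), line_montage()),
                   ep)
  # flagged middle channel equidistant from both neighbours -> (a+b)/2
  out <- interpolate_channels(ep, c(FALSE, TRUE, FALSE), line_montage())
  expect_equal(out[2, ], (ep[1, ] + ep[3, ]) / 2)
  expect_identical(out[c(1, 3), ], ep[c(1, 3), ])  # untouched channels
  # arbitrary geometry, k = 3: inverse-distance oracle
  set.seed(73)
  m <- synthetic_montage(20)
  ep2 <- matrix(rnorm(20 * 30), 20, 30)
  mask <- rep(FALSE, 20); mask[5] <- TRUE
  got <- interpolate_channels(ep2, mask, m, k = 3)
  pos <- as.matrix(m[, c("x", "y", "z")])
  d <- sqrt(colSums((t(pos[-5, ]) - pos[5, ])^2))
  good <- setdiff(1:20, 5)
  nn <- good[order(d)][1:3]
  wts <- 1 / sort(d)[1:3]; wts <- wts / sum(wts)
  expect_equal(got[5, ], colSums(ep2[nn, ] * wts))
  expect_error(interpolate_channels(ep2, rep(TRUE, 20), m), "reject")
})

test_that("trial rejection uses the strict >35% contaminated rule", {
  dat <- array(0, c(3, 128, 462))
  eps <- make_epoch_set(dat, labels = data.frame(
    block = 1, trial = 1:3, cue = "valid", category = "face",
    duration_ms = 100, lookaway = FALSE))
  masks <- list(
    c(rep(TRUE, 45), rep(FALSE, 83)),   # 35.2% -> rejected
    c(rep(TRUE, 44), rep(FALSE, 84)),   # 34.4% -> kept
    rep(FALSE, 128))                    # clean -> kept
  out <- reject_bad_trials(eps, masks, preproc_config())
  expect_equal(attr(out, "n_rejected"), 1)
  expect_equal(attr(out, "kept"), c(2, 3))
})

test_that("high-amplitude smoothing is local, bounded and idempotent", {
  cfg <- preproc_config()
  # everything within +/-119 uV -> identity
  set.seed(74)
  ep <- matrix(runif(2 * 462, -119, 119), 2, 462)
  expect_identical(smooth_high_amplitude(ep, cfg), ep)
  # single 300 uV spike on a flat background
  ep2 <- matrix(0, 1, 462)
  ep2[1, 231] <- 300
  sm <- smooth_high_amplitude(ep2, cfg)
  expect_lt(abs(sm[1, 231]), 300)
  # moving-average oracle: mean of the clipped 5-sample window
  expect_equal(sm[1, 231], 120 / 5)
  expect_equal(sm[1, -231], ep2[1, -231])  # everything else untouched
  # idempotence
  ep3 <- matrix(rnorm(3 * 462, sd = 80), 3, 462)
  once <- smooth_high_amplitude(ep3, cfg)
  expect_equal(smooth_high_amplitude(once, cfg), once, tolerance = 1e-12)
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  cfg <- preproc_config()
  times <- epoch_times()
  bl <- which(times >= -150 & times < 0)
  # constant offset -> all zeros
  eps <- make_epoch_set(array(3.5, c(2, 4, 462)))
  out <- baseline_correct(eps, cfg)
  expect_true(all(out$data == 0))
  # random epochs -> pre-onset mean 0 within 1e-12, and idempotent
  set.seed(75)
  eps2 <- make_epoch_set(array(rnorm(2 * 4 * 462), c(2, 4, 462)))
  out2 <- baseline_correct(eps2, cfg)
  for (i in 1:2)
    expect_true(all(abs(rowMeans(out2$data[i, , bl])) < 1e-12))
  expect_equal(baseline_correct(out2, cfg)$data, out2$data,
               tolerance = 1e-12)
})

test_that("the full chain conserves counts and passes clean data untouched", {
  m <- synthetic_montage(32)
  des <- generate_session_design(design_spec(n_blocks = 4), seed = 76)
  clean <- noise_artifact_spec(noise_rms_uv = 3, p_artifact = 0,
                               p_lookaway = 0)
  eps <- simulate_subject_epochs(des, erp_kernel_spec(), clean, seed = 77,
                                 montage = m)
  pp <- run_preprocessing(eps, preproc_config(), m)
  expect_equal(pp$qc$n_lookaway_rejected, 0)
  expect_equal(pp$qc$n_trials_rejected, 0)
  expect_equal(pp$qc$n_surviving, nrow(des$trials))
  expect_false(pp$qc$excluded)
  # count conservation with artifacts and look-away on
  dirty <- noise_artifact_spec()
  eps2 <- simulate_subject_epochs(des, erp_kernel_spec(), dirty, seed = 78,
                                  montage = m)
  pp2 <- run_preprocessing(eps2, preproc_config(), m)
  expect_equal(pp2$qc$n_lookaway_rejected + pp2$qc$n_trials_rejected +
                 pp2$qc$n_surviving, pp2$qc$n_generated)
  expect_equal(sum(pp2$qc$surviving_per_condition), pp2$qc$n_surviving)
})

test_that("subjects lacking two trials in any condition are excluded", {
  m <- synthetic_montage(32)
  # tiny session: with only one block, some of the six cells must be < 2
  des <- generate_session_design(design_spec(n_blocks = 1), seed = 79)
  eps <- simulate_subject_epochs(des, erp_kernel_spec(),
                                 noise_artifact_spec(p_lookaway = 0,
                                                     p_artifact = 0),
                                 seed = 80, montage = m)
  pp <- run_preprocessing(eps, preproc_config(), m)
  expect_true(pp$qc$excluded)
})
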