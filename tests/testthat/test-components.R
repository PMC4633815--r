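test_that("condition averaging is the arithmetic epoch mean", {
  set.seed(81)
  dat <- array(rnorm(6 * 3 * 462), c(6, 3, 462))
  labels <- data.frame(block = 1, trial = 1:6,
                       cue = c("valid", "valid", "invalid", "nocue",
                               "nocue", "nocue"),
                       category = "face", duration_ms = 100, lookaway = FALSE)
  eps <- make_epoch_set(dat, labels = labels)
  erps <- average_epochs_by_condition(eps)
  # single-epoch condition equals that epoch; two epochs -> (a+b)/2
  expect_equal(erps[["face.invalid"]], dat[3, , ])
  expect_equal(erps[["face.valid"]], (dat[1, , ] + dat[2, , ]) / 2)
  # brute-force mean oracle
  expect_equal(erps[["face.nocue"]], apply(dat[4:6, , ], c(2, 3), mean))
  expect_equal(attr(erps, "low_n"), "face.invalid")
})

test_that("ROI averaging is the unweighted channel mean", {
  m <- synthetic_montage(32)
  roi <- roi_definition()
  set.seed(82)
  erp <- matrix(rnorm(32 * 462), 32, 462)
  idx <- match(roi$names, m$name)
  expect_equal(roi_average(erp, roi, m$name), colMeans(erp[idx, ]))
  # single-channel ROI returns that channel
  expect_equal(roi_average(erp, roi_definition("OZ"), m$name),
               erp[match("OZ", m$name), ])
  # all-equal channels -> the common series
  erp2 <- matrix(rep(sin(1:462 / 20), each = 32), 32)
  expect_equal(roi_average(erp2, roi, m$name), sin(1:462 / 20))
  expect_error(roi_average(erp, roi_definition("NOPE"), m$name), "NOPE")
})

test_that("window means use inclusive nearest-sample endpoints", {
  times <- epoch_times()
  # the P1 window covers exactly 30 samples (182..298 ms on the axis)
  idx <- window_indices(times, 180, 300)
  expect_equal(length(idx), 30)
  expect_equal(idx, 84:113)  # 1-based; k = 83..112 on the 0-based axis
  # constant series -> that constant
  expect_equal(extract_window_mean(rep(2.5, 462),
                                   list(start_ms = 180, end_ms = 300), times),
               2.5)
  # linear ramp -> value at the window midpoint (within one sample's slope)
  ramp <- 0.01 * times
  got <- extract_window_mean(ramp, list(start_ms = 360, end_ms = 540), times)
  expect_lt(abs(got - 0.01 * 450), 0.01 * 4)
})

test_that("the amplitude table negates only LSW rows when the flag is on", {
  cohort <- small_cohort()
  roi <- roi_definition()
  raw <- build_amplitude_table(cohort$erps, roi, cohort$channel_names,
                               invert_lsw = FALSE)
  inv <- build_amplitude_table(cohort$erps, roi, cohort$channel_names,
                               invert_lsw = TRUE)
  expect_equal(nrow(raw), length(cohort$erps) * 2 * 3 * 3)
  expect_false(attr(raw, "sign_inverted_lsw"))
  expect_true(attr(inv, "sign_inverted_lsw"))
  is_lsw <- raw$component == "LSW"
  expect_equal(inv$amplitude_uv[is_lsw], -raw$amplitude_uv[is_lsw])
  expect_equal(inv$amplitude_uv[!is_lsw], raw$amplitude_uv[!is_lsw])
})

test_that("ROI window extraction commutes with epoch averaging", {
  # linearity: mean of window-means equals window-mean of the mean series
  cohort <- small_cohort()
  roi <- roi_definition()
  win <- list(start_ms = 360, end_ms = 540)
  series <- lapply(cohort$erps, function(e)
    roi_average(e[["face.valid"]], roi, cohort$channel_names))
  per_subject <- vapply(series, extract_window_mean, numeric(1), window = win)
  grand <- Reduce(`+`, series) / length(series)
  expect_equal(mean(per_subject), extract_window_mean(grand, win),
               tolerance = 1e-12)
})

test_that("grand averages recover the injected effect directions", {
  cohort <- small_cohort()
  roi <- roi_definition()
  tbl <- build_amplitude_table(cohort$erps, roi, cohort$channel_names,
                               invert_lsw = FALSE)
  cellmean <- function(comp, cue) mean(tbl$amplitude_uv[
    tbl$component == comp & tbl$cue == cue])
  expect_gt(cellmean("P1", "valid"), cellmean("P1", "invalid"))
  expect_lt(cellmean("LSW", "invalid"), cellmean("LSW", "valid"))
  # direction unchanged when the ROI shrinks or grows by a third
  m <- cohort$montage
  pos <- m[match(roi$names, m$name), c("x", "y", "z")]
  ctr <- colMeans(pos)
  d <- sqrt((m$x - ctr[1])^2 + (m$y - ctr[2])^2 + (m$z - ctr[3])^2)
  roi_small <- roi_definition(roi$names[order(d[match(roi$names, m$name)])][1:6])
  roi_big <- roi_definition(m$name[order(d)][1:12])
  for (r in list(roi_small, roi_big)) {
    t2 <- build_amplitude_table(cohort$erps, r, cohort$channel_names,
                                invert_lsw = FALSE)
    cm <- function(comp, cue) mean(t2$amplitude_uv[
      t2$component == comp & t2$cue == cue])
    expect_gt(cm("P1", "valid"), cm("P1", "invalid"))
    expect_lt(cm("LSW", "invalid"), cm("LSW", "valid"))
  }
})

test_that("window suggestion finds the grand-average extrema", {
  times <- epoch_times()
  syn <- 5 * exp(-(times - 240)^2 / (2 * 30^2)) +
    4 * exp(-(times - 450)^2 / (2 * 40^2)) -
    6 * exp(-(times - 1000)^2 / (2 * 80^2))
  sug <- find_component_windows(syn, times)
  expect_equal(nrow(sug), 3)
  for (ctr in c(240, 450, 1000))
    expect_true(any(sug$start_ms <= ctr & sug$end_ms >= ctr))
  expect_equal(sug$polarity, c(1, 1, -1))
  # flat input -> no candidates; single bump -> one candidate
  expect_equal(nrow(find_component_windows(rep(0, 462), times)), 0)
  one <- find_component_windows(3 * exp(-(times - 500)^2 / (2 * 50^2)), times)
  expect_equal(nrow(one), 1)
})
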