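make_recording <- function(x, y = x, pupil = 1200) {
  n <- length(x)
  df <- data.frame(time_ms = 0:(n - 1), xL_deg = x, yL_deg = y,
                   pupilL = rep_len(pupil, n), xR_deg = x, yR_deg = y,
                   pupilR = rep_len(pupil, n))
  attr(df, "sampling_rate") <- 1000
  class(df) <- c("gaze_recording", "data.frame")
  df
}

sine <- function(f, n = 4000, fs = 1000) sin(2 * pi * f * (0:(n - 1)) / fs)

test_that("the low-pass filter has the stated frequency response", {
  ## DC gain 1
  rec <- make_recording(rep(0.7, 3000))
  expect_equal(lowpass_filter(rec)$xL_deg, rep(0.7, 3000), tolerance = 1e-9)
  ## 5 Hz passes with < 1% amplitude loss and zero phase shift
  s5 <- sine(5)
  out5 <- lowpass_filter(make_recording(s5))$xL_deg
  core <- 501:3500
  fit <- stats::coef(stats::lm(out5[core] ~ s5[core] + cos(2 * pi * 5 * (core - 1) / 1000)))
  expect_equal(unname(fit[2]), 1, tolerance = 0.01)   # in-phase gain
  expect_lt(abs(unname(fit[3])), 0.01)                # quadrature leak
  ## 200 Hz is attenuated below 5%
  s200 <- sine(200)
  out200 <- lowpass_filter(make_recording(s200))$xL_deg
  expect_lt(max(abs(out200[core])), 0.05)
  ## cutoffs at or above Nyquist are rejected
  expect_error(lowpass_filter(make_recording(s5), cutoff = 500), "Nyquist")
})

test_that("filtering is idempotent for band-limited signals", {
  x <- sine(4) + 0.5 * sine(11) + 0.2 * sine(23)
  once <- lowpass_filter(make_recording(x))$xL_deg
  twice <- lowpass_filter(make_recording(once))$xL_deg
  expect_lt(sqrt(mean((twice - once)^2)) / sqrt(mean(once^2)), 0.01)
})

test_that("the zero-phase response matches forward-backward Butterworth filtering", {
  skip_if_not_installed("signal")
  set.seed(1)
  x <- cumsum(rnorm(6000, 0, 0.003))
  mine <- lowpass_filter(make_recording(x))$xL_deg
  bf <- signal::butter(4, 60 / 500, type = "low")
  ref <- signal::filtfilt(bf, x)
  core <- 301:5700          # away from edge transients
  expect_gt(stats::cor(mine[core], ref[core]), 0.9999)
  expect_lt(sqrt(mean((mine[core] - ref[core])^2)) /
              sqrt(mean(ref[core]^2)), 0.02)
})

test_that("missing spans survive filtering untouched and pupil is passed through", {
  x <- sine(5, 3000)
  rec <- make_recording(x, pupil = 1000 + sine(0.5, 3000))
  rec$xL_deg[1000:1100] <- NA
  rec$yL_deg[1000:1100] <- NA
  out <- lowpass_filter(rec)
  expect_true(all(is.na(out$xL_deg[1000:1100])))
  expect_false(anyNA(out$xL_deg[-(1000:1100)]))
  expect_identical(out$pupilL, rec$pupilL)
})

test_that("segmentation windows are inclusive and cue-locked", {
  sched <- build_schedule("full_certainty_1s", 3, seed = 1)
  rec <- make_recording(rep(0, ceiling(max(sched$target_onset_ms)) + 400))
  segs <- segment_trials(rec, sched)
  expect_length(segs, 3)
  seg <- segs[[1]]
  expect_length(seg$time_rel_ms, 1000 + 601)   # FP + 601 samples
  expect_equal(seg$time_rel_ms[1], -300)
  expect_equal(seg$time_rel_ms[length(seg$time_rel_ms)], 1300)
  expect_equal(seg$time_rel_ms[seg$cue_index], 0)
  expect_equal(seg$time_rel_ms[seg$target_index], 1000)
})

test_that("trials without margins are dropped and empty schedules allowed", {
  sched <- build_schedule("full_certainty_1s", 2, seed = 2)
  expect_length(segment_trials(make_recording(rep(0, 100)), sched[0, ]), 0)
  ## recording too short for the second trial
  short <- make_recording(rep(0, ceiling(sched$target_onset_ms[1]) + 400))
  expect_warning(segs <- segment_trials(short, sched), "dropped")
  expect_length(segs, 1)
  ## cue too close to recording start
  sched2 <- sched
  sched2$cue_onset_ms <- sched2$cue_onset_ms - sched2$cue_onset_ms[1]
  sched2$target_onset_ms <- sched2$cue_onset_ms + sched2$foreperiod_ms
  expect_warning(segment_trials(short, sched2), "dropped")
})

make_segment <- function(pL, pR = pL, x = NULL) {
  n <- length(pL)
  if (is.null(x)) x <- rep(0, n)
  seg <- list(trial_id = 1L, block_type = "full_certainty_1s",
              foreperiod_ms = n - 601, time_rel_ms = -300:(n - 301),
              xL_deg = x, yL_deg = x, pupilL = pL,
              xR_deg = x, yR_deg = x, pupilR = pR,
              cue_index = 301L, target_index = n - 300L)
  class(seg) <- "trial_segment"
  seg
}

test_that("pupil-deviation blinks need both eyes and 3+ consecutive samples", {
  set.seed(3)
  base <- 1000 + rnorm(1700, 0, 2)
  ## no excursion: no blinks
  expect_equal(nrow(detect_blinks(make_segment(base))), 0)
  ## a binocular 10-sample excursion far beyond 2.5 SD
  p <- base
  p[800:809] <- p[800:809] - 60
  ev <- detect_blinks(make_segment(p))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source, "pupil_deviation")
  ## the excursion is covered by the event
  expect_lte(ev$onset_ms, -300 + 799)
  expect_gte(ev$offset_ms, -300 + 808)
  ## brute-force check of the flagged span
  mono <- abs(p - mean(p)) > 2.5 * sd(p)
  both <- which(mono)    # same trace in both eyes
  expect_true(all(-300 + both - 1 >= ev$onset_ms &
                    -300 + both - 1 <= ev$offset_ms))
  ## a 2-sample excursion is below the minimum duration
  q <- base
  q[900:901] <- q[900:901] - 60
  expect_equal(nrow(detect_blinks(make_segment(q))), 0)
  ## monocular excursions never count
  ev2 <- detect_blinks(make_segment(p, pR = base))
  expect_equal(nrow(ev2), 0)
})

test_that("blink detection is shift- and scale-invariant in pupil units", {
  set.seed(4)
  base <- 1000 + rnorm(1700, 0, 2)
  p <- base
  p[400:420] <- p[400:420] + 40
  a <- detect_blinks(make_segment(p))
  b <- detect_blinks(make_segment(p + 500))
  c <- detect_blinks(make_segment(p * 3.7))
  expect_equal(a, b)
  expect_equal(a, c)
})

test_that("missing data becomes a blink; all-missing flags the whole segment", {
  set.seed(5)
  base <- 1000 + rnorm(1700, 0, 2)
  seg <- make_segment(base)
  seg$pupilL[600:650] <- NA
  ev <- detect_blinks(seg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source, "missing_data")
  expect_equal(ev$onset_ms, -300 + 599)
  expect_equal(ev$offset_ms, -300 + 649)
  seg2 <- make_segment(rep(NA_real_, 1700))
  ev2 <- detect_blinks(seg2)
  expect_equal(nrow(ev2), 1)
  expect_equal(c(ev2$onset_ms, ev2$offset_ms), c(-300, 1399))
})

test_that("the exclusion mask pads blinks by the margin and clips at edges", {
  seg <- make_segment(rep(1000, 1700))
  none <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                     source = character(0))
  expect_true(all(exclusion_mask(seg, none)))
  one <- data.frame(onset_ms = 500, offset_ms = 600, source = "x")
  m <- exclusion_mask(seg, one, margin_ms = 200)
  tt <- seg$time_rel_ms
  expect_true(all(!m[tt >= 300 & tt <= 800]))
  expect_true(all(m[tt < 300 | tt > 800]))
  edge <- data.frame(onset_ms = -300, offset_ms = -250, source = "x")
  me <- exclusion_mask(seg, edge, margin_ms = 200)
  expect_true(all(!me[tt <= -50]))
  expect_true(all(me[tt > -50]))
})

test_that("valid-sample counts equal the complement of the padded union", {
  set.seed(6)
  seg <- make_segment(rep(1000, 1700))
  tt <- seg$time_rel_ms
  for (rep_i in 1:20) {
    k <- sample(1:4, 1)
    on <- sort(sample(seq(-250, 1300, 10), k))
    off <- on + sample(seq(10, 300, 10), k, replace = TRUE)
    blinks <- data.frame(onset_ms = on, offset_ms = off,
                         source = rep("x", k))
    m <- exclusion_mask(seg, blinks, margin_ms = 200)
    ## brute-force set union
    bad <- rep(FALSE, length(tt))
    for (i in 1:k) bad <- bad | (tt >= on[i] - 200 & tt <= off[i] + 200)
    expect_equal(sum(m), length(tt) - sum(bad))
    expect_equal(m, !bad)
  }
})
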