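#' Zero-phase low-pass filter of gaze position channels
#'
#' Zero-phase Butterworth filtering of the four position channels; pupil
#' channels are left untouched. The filter is applied in the frequency
#' domain with the squared magnitude response of a digital Butterworth
#' low-pass (the response of forward-backward filtering), which has exactly
#' zero phase shift and therefore preserves event timing. Missing-data
#' spans are preserved as missing: each contiguous run of non-missing
#' samples is filtered separately (with reflective edge padding), and runs
#' too short to filter are passed through unchanged.
#'
#' @param recording A `gaze_recording` (see [simulate_gaze()]).
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order Butterworth filter order (of the underlying single-pass
#'   filter; the zero-phase response applies it twice).
#' @return The recording with filtered position channels.
#' @export
lowpass_filter <- function(recording, cutoff = 60, order = 4) {
  fs <- attr(recording, "sampling_rate")
  if (is.null(fs)) fs <- 1000
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  ## x and y of one eye share missing spans in practice; when they do,
  ## both are filtered in a single complex-valued FFT pass
  for (eye in list(c("xL_deg", "yL_deg"), c("xR_deg", "yR_deg"))) {
    x <- recording[[eye[1]]]
    y <- recording[[eye[2]]]
    if (identical(is.na(x), is.na(y))) {
      z <- filter_runs(complex(real = x, imaginary = y), fs, cutoff, order)
      recording[[eye[1]]] <- Re(z)
      recording[[eye[2]]] <- Im(z)
    } else {
      recording[[eye[1]]] <- filter_runs(x, fs, cutoff, order)
      recording[[eye[2]]] <- filter_runs(y, fs, cutoff, order)
    }
  }
  recording
}

## zero-phase filter applied per contiguous non-NA run
filter_runs <- function(x, fs, cutoff, order, min_len = 30) {
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values & r$lengths >= min_len)) {
    idx <- starts[i]:ends[i]
    x[idx] <- zero_phase_lowpass(x[idx], fs, cutoff, order)
  }
  x
}

## FFT implementation of zero-phase Butterworth low-pass: the spectrum is
## multiplied by |H(f)|^2 = 1 / (1 + w^(2p)), the squared magnitude of the
## bilinear-transformed digital Butterworth response with prewarped
## frequency w = tan(pi f / fs) / tan(pi fc / fs) -- the response of one
## forward and one backward pass. Edges are padded by point reflection.
zero_phase_lowpass <- function(x, fs, cutoff, order) {
  n <- length(x)
  pad <- min(n, 3 * ceiling(fs / cutoff))
  xe <- c(2 * x[1] - x[pad:2], x, 2 * x[n] - x[(n - 1):(n - pad + 1)])
  ne <- length(xe)
  N <- stats::nextn(ne, c(2, 3, 5))
  xe <- c(xe, rep(xe[ne], N - ne))
  k <- 0:(N - 1)
  f <- pmin(k, N - k) / N                    # cycles/sample in [0, 0.5]
  w <- tan(pi * f) / tan(pi * cutoff / fs)
  H2 <- 1 / (1 + w^(2 * order))
  y <- stats::fft(stats::fft(xe) * H2, inverse = TRUE) / N
  if (!is.complex(x)) y <- Re(y)     # complex input carries two channels
  y[pad:(pad + n - 1)]               # x[1] sits after the pad - 1 points
}

#' Segment a recording into per-trial epochs
#'
#' Each trial is cut from 300 ms before cue onset to 300 ms after target
#' onset, inclusive at both endpoints: a trial with foreperiod FP yields
#' FP + 601 samples at 1000 Hz. The within-segment time axis is relative to
#' cue onset (t = 0 at the cue). Trials whose window falls outside the
#' recording are dropped with a warning.
#'
#' @param recording A `gaze_recording`.
#' @param schedule A `trial_schedule`.
#' @param margin_ms Margin around cue and target, ms.
#' @return A list of `trial_segment` objects: each is a list with
#'   `trial_id`, `block_type`, `foreperiod_ms`, `time_rel_ms` (relative to
#'   cue), position/pupil channel vectors, `cue_index` and `target_index`
#'   (1-based sample indices of cue and target within the segment).
#' @export
segment_trials <- function(recording, schedule, margin_ms = 300) {
  t0 <- recording$time_ms[1]
  t_end <- recording$time_ms[nrow(recording)]
  segs <- list()
  dropped <- 0L
  for (i in seq_len(nrow(schedule))) {
    cue <- round(schedule$cue_onset_ms[i])
    fp <- schedule$foreperiod_ms[i]
    lo <- cue - margin_ms
    hi <- cue + fp + margin_ms
    if (lo < t0 || hi > t_end) {
      dropped <- dropped + 1L
      next
    }
    idx <- (lo - t0 + 1):(hi - t0 + 1)
    seg <- list(trial_id = schedule$trial_id[i],
                block_type = schedule$block_type[i],
                foreperiod_ms = fp,
                time_rel_ms = (lo:hi) - cue,
                xL_deg = recording$xL_deg[idx],
                yL_deg = recording$yL_deg[idx],
                pupilL = recording$pupilL[idx],
                xR_deg = recording$xR_deg[idx],
                yR_deg = recording$yR_deg[idx],
                pupilR = recording$pupilR[idx],
                cue_index = margin_ms + 1L,
                target_index = margin_ms + fp + 1L)
    class(seg) <- "trial_segment"
    segs[[length(segs) + 1]] <- seg
  }
  if (dropped > 0) {
    warning(dropped, " trial(s) dropped: segment window outside recording")
  }
  segs
}

#' Detect blinks in a trial segment
#'
#' Blinks are the union of (a) missing-data spans (any position or pupil
#' channel missing; the stand-in for the tracker's built-in detector,
#' which flags dropout) and (b) spans where the pupil size of *both* eyes
#' deviates from the segment mean by more than `sd_mult` standard
#' deviations for at least `min_samples` consecutive samples. Segment mean
#' and SD are computed per eye over non-missing samples. Overlapping or
#' touching events are merged.
#'
#' @param segment A `trial_segment`.
#' @param sd_mult Pupil deviation criterion, in SDs.
#' @param min_samples Minimum run length of the deviation, samples.
#' @return A data frame with columns `onset_ms`, `offset_ms` (segment time,
#'   relative to cue) and `source` (`"missing_data"`, `"pupil_deviation"`
#'   or `"merged"`).
#' @export
detect_blinks <- function(segment, sd_mult = 2.5, min_samples = 3) {
  n <- length(segment$time_rel_ms)
  miss <- is.na(segment$pupilL) | is.na(segment$pupilR) |
    is.na(segment$xL_deg) | is.na(segment$xR_deg) |
    is.na(segment$yL_deg) | is.na(segment$yR_deg)
  if (all(miss)) {
    return(data.frame(onset_ms = segment$time_rel_ms[1],
                      offset_ms = segment$time_rel_ms[n],
                      source = "missing_data"))
  }
  dev_flag <- function(p) {
    m <- mean(p[!miss], na.rm = TRUE)
    s <- stats::sd(p[!miss], na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(FALSE, n))
    out <- abs(p - m) > sd_mult * s
    out[is.na(out)] <- FALSE
    out
  }
  both <- dev_flag(segment$pupilL) & dev_flag(segment$pupilR)
  m1 <- find_runs(miss, 1)
  m2 <- find_runs(both, min_samples)
  iv <- rbind(m1, m2)
  src <- c(rep("missing_data", nrow(m1)), rep("pupil_deviation", nrow(m2)))
  if (nrow(iv) == 0) {
    return(fast_df(list(onset_ms = numeric(0), offset_ms = numeric(0),
                        source = character(0))))
  }
  mi <- merge_intervals(iv, src)
  fast_df(list(onset_ms = segment$time_rel_ms[mi$iv[, 1]],
               offset_ms = segment$time_rel_ms[mi$iv[, 2]],
               source = mi$src))
}

## runs of TRUE with length >= min_len, as a 2-column index matrix
find_runs <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  cbind(start = (ends - r$lengths + 1)[keep], end = ends[keep])
}

## data.frame constructor without the deparse/validation overhead of
## data.frame(); all columns must already have equal length
fast_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}

## merge overlapping or touching [start, end] index intervals
merge_intervals <- function(iv, src) {
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  src <- src[o]
  k <- 1L
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= iv[k, 2] + 1) {
      if (iv[i, 2] > iv[k, 2]) iv[k, 2] <- iv[i, 2]
      if (src[k] != src[i]) src[k] <- "merged"
    } else {
      k <- k + 1L
      iv[k, ] <- iv[i, ]
      src[k] <- src[i]
    }
  }
  list(iv = iv[seq_len(k), , drop = FALSE], src = src[seq_len(k)])
}

#' Per-sample validity mask after blink exclusion
#'
#' Samples inside a blink, within `margin_ms` before each blink onset or
#' after each blink offset, or with missing data, are invalid. Padded
#' intervals are clipped at the segment boundaries.
#'
#' @param segment A `trial_segment`.
#' @param blinks Blink events from [detect_blinks()].
#' @param margin_ms Exclusion margin around each blink, ms.
#' @return A logical vector, `TRUE` where the sample is valid.
#' @export
exclusion_mask <- function(segment, blinks, margin_ms = 200) {
  tt <- segment$time_rel_ms
  valid <- !(is.na(segment$xL_deg) | is.na(segment$yL_deg) |
               is.na(segment$xR_deg) | is.na(segment$yR_deg))
  if (!is.null(blinks) && nrow(blinks) > 0) {
    for (i in seq_len(nrow(blinks))) {
      valid[tt >= blinks$onset_ms[i] - margin_ms &
              tt <= blinks$offset_ms[i] + margin_ms] <- FALSE
    }
  }
  valid
}
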