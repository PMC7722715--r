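#' Assign the trial condition from block type and foreperiod
#'
#' Full-certainty blocks give `full_certainty` trials; high-certainty
#' blocks give `high_certainty_frequent` trials when the trial's foreperiod
#' is the block's 80% duration and `high_certainty_rare` when it is the 20%
#' duration; low-certainty blocks give `low_certainty` trials.
#'
#' @param block_type Character vector of block types.
#' @param foreperiod_ms Numeric vector of foreperiods, ms.
#' @return Character vector of condition labels.
#' @export
assign_condition <- function(block_type, foreperiod_ms) {
  stopifnot(length(block_type) == length(foreperiod_ms))
  mapply(function(bt, fp) {
    bt <- match.arg(bt, BLOCK_TYPES)
    dist <- block_distribution(bt)
    i <- match(fp, dist$support)
    if (is.na(i) || dist$probs[i] == 0) {
      stop("foreperiod ", fp, " ms cannot occur in block '", bt, "'")
    }
    switch(bt,
      full_certainty_1s = ,
      full_certainty_2s = "full_certainty",
      low_certainty = "low_certainty",
      if (dist$probs[i] == 0.8) "high_certainty_frequent"
      else "high_certainty_rare")
  }, block_type, foreperiod_ms, USE.NAMES = FALSE)
}

#' Saccade-rate time course across trials
#'
#' At each time point `t` relative to the lock event (cue or target), the
#' rate is the number of trials with a saccade *onset* at `t`, among trials
#' valid at `t`, divided by the number of valid trials and multiplied by the
#' sampling rate: saccades per second. Samples excluded by the blink mask
#' contribute to neither numerator nor denominator. Where no trial is
#' valid, the rate is 0 by convention.
#'
#' @param trials A list of processed trials; each element a list with
#'   `segment` (a `trial_segment`), `valid` (logical mask) and `events`
#'   (binocular event data frame, onsets in segment time).
#' @param lock `"cue"` or `"target"`.
#' @return An object of class `rate_timecourse`: data frame `time_ms`
#'   (relative to the lock event), `rate` (saccades/s), `n_valid`; with
#'   attribute `lock`.
#' @export
rate_timecourse <- function(trials, lock = c("cue", "target")) {
  lock <- match.arg(lock)
  if (length(trials) == 0) {
    out <- data.frame(time_ms = numeric(0), rate = numeric(0),
                      n_valid = integer(0))
    attr(out, "lock") <- lock
    class(out) <- c("rate_timecourse", "data.frame")
    return(out)
  }
  shift <- vapply(trials, function(tr) {
    if (lock == "cue") 0 else -tr$segment$foreperiod_ms
  }, numeric(1))
  lo <- min(vapply(seq_along(trials), function(i) {
    trials[[i]]$segment$time_rel_ms[1] + shift[i]
  }, numeric(1)))
  hi <- max(vapply(seq_along(trials), function(i) {
    tr <- trials[[i]]$segment$time_rel_ms
    tr[length(tr)] + shift[i]
  }, numeric(1)))
  axis <- lo:hi
  n_valid <- integer(length(axis))
  n_onset <- integer(length(axis))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    tt <- tr$segment$time_rel_ms + shift[i]
    pos <- tt - lo + 1
    n_valid[pos] <- n_valid[pos] + tr$valid
    if (nrow(tr$events) > 0) {
      op <- round(tr$events$onset_ms + shift[i]) - lo + 1
      op <- op[op >= 1 & op <= length(axis)]
      n_onset[op] <- n_onset[op] + 1L
    }
  }
  rate <- ifelse(n_valid > 0, n_onset / n_valid * 1000, 0)
  out <- data.frame(time_ms = axis, rate = rate, n_valid = n_valid)
  attr(out, "lock") <- lock
  class(out) <- c("rate_timecourse", "data.frame")
  out
}

#' Mean pre-target saccade rate
#'
#' Unweighted mean of the per-sample rate over the pre-target window,
#' inclusive at both endpoints (the default \[-100, 0\] ms window holds 101
#' samples at 1000 Hz).
#'
#' @param tc A target-locked [rate_timecourse()].
#' @param window Two-element window relative to the lock event, ms.
#' @return Mean rate in saccades/s, or `NA` (with a warning) if no valid
#'   trial covers any window sample.
#' @export
mean_pretarget_sr <- function(tc, window = c(-100, 0)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- tc$time_ms >= window[1] & tc$time_ms <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] not covered by the time course")
  if (all(tc$n_valid[sel] == 0)) {
    warning("no valid trials anywhere in the pre-target window")
    return(NA_real_)
  }
  mean(tc$rate[sel])
}

#' Smooth a rate time course for display
#'
#' Centered moving average with a window of `window_ms` samples; near the
#' edges the window shrinks symmetrically. For display only -- analysis
#' statistics are always computed on unsmoothed traces.
#'
#' @param tc A [rate_timecourse()].
#' @param window_ms Smoothing window, ms.
#' @return The time course with a smoothed `rate` column.
#' @export
smooth_timecourse <- function(tc, window_ms = 50) {
  stopifnot(window_ms >= 1)
  n <- nrow(tc)
  half <- floor(window_ms / 2)
  cs <- cumsum(c(0, tc$rate))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  tc$rate <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  tc
}

#' Subject-level pre-target saccade-rate table
#'
#' Builds the subject x condition x foreperiod table of mean pre-target
#' saccade rate: within each cell, trials are pooled into a target-locked
#' rate time course (rate across trials per sample) which is then averaged
#' over the pre-target window.
#'
#' @param trials Processed trials of one subject (see [rate_timecourse()]);
#'   each element must also carry `block_type` and `foreperiod_ms` in its
#'   `segment`.
#' @param subject_id Identifier stored in the output.
#' @param window Pre-target window, ms relative to target.
#' @return A data frame of class `pretarget_sr_table`: `subject_id`,
#'   `condition`, `foreperiod_ms`, `mean_sr`, `n_trials`.
#' @export
pretarget_sr_table <- function(trials, subject_id = 1L, window = c(-100, 0)) {
  cond <- vapply(trials, function(tr) {
    assign_condition(tr$segment$block_type, tr$segment$foreperiod_ms)
  }, character(1))
  fp <- vapply(trials, function(tr) tr$segment$foreperiod_ms, numeric(1))
  cells <- unique(data.frame(condition = cond, foreperiod_ms = fp))
  cells <- cells[order(cells$condition, cells$foreperiod_ms), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- which(cond == cells$condition[i] & fp == cells$foreperiod_ms[i])
    tc <- rate_timecourse(trials[sel], lock = "target")
    sr <- suppressWarnings(mean_pretarget_sr(tc, window))
    data.frame(subject_id = subject_id, condition = cells$condition[i],
               foreperiod_ms = cells$foreperiod_ms[i], mean_sr = sr,
               n_trials = length(sel))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pretarget_sr_table", "data.frame")
  out
}
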