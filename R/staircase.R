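#' Run a 1-up 3-down adaptive staircase
#'
#' The classic transformed up-down rule: after three consecutive correct
#' responses the stimulus level (tilt) decreases by one logarithmic step;
#' after a single incorrect response it increases by one step. The run
#' terminates after `max_reversals` reversals of direction or after
#' `max_trials` trials, whichever comes first. The rule converges to the
#' level where P(3 correct in a row) = 0.5, i.e. P(correct) = 0.5^(1/3)
#' (about 79.4%).
#'
#' @param observer A function mapping tilt (deg, > 0) to P(correct) in
#'   \[0, 1\]. Monotonicity is checked on a grid; a non-monotone observer is
#'   allowed but flagged with a warning.
#' @param start_tilt Starting tilt, deg (> 0).
#' @param seed Integer seed for the simulated responses.
#' @param step_log10 Step size in log10 units (tilt is multiplied or
#'   divided by `10^step_log10`).
#' @param max_reversals,max_trials Termination rules.
#' @return A list of class `staircase_result`: `threshold_tilt` (the final
#'   tilt), and `state` with `current_tilt`, `step_index`, `reversal_count`,
#'   `trial_count` and `history` (data frame of `tilt`, `correct`).
#' @export
run_staircase <- function(observer, start_tilt = 15, seed = 1,
                          step_log10 = 0.1, max_reversals = 4,
                          max_trials = 100) {
  stopifnot(is.function(observer))
  if (start_tilt <= 0) stop("start_tilt must be positive")
  grid <- exp(seq(log(0.01), log(start_tilt), length.out = 25))
  pg <- vapply(grid, observer, numeric(1))
  if (any(pg < 0 | pg > 1)) stop("observer must return probabilities in [0, 1]")
  if (any(diff(pg) < -1e-9)) {
    warning("observer is not monotone nondecreasing in tilt")
  }
  rng <- local_seed(seed)
  on.exit(rng(), add = TRUE)

  tilt <- start_tilt
  n_correct_run <- 0L
  reversals <- 0L
  direction <- 0L       # -1 descending, +1 ascending, 0 before first step
  trials <- 0L
  step_index <- 0L
  hist_tilt <- numeric(0)
  hist_correct <- logical(0)

  while (reversals < max_reversals && trials < max_trials) {
    trials <- trials + 1L
    correct <- stats::runif(1) < observer(tilt)
    hist_tilt <- c(hist_tilt, tilt)
    hist_correct <- c(hist_correct, correct)
    move <- 0L
    if (correct) {
      n_correct_run <- n_correct_run + 1L
      if (n_correct_run == 3L) {
        move <- -1L
        n_correct_run <- 0L
      }
    } else {
      move <- +1L
      n_correct_run <- 0L
    }
    if (move != 0L) {
      if (direction != 0L && move != direction) reversals <- reversals + 1L
      direction <- move
      step_index <- step_index + move
      tilt <- tilt * 10^(move * step_log10)
    }
  }

  structure(list(
    threshold_tilt = tilt,
    state = list(current_tilt = tilt, step_index = step_index,
                 reversal_count = reversals, trial_count = trials,
                 history = data.frame(tilt = hist_tilt, correct = hist_correct))
  ), class = "staircase_result")
}

#' Weibull psychometric observer for a 2AFC task
#'
#' P(correct) = 0.5 + 0.5 * (1 - exp(-(x / alpha)^beta)): chance level 0.5,
#' no lapses.
#'
#' @param alpha Threshold parameter, deg.
#' @param beta Slope parameter.
#' @return A function tilt -> P(correct), usable with [run_staircase()].
#' @export
weibull_observer <- function(alpha = 1.02, beta = 3) {
  force(alpha); force(beta)
  function(x) 0.5 + 0.5 * (1 - exp(-(x / alpha)^beta))
}
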