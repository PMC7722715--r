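#' Configuration of a full synthetic experiment
#'
#' Bundles every stage's parameters with the session structure and a master
#' seed. Defaults reproduce the paradigm's session: 20 subjects, 17 blocks
#' each (one of each full-certainty type, five of each high-certainty type,
#' five low-certainty), 80 trials per block; 60 Hz low-pass cutoff; blink
#' criterion 2.5 SD for >= 3 samples with a 200 ms exclusion margin;
#' velocity threshold 6 robust SDs for >= 6 samples with a 50 ms
#' inter-saccade interval; pre-target window \[-100, 0\] ms; alpha 0.05.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_block Trials per block (divisible by 5).
#' @param blocks_per_type Named integer vector: blocks per block type.
#' @param sim A [sim_params()] object (its `seed` is overridden per
#'   subject/block from the master seed).
#' @param detector A [detector_params()] object.
#' @param filter_cutoff_hz Low-pass cutoff for position channels.
#' @param blink_sd,blink_min_samples,blink_margin_ms Blink criterion and
#'   exclusion margin.
#' @param pretarget_window Pre-target averaging window, ms.
#' @param alpha Significance level for contrasts and verdicts.
#' @param seed Master seed; per-subject/per-block/per-stage seeds are
#'   derived from it with a counter-based scheme.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 20,
                       n_trials_per_block = 80,
                       blocks_per_type = c(full_certainty_1s = 1,
                                           full_certainty_2s = 1,
                                           high_certainty_1s = 5,
                                           high_certainty_2s = 5,
                                           low_certainty = 5),
                       sim = sim_params(),
                       detector = detector_params(),
                       filter_cutoff_hz = 60,
                       blink_sd = 2.5,
                       blink_min_samples = 3,
                       blink_margin_ms = 200,
                       pretarget_window = c(-100, 0),
                       alpha = 0.05,
                       seed = 1) {
  stopifnot(n_subjects >= 1, n_trials_per_block >= 5,
            all(names(blocks_per_type) %in% BLOCK_TYPES))
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Process one block: filter, segment, blink-clean, detect
#'
#' Applies the preprocessing and detection chain to one continuous block
#' recording: zero-phase low-pass filtering of the position channels,
#' per-trial segmentation, blink detection and exclusion masking, monocular
#' velocity-threshold detection in each eye and binocular conjunction.
#'
#' @param recording A `gaze_recording`.
#' @param schedule The block's `trial_schedule`.
#' @param config A [run_config()].
#' @return A list of processed trials, each a list with `segment`, `blinks`,
#'   `valid` and `events` (binocular saccades, onsets in segment time).
#' @export
process_block <- function(recording, schedule, config = run_config()) {
  rec <- lowpass_filter(recording, cutoff = config$filter_cutoff_hz)
  segs <- segment_trials(rec, schedule)
  lapply(segs, function(seg) {
    blinks <- detect_blinks(seg, sd_mult = config$blink_sd,
                            min_samples = config$blink_min_samples)
    valid <- exclusion_mask(seg, blinks, margin_ms = config$blink_margin_ms)
    evL <- detect_monocular(cbind(seg$xL_deg, seg$yL_deg), valid,
                            config$detector, time_ms = seg$time_rel_ms)
    evR <- detect_monocular(cbind(seg$xR_deg, seg$yR_deg), valid,
                            config$detector, time_ms = seg$time_rel_ms)
    events <- binocular_conjunction(evL, evR, config$detector)
    list(segment = seg, blinks = blinks, valid = valid, events = events)
  })
}

#' Simulate and analyze a full experiment
#'
#' Runs the complete chain for every simulated subject -- schedule
#' generation, gaze simulation under the temporal-orienting generative law,
#' preprocessing, saccade detection, pre-target saccade-rate table -- and
#' then the statistical battery: the two-way (Condition x Foreperiod)
#' repeated-measures ANOVA on the 1 s/2 s cells, one-way ANOVAs and planned
#' contrast families per foreperiod, the low-certainty foreperiod trend,
#' within-subject SEMs, and the verdicts for the orienting and certainty
#' hypotheses. Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return An object of class `experiment_result`: list with `sr_table`,
#'   `anova` (two-way), `anova_by_fp`, `contrasts`, `trend`, `sem`,
#'   `verdicts` (list of `hypothesis_verdict`) and `manifest`.
#' @export
run_experiment <- function(config = run_config()) {
  block_types <- rep(names(config$blocks_per_type), config$blocks_per_type)
  tables <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    trials <- list()
    for (b in seq_along(block_types)) {
      bt <- block_types[b]
      sched <- build_schedule(bt, config$n_trials_per_block,
                              seed = derive_seed(config$seed, s, b, 1))
      sim <- config$sim
      sim$seed <- derive_seed(config$seed, s, b, 2)
      gz <- simulate_gaze(sched, sim)
      trials <- c(trials, process_block(gz$recording, sched, config))
    }
    tables[[s]] <- pretarget_sr_table(trials, subject_id = s,
                                      window = config$pretarget_window)
  }
  sr_table <- do.call(rbind, tables)
  class(sr_table) <- c("pretarget_sr_table", "data.frame")
  analyze_sr_table(sr_table, config)
}

#' Statistical battery over a pre-target saccade-rate table
#'
#' @param sr_table A `pretarget_sr_table` covering all four conditions at
#'   1000 and 2000 ms (and, if present, the five low-certainty foreperiods
#'   for the trend analysis).
#' @param config A [run_config()] (significance level, manifest).
#' @return An `experiment_result`; see [run_experiment()].
#' @export
analyze_sr_table <- function(sr_table, config = run_config()) {
  core <- sr_table[sr_table$foreperiod_ms %in% c(1000, 2000), ]
  anova2 <- rm_anova(core, factors = c("condition", "foreperiod_ms"))
  anova_by_fp <- lapply(c(1000, 2000), function(fp) {
    rm_anova(core[core$foreperiod_ms == fp, ], factors = "condition")
  })
  names(anova_by_fp) <- c("fp_1000", "fp_2000")
  contr <- planned_contrasts(core, conf = 0.95)
  verdicts <- list(
    orienting = evaluate_hypothesis(contr, "orienting", alpha = config$alpha),
    certainty = evaluate_hypothesis(contr, "certainty", alpha = config$alpha))
  trend <- if (sum(sr_table$condition == "low_certainty" &
                     !is.na(sr_table$mean_sr)) >=
               5 * length(unique(sr_table$subject_id))) {
    foreperiod_trend(sr_table)
  } else NULL
  sem <- within_subject_sem(core)
  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    n_trials_per_block = config$n_trials_per_block,
    blocks_per_type = config$blocks_per_type,
    filter = sprintf("butterworth order 4, zero-phase, %g Hz",
                     config$filter_cutoff_hz),
    segment_endpoints = "inclusive at -300 and +300 ms",
    pretarget_window = sprintf("[%g, %g] ms, endpoints inclusive",
                               config$pretarget_window[1],
                               config$pretarget_window[2]),
    threshold_mode = config$detector$threshold_mode,
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  structure(list(sr_table = sr_table, anova = anova2,
                 anova_by_fp = anova_by_fp, contrasts = contr,
                 trend = trend, sem = sem, verdicts = verdicts,
                 manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Synthetic foreperiod experiment:",
      x$manifest$n_subjects, "subjects,",
      sum(x$manifest$blocks_per_type), "blocks x",
      x$manifest$n_trials_per_block, "trials\n\n")
  cat("Two-way repeated-measures ANOVA (Condition x Foreperiod):\n")
  av <- x$anova
  av[] <- lapply(av, function(c) if (is.numeric(c)) signif(c, 4) else c)
  print(av, row.names = FALSE)
  cat("\nPlanned contrasts:\n")
  ct <- x$contrasts[, c("label", "estimate", "t", "p_fdr", "dz", "bf01")]
  ct[] <- lapply(ct, function(c) if (is.numeric(c)) signif(c, 3) else c)
  print(ct, row.names = FALSE)
  cat("\n")
  print(x$verdicts$orienting)
  print(x$verdicts$certainty)
  invisible(x)
}
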