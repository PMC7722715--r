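#' Ordinal predictions of the certainty and temporal-orienting hypotheses
#'
#' Both hypotheses predict an ordering of mean pre-target saccade rate (SR)
#' across the four trial conditions, separately for 1 s and 2 s foreperiods.
#' Lower level means stronger pre-target inhibition (lower SR).
#'
#' * Certainty: SR follows the block-wise state of certainty only, at both
#'   foreperiods: full < \{frequent = rare\} < low.
#' * Orienting, 1 s foreperiod: SR follows the marginal frequency of the
#'   foreperiod in the block (100/80/20/20%):
#'   full < frequent < \{rare = low\}.
#' * Orienting, 2 s foreperiod: SR follows the conditional (hazard)
#'   probability of the target at 2 s (1 vs 1/3):
#'   \{full = frequent = rare\} < low.
#'
#' @param hypothesis `"certainty"` or `"orienting"`.
#' @return An object of class `prediction_table`: a data frame with columns
#'   `hypothesis`, `foreperiod_ms`, `condition`, `level` (small integer;
#'   lower = stronger inhibition; equal levels form an equality class).
#' @export
sr_predictions <- function(hypothesis = c("orienting", "certainty")) {
  hypothesis <- match.arg(hypothesis)
  lev <- if (hypothesis == "certainty") {
    list(`1000` = c(1, 2, 2, 3), `2000` = c(1, 2, 2, 3))
  } else {
    list(`1000` = c(1, 2, 3, 3), `2000` = c(1, 1, 1, 2))
  }
  out <- do.call(rbind, lapply(names(lev), function(fp) {
    data.frame(hypothesis = hypothesis, foreperiod_ms = as.numeric(fp),
               condition = CONDITIONS, level = lev[[fp]])
  }))
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Equality classes of a prediction table
#'
#' @param table A [sr_predictions()] table.
#' @param foreperiod_ms Foreperiod (1000 or 2000).
#' @return A list of character vectors of condition names; conditions in the
#'   same vector are predicted not to differ.
#' @export
equality_classes <- function(table, foreperiod_ms) {
  stopifnot(inherits(table, "prediction_table"))
  sub <- table[table$foreperiod_ms == foreperiod_ms, ]
  if (nrow(sub) == 0) stop("no predictions for foreperiod ", foreperiod_ms)
  unname(split(sub$condition, sub$level))
}

#' The planned contrast set of the paradigm
#'
#' Five planned contrasts, grouped into one family per foreperiod as in the
#' analysis plan: at 1 s, full-certainty vs low-certainty, rare vs frequent,
#' and rare vs low; at 2 s, full vs low and full vs the two high-certainty
#' conditions combined (within-subject average of frequent and rare).
#'
#' @return A data frame with columns `label`, `foreperiod_ms`, `a`, `b`
#'   where `a` and `b` name the condition (or `"high_combined"`) entering
#'   the paired difference `a - b`.
#' @export
planned_contrast_set <- function() {
  data.frame(
    label = c("full_vs_low_1s", "rare_vs_frequent_1s", "rare_vs_low_1s",
              "full_vs_low_2s", "full_vs_high_combined_2s"),
    foreperiod_ms = c(1000, 1000, 1000, 2000, 2000),
    a = c("full_certainty", "high_certainty_rare", "high_certainty_rare",
          "full_certainty", "full_certainty"),
    b = c("low_certainty", "high_certainty_frequent", "low_certainty",
          "low_certainty", "high_combined")
  )
}

## Which contrast outcomes each hypothesis predicts. `sign` is the expected
## sign of mean(a - b) for an inequality; NA marks a predicted equality.
hypothesis_expectations <- function(hypothesis) {
  if (hypothesis == "orienting") {
    data.frame(
      label = c("full_vs_low_1s", "rare_vs_frequent_1s", "rare_vs_low_1s",
                "full_vs_low_2s", "full_vs_high_combined_2s"),
      kind = c("inequality", "inequality", "equality",
               "inequality", "equality"),
      sign = c(-1, +1, NA, -1, NA)
    )
  } else {
    data.frame(
      label = c("full_vs_low_1s", "rare_vs_frequent_1s", "rare_vs_low_1s",
                "full_vs_low_2s", "full_vs_high_combined_2s"),
      kind = c("inequality", "equality", "inequality",
               "inequality", "inequality"),
      sign = c(-1, NA, -1, -1, -1)
    )
  }
}

#' Evaluate contrast results against a hypothesis' predictions
#'
#' A hypothesis is judged `"consistent"` when every predicted inequality has
#' a significant contrast (FDR-adjusted p below `alpha`) in the predicted
#' direction, and every predicted equality is non-significant with BF01
#' above `bf_null_min`. Missing contrasts are reported as gaps and block the
#' verdict.
#'
#' @param contrasts A `contrast_results` data frame from
#'   [planned_contrasts()], covering the [planned_contrast_set()] labels.
#' @param hypothesis `"orienting"` or `"certainty"`.
#' @param alpha Significance level for FDR-adjusted p-values.
#' @param bf_null_min Minimum BF01 for a supported equality.
#' @return An object of class `hypothesis_verdict`: list with `hypothesis`,
#'   `verdict` (`"consistent"`, `"inconsistent"` or `"undetermined"`),
#'   `checks` (per-contrast data frame) and `gaps`.
#' @export
evaluate_hypothesis <- function(contrasts, hypothesis = c("orienting", "certainty"),
                                alpha = 0.05, bf_null_min = 1) {
  hypothesis <- match.arg(hypothesis)
  exp_tab <- hypothesis_expectations(hypothesis)
  gaps <- setdiff(exp_tab$label, contrasts$label)
  checks <- merge(exp_tab, contrasts, by = "label", sort = FALSE)
  if (nrow(checks)) {
    checks$pass <- ifelse(
      checks$kind == "inequality",
      checks$p_fdr < alpha & sign(checks$estimate) == checks$sign,
      checks$p_fdr >= alpha & checks$bf01 > bf_null_min
    )
  } else {
    checks$pass <- logical(0)
  }
  verdict <- if (length(gaps) > 0) "undetermined"
             else if (all(checks$pass)) "consistent" else "inconsistent"
  structure(list(hypothesis = hypothesis, verdict = verdict,
                 checks = checks, gaps = gaps,
                 alpha = alpha, bf_null_min = bf_null_min),
            class = "hypothesis_verdict")
}

#' @export
print.hypothesis_verdict <- function(x, ...) {
  cat(sprintf("Hypothesis '%s': %s\n", x$hypothesis, toupper(x$verdict)))
  if (length(x$gaps)) cat("  missing contrasts:", paste(x$gaps, collapse = ", "), "\n")
  if (nrow(x$checks)) {
    df <- x$checks[, c("label", "kind", "estimate", "p_fdr", "bf01", "pass")]
    df$estimate <- signif(df$estimate, 3)
    df$p_fdr <- signif(df$p_fdr, 3)
    df$bf01 <- signif(df$bf01, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
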