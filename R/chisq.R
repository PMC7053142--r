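#' Complete-case 2x2 table at the final visit
#'
#' Cross-tabulates arm against outcome over the non-missing final-visit
#' records only (complete-case).
#'
#' @param data a `trial_data` data frame.
#' @return 2x2 integer matrix, rows `treatment`/`control`, columns
#'   `event`/`no_event`.
#' @export
tabulate_final_visit <- function(data) {
  v_final <- max(data$visit)
  d <- data[data$visit == v_final & !data$missing, , drop = FALSE]
  matrix(c(sum(d$arm == 1L & d$y == 1L), sum(d$arm == 1L & d$y == 0L),
           sum(d$arm == 0L & d$y == 1L), sum(d$arm == 0L & d$y == 0L)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(arm = c("treatment", "control"),
                         outcome = c("event", "no_event")))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected Pearson statistic on 1 degree of freedom (no continuity
#' correction), with the p-value from the upper tail of chi-squared(1). A
#' zero row or column margin makes the test undefined and is flagged.
#'
#' @param table 2x2 count matrix from [tabulate_final_visit()].
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
pearson_chi2 <- function(table) {
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       degenerate = FALSE)
}

#' Log-odds ratio with Wald interval from a 2x2 table
#'
#' Estimate `log(n11 n00 / (n10 n01))` (treatment versus control, event = 1)
#' with the usual delta-method standard error
#' `sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)` and a 95% Wald interval. Any zero
#' cell yields a degenerate result (no 0.5 correction is applied; degenerate
#' replicates are excluded from estimate-based summaries and counted).
#'
#' @param table 2x2 count matrix from [tabulate_final_visit()].
#' @return list with `estimate`, `se`, `ci_low`, `ci_high`, `degenerate`.
#' @export
log_odds_ratio <- function(table) {
  if (any(table == 0))
    return(list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, degenerate = TRUE))
  est <- log(table[1, 1] * table[2, 2] / (table[1, 2] * table[2, 1]))
  se <- sqrt(sum(1 / table))
  z <- qnorm(0.975)
  list(estimate = est, se = se,
       ci_low = est - z * se, ci_high = est + z * se, degenerate = FALSE)
}

#' Complete-case chi-squared analysis of one replicate
#'
#' Combines [tabulate_final_visit()], [pearson_chi2()] and
#' [log_odds_ratio()] into one analysis-result row. The rejection p-value is
#' the Pearson chi-squared p-value; the estimate, standard error and interval
#' are on the log-odds-ratio scale.
#'
#' @param data a `trial_data` data frame.
#' @return one-row data frame with columns `method`, `estimate`, `se`,
#'   `statistic`, `p_value`, `ci_low`, `ci_high`, `converged`, `degenerate`.
#' @export
analyze_chisq <- function(data) {
  tab <- tabulate_final_visit(data)
  test <- pearson_chi2(tab)
  or <- log_odds_ratio(tab)
  data.frame(method = "chisq",
             estimate = or$estimate, se = or$se,
             statistic = test$statistic, p_value = test$p_value,
             ci_low = or$ci_low, ci_high = or$ci_high,
             converged = TRUE,
             degenerate = or$degenerate || test$degenerate,
             stringsAsFactors = FALSE)
}
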