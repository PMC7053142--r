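#' Delete final-visit outcomes completely at random
#'
#' Flags exactly `round(rate * arm size)` final-visit records per arm as
#' missing, chosen by simple random sampling without replacement, so the
#' realized per-arm dropout count is fixed, not binomial. Earlier visits are
#' never touched (monotone dropout at the final visit only).
#'
#' @param data a `trial_data` data frame ([generate_complete_replicate()]).
#' @param control_rate,treatment_rate per-arm dropout proportions in \[0, 1\].
#' @return the data with `missing` set on the sampled final-visit rows.
#' @export
apply_mcar <- function(data, control_rate, treatment_rate) {
  stopifnot(control_rate >= 0, control_rate <= 1,
            treatment_rate >= 0, treatment_rate <= 1)
  v_final <- max(data$visit)
  for (a in c(0L, 1L)) {
    rate <- if (a == 0L) control_rate else treatment_rate
    idx <- which(data$visit == v_final & data$arm == a & !data$missing)
    k <- round(rate * length(idx))
    if (k > 0L) data$missing[sample(idx, k)] <- TRUE
  }
  data
}

#' Calibrate the missing-at-random dropout model
#'
#' The probability that a subject's final-visit outcome is missing follows a
#' logistic model in the previous outcome and treatment arm:
#' `logit Pr(missing) = gamma1 + gamma2 * y_prev + gamma3 * X`. `gamma2` is
#' fixed in advance (+1.5 makes prior responders about 4.5 times as likely to
#' drop out, -1.5 about 0.22 times); `gamma1` and `gamma3` are solved so the
#' expected dropout rate in each arm matches its target, using the marginal
#' previous-outcome probabilities implied by the generative model
#' (`pi_c = prevalence` in control, `pi_t = prevalence + delta` in treatment;
#' pass `delta = 0` for null-hypothesis data). Each equation is a strictly
#' increasing function of the intercept and is solved by a bracketing root
#' finder to residuals below 1e-10.
#'
#' @param gamma2 log-odds ratio of dropout per unit of the previous outcome.
#' @param prevalence marginal event probability at the previous visit in the
#'   control arm.
#' @param delta increment of that probability in the treatment arm.
#' @param target_control_rate,target_treatment_rate desired expected per-arm
#'   dropout probabilities, in (0,1).
#' @return object of class `missingness_model`: list with `gamma1`, `gamma2`,
#'   `gamma3`, the targets and the marginal probabilities used.
#' @export
#' @examples
#' calibrate_mar(1.5, prevalence = 0.1, delta = 0.05,
#'               target_control_rate = 0.3, target_treatment_rate = 0.3)
calibrate_mar <- function(gamma2, prevalence, delta,
                          target_control_rate, target_treatment_rate) {
  stopifnot(target_control_rate > 0, target_control_rate < 1,
            target_treatment_rate > 0, target_treatment_rate < 1,
            prevalence > 0, prevalence < 1, delta >= 0)
  pi_c <- prevalence
  pi_t <- min(prevalence + delta, 1)

  solve_intercept <- function(pi, target) {
    f <- function(g) (1 - pi) * plogis(g) + pi * plogis(g + gamma2) - target
    r <- uniroot(f, interval = c(-40, 40), tol = .Machine$double.eps^0.75,
                 extendInt = "upX")
    if (abs(f(r$root)) > 1e-10)
      stop("MAR calibration failed to reach the target rate")
    r$root
  }
  gamma1 <- solve_intercept(pi_c, target_control_rate)
  gamma3 <- solve_intercept(pi_t, target_treatment_rate) - gamma1
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 target_control_rate = target_control_rate,
                 target_treatment_rate = target_treatment_rate,
                 pi_control = pi_c, pi_treatment = pi_t),
            class = "missingness_model")
}

#' @export
print.missingness_model <- function(x, ...) {
  cat(sprintf(
    "MAR dropout model: logit Pr(missing) = %.4f %+.4f y_prev %+.4f X\n",
    x$gamma1, x$gamma2, x$gamma3))
  cat(sprintf("  targets: control %.0f%%, treatment %.0f%%\n",
              100 * x$target_control_rate, 100 * x$target_treatment_rate))
  invisible(x)
}

#' Expected per-arm dropout rates under a calibrated MAR model
#'
#' @param model a [calibrate_mar()] result.
#' @return named numeric vector `c(control =, treatment =)` of expected rates.
#' @export
expected_mar_rates <- function(model) {
  c(control = (1 - model$pi_control) * plogis(model$gamma1) +
      model$pi_control * plogis(model$gamma1 + model$gamma2),
    treatment = (1 - model$pi_treatment) *
      plogis(model$gamma1 + model$gamma3) +
      model$pi_treatment * plogis(model$gamma1 + model$gamma2 + model$gamma3))
}

#' Delete final-visit outcomes under the MAR model
#'
#' Each subject's final-visit record is flagged missing independently with
#' probability `plogis(gamma1 + gamma2 * y_prev + gamma3 * X)`, where
#' `y_prev` is the subject's outcome at the penultimate visit. Earlier visits
#' are untouched.
#'
#' @param data a `trial_data` data frame with complete final-visit records.
#' @param model a calibrated [calibrate_mar()] model.
#' @return the data with `missing` flags set at the final visit.
#' @export
apply_mar <- function(data, model) {
  stopifnot(inherits(model, "missingness_model"))
  v_final <- max(data$visit)
  idx3 <- which(data$visit == v_final)
  idx2 <- which(data$visit == v_final - 1L)
  # rows are grouped by subject with visits in order, so idx2/idx3 align
  stopifnot(identical(data$subject[idx3], data$subject[idx2]))
  pr <- plogis(model$gamma1 + model$gamma2 * data$y[idx2] +
               model$gamma3 * data$arm[idx3])
  data$missing[idx3] <- rbinom(length(idx3), 1L, pr) == 1L
  data
}
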