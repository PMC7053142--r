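#' Solve Beta distribution parameters from prevalence and correlation
#'
#' The subject-level baseline event probability is drawn from a Beta(a, b)
#' distribution. Its mean fixes the prevalence, `a / (a + b)`, and the
#' exchangeable within-subject correlation of repeated Bernoulli outcomes with
#' a shared subject probability is `rho = 1 / (1 + a + b)`. Inverting the two
#' moment equations gives the closed form `a + b = 1/rho - 1`,
#' `a = prevalence * (a + b)`.
#'
#' @param prevalence target mean of the Beta distribution, in (0,1).
#' @param rho target within-subject correlation, in (0,1).
#' @return object of class `beta_params`: list with positive elements `a`, `b`.
#' @export
#' @examples
#' solve_beta_params(0.1, 0.3)  # a = 7/30, b = 2.1
solve_beta_params <- function(prevalence, rho) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be a single value strictly between 0 and 1")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("`rho` must be a single value strictly between 0 and 1 ",
         "(a + b = 1/rho - 1 must be positive and finite)")
  s <- 1 / rho - 1
  structure(list(a = prevalence * s, b = (1 - prevalence) * s),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(a = %.6g, b = %.6g): mean %.6g, correlation %.6g\n",
              x$a, x$b, x$a / (x$a + x$b), 1 / (1 + x$a + x$b)))
  invisible(x)
}

#' Two-proportion sample size without continuity correction
#'
#' Total sample size for a two-sided two-proportion z-test at 1:1 allocation,
#' pooled-variance form, no continuity correction: the per-arm size is
#' \deqn{n = \frac{\{z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{1-\beta}\sqrt{p_1 q_1 + p_2 q_2}\}^2}{(p_1 - p_2)^2}}
#' rounded up, and the total is twice that. Detecting 0.1 versus 0.2 at 80%
#' power and alpha 0.05 gives 398; 0.5 versus 0.6 gives 776.
#'
#' @param p_control,p_treatment event probabilities in the two arms.
#' @param power target power, default 0.80.
#' @param alpha two-sided significance level, default 0.05.
#' @return total sample size (integer, even).
#' @export
#' @examples
#' required_sample_size(0.1, 0.2)  # 398
required_sample_size <- function(p_control, p_treatment,
                                 power = 0.80, alpha = 0.05) {
  stopifnot(p_control > 0, p_control < 1, p_treatment > 0, p_treatment < 1,
            power > 0, power < 1, alpha > 0, alpha < 1)
  if (p_control == p_treatment)
    stop("`p_control` and `p_treatment` must differ (sample size is infinite)")
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  p_bar <- (p_control + p_treatment) / 2
  n_arm <- (z_a * sqrt(2 * p_bar * (1 - p_bar)) +
            z_b * sqrt(p_control * (1 - p_control) +
                       p_treatment * (1 - p_treatment)))^2 /
           (p_control - p_treatment)^2
  2L * as.integer(ceiling(n_arm))
}

#' Generate one complete longitudinal binary trial replicate
#'
#' For each subject a baseline event probability `p_i1` is drawn from
#' Beta(a, b); the visit-1 outcome is Bernoulli(`p_i1`). At each later visit
#' the probability increments by `delta` in the treatment arm only,
#' `p_ij = p_i(j-1) + delta * X_i`, and a fresh Bernoulli outcome is drawn.
#' Under the null hypothesis the probability stays at `p_i1` for every visit
#' in both arms. The first half of subjects form the treatment arm, the
#' second half the control arm (exchangeable with randomization because
#' subjects are i.i.d.). Draws use the current RNG state; seed beforehand
#' for reproducibility.
#'
#' Under the alternative the Beta draw can land so close to 1 that the
#' incremented trajectory would leave \[0, 1\] (a material fraction of
#' subjects when the Beta is U-shaped, e.g. prevalence 0.5 with correlation
#' 0.7). The baseline probability is therefore capped at
#' `1 - delta * (n_visits - 1)` in both arms, which keeps every trajectory a
#' valid probability while preserving the full end-of-study risk difference
#' `delta * (n_visits - 1)` between arms; the capped fraction is recorded in
#' the `clipped_frac` attribute. Capping both arms keeps the baseline
#' distribution exchangeable across arms, as randomization requires.
#'
#' @param config a [scenario_config()].
#' @param beta optional [solve_beta_params()] result; computed from the config
#'   when `NULL`.
#' @return data frame of class `trial_data` in long format with columns
#'   `subject`, `arm` (1 treatment, 0 control), `visit` (1..n_visits), `p`
#'   (latent per-visit event probability), `y` (0/1 outcome) and `missing`
#'   (all `FALSE`). The fraction of probability increments that required
#'   clipping is attached as attribute `clipped_frac`.
#' @export
#' @examples
#' set.seed(1)
#' td <- generate_complete_replicate(scenario_config(0.1, 0.3, n_reps = 1))
#' head(td)
generate_complete_replicate <- function(config, beta = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(beta)) beta <- solve_beta_params(config$prevalence, config$rho)
  n <- config$n_total
  J <- config$n_visits
  arm <- rep(c(1L, 0L), each = n %/% 2L)
  delta <- if (config$hypothesis == "null") 0 else config$delta

  P <- matrix(0, n, J)
  p1 <- rbeta(n, beta$a, beta$b)
  cap <- 1 - delta * (J - 1L)
  n_clipped <- sum(p1 > cap)
  P[, 1L] <- pmin(p1, cap)
  for (j in 2:J) P[, j] <- P[, j - 1L] + delta * arm
  Y <- matrix(rbinom(n * J, 1L, as.vector(P)), n, J)

  out <- data.frame(
    subject = rep(seq_len(n), each = J),
    arm = rep(arm, each = J),
    visit = rep(seq_len(J), times = n),
    p = as.vector(t(P)),
    y = as.integer(t(Y)),
    missing = FALSE)
  attr(out, "clipped_frac") <- n_clipped / n
  class(out) <- c("trial_data", "data.frame")
  out
}
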