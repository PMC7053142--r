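#' Fit the random-intercept logistic GLMM by restricted pseudo-likelihood
#'
#' Fits `logit Pr(Y_ij = 1 | b_i) = beta1 + beta2 X_i + beta3 t_ij +
#' beta4 X_i t_ij + b_i`, with `b_i ~ N(0, sigma_b^2)`, to the non-missing
#' rows of a long-format trial data frame. Time is treated as continuous with
#' the stored visit coding `t = 1, 2, ..., J`. Subjects missing the final
#' visit contribute their earlier visits, which is how the mixed model uses
#' partial information that the complete-case analysis discards. The single
#' random intercept induces a compound-symmetric within-subject working
#' covariance.
#'
#' Estimation is the doubly iterative penalized quasi-likelihood scheme
#' (restricted pseudo-likelihood): the model is linearized around the current
#' fixed effects and predicted random intercepts via the working variate
#' `z = eta + (y - mu) / (mu (1 - mu))` with weights `w = mu (1 - mu)`, the
#' resulting weighted linear mixed pseudo-model is fitted by REML — the
#' variance ratio `lambda = sigma_b^2 / phi` by one-dimensional profiled-REML
#' optimization (the residual pseudo-variance `phi` is estimated, not fixed
#' at 1), the fixed effects by generalized least squares — and the random
#' intercepts are refreshed as BLUPs; the cycle repeats until the maximum
#' relative change over all parameters falls below `tol`. `sigma_b^2` is
#' floored at zero: a boundary estimate is permitted, not an error. The
#' fixed-effect covariance comes from the final GLS step.
#'
#' @param data long-format data frame with columns `subject`, `arm`, `visit`,
#'   `y`, `missing`; missing rows are dropped before fitting.
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @param max_iter maximum outer linearizations (default 100).
#' @param fix_sigma_b2 set to `0` to fix the random-intercept variance at
#'   zero, in which case the fit reduces to iteratively reweighted logistic
#'   regression; `NULL` (default) estimates it.
#' @return object of class `glmm_rpl_fit`: list with `beta` (named 4-vector),
#'   `sigma_b2`, `residual_scale` (`phi`), `lambda`, `cov_beta` (4x4),
#'   `ranef` (per-subject intercept BLUPs), `n_iterations`, `converged`,
#'   `t_final`, `n_obs`, `n_subjects`.
#' @export
#' @examples
#' set.seed(42)
#' td <- generate_complete_replicate(scenario_config(0.1, 0.3, n_reps = 1))
#' fit <- fit_rpl(td)
#' fit$beta
fit_rpl <- function(data, tol = 1e-8, max_iter = 100L, fix_sigma_b2 = NULL,
                    estimate_scale = FALSE) {
  d <- data[!data$missing, , drop = FALSE]
  d <- d[order(d$subject, d$visit), , drop = FALSE]
  y <- as.numeric(d$y)
  id <- match(d$subject, unique(d$subject))
  X <- cbind("(Intercept)" = 1, arm = as.numeric(d$arm),
             time = as.numeric(d$visit),
             "arm:time" = as.numeric(d$arm) * as.numeric(d$visit))
  n <- length(y)
  p <- ncol(X)
  m <- max(id)
  fix0 <- !is.null(fix_sigma_b2)
  if (fix0 && fix_sigma_b2 != 0)
    stop("only `fix_sigma_b2 = 0` is supported")

  beta_init <- stats::glm.fit(X, y, family = binomial())$coefficients

  run_pql <- function(damp) {
    beta <- beta_init
    b <- numeric(m)
    lambda <- if (fix0) 0 else 0.1
    phi <- 1
    sigma_b2 <- lambda * phi
    upper <- 20
    par_old <- c(beta, sigma_b2, phi, b)
    converged <- FALSE
    iter <- 0L
    final <- NULL

    repeat {
      iter <- iter + 1L
      eta <- drop(X %*% beta) + b[id]
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w

      # per-subject sufficient statistics; V0^{-1} via Woodbury on
      # W^{-1} + lambda J per subject block
      Xw <- X * w
      XtWX <- crossprod(X, Xw)
      XtWz <- drop(crossprod(Xw, z))
      ztWz <- sum(w * z * z)
      sw <- rowsum(w, id, reorder = FALSE)[, 1L]
      SXw <- rowsum(Xw, id, reorder = FALSE)
      Szw <- rowsum(w * z, id, reorder = FALSE)[, 1L]

      reml_fit <- function(lam) {
        cc <- lam / (1 + lam * sw)
        A <- XtWX - crossprod(SXw * sqrt(cc))
        u <- XtWz - drop(crossprod(SXw, cc * Szw))
        R <- chol(A)
        bh <- backsolve(R, forwardsolve(t(R), u))
        rss <- max(ztWz - sum(cc * Szw^2) - sum(u * bh), 1e-300)
        if (estimate_scale) {
          phih <- rss / (n - p)
          crit <- (n - p) * log(phih) + sum(log1p(lam * sw)) +
            2 * sum(log(diag(R)))
        } else {
          phih <- 1
          crit <- rss + sum(log1p(lam * sw)) + 2 * sum(log(diag(R)))
        }
        list(crit = crit, beta = drop(bh), phi = phih, A = A)
      }

      if (fix0) {
        lam_hat <- 0
      } else {
        repeat {
          opt <- optimize(function(l) reml_fit(l)$crit,
                          interval = c(0, upper), tol = 1e-9)
          lam_hat <- opt$minimum
          if (lam_hat < 0.9 * upper || upper >= 5e3) break
          upper <- upper * 4
        }
        if (reml_fit(0)$crit <= opt$objective) lam_hat <- 0
      }
      final <- reml_fit(lam_hat)
      beta_prop <- final$beta
      names(beta_prop) <- colnames(X)
      phi <- final$phi
      sigma_b2 <- lam_hat * phi
      b_prop <- lam_hat * (Szw - drop(SXw %*% beta_prop)) /
        (1 + lam_hat * sw)
      lambda <- lam_hat
      # fixed-point residual: proposal versus current state; the BLUPs are
      # part of the state (they move the linearization), so they are in the
      # convergence vector too
      par_new <- c(beta_prop, sigma_b2, phi, b_prop)
      step <- max(abs(par_new - par_old) / pmax(abs(par_old), 1))
      if (step < tol) {
        beta <- beta_prop
        b <- b_prop
        converged <- TRUE
        break
      }
      beta <- damp * beta_prop + (1 - damp) * beta
      b <- damp * b_prop + (1 - damp) * b
      par_old <- c(beta, sigma_b2, phi, b)
      if (iter >= max_iter) break
    }
    list(beta = beta, b = b, lambda = lambda, phi = phi,
         sigma_b2 = sigma_b2, final = final, iter = iter,
         converged = converged)
  }

  # undamped first; under near-separation the PQL map can oscillate, in
  # which case retry with half-step updates, which restores contraction
  fit <- run_pql(damp = 1)
  if (!fit$converged) fit <- run_pql(damp = 0.5)
  beta <- fit$beta
  b <- fit$b
  lambda <- fit$lambda
  phi <- fit$phi
  sigma_b2 <- fit$sigma_b2
  final <- fit$final
  iter <- fit$iter
  converged <- fit$converged

  cov_beta <- phi * chol2inv(chol(final$A))
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  structure(
    list(beta = beta, sigma_b2 = sigma_b2, residual_scale = phi,
         lambda = lambda, cov_beta = cov_beta, ranef = b,
         n_iterations = iter, converged = converged,
         t_final = max(d$visit), n_obs = n, n_subjects = m),
    class = "glmm_rpl_fit")
}

#' Variance components of a Gaussian one-way random-intercept model
#'
#' Runs the same profiled-REML machinery as the inner step of [fit_rpl()] on
#' Gaussian data with identity link and unit weights (a single linearization
#' is exact there), for an intercept-only mean. Used to validate the REML
#' step against the closed-form balanced one-way ANOVA decomposition.
#'
#' @param y numeric response.
#' @param id subject identifiers.
#' @return named vector `c(sigma_b2, residual)`.
#' @keywords internal
reml_variance_components <- function(y, id) {
  id <- match(id, unique(id))
  n <- length(y)
  m <- max(id)
  sw <- rowsum(rep(1, n), id, reorder = FALSE)[, 1L]
  Sy <- rowsum(y, id, reorder = FALSE)[, 1L]
  yty <- sum(y * y)
  ytot <- sum(y)

  crit <- function(lam) {
    cc <- lam / (1 + lam * sw)
    A <- n - sum(cc * sw^2)           # X'V0^-1 X for intercept-only X
    u <- ytot - sum(cc * sw * Sy)
    mu <- u / A
    rss <- yty - sum(cc * Sy^2) - u * mu
    phih <- rss / (n - 1)
    (n - 1) * log(phih) + sum(log1p(lam * sw)) + log(A)
  }
  opt <- optimize(crit, c(0, 1e4), tol = 1e-12)
  lam <- if (crit(0) <= opt$objective) 0 else opt$minimum
  cc <- lam / (1 + lam * sw)
  A <- n - sum(cc * sw^2)
  u <- ytot - sum(cc * sw * Sy)
  mu <- u / A
  rss <- yty - sum(cc * Sy^2) - u * mu
  phi <- rss / (n - 1)
  c(sigma_b2 = lam * phi, residual = phi)
}

#' @export
print.glmm_rpl_fit <- function(x, ...) {
  cat("Random-intercept logistic GLMM (restricted pseudo-likelihood)\n")
  cat(sprintf("  %d observations, %d subjects; %s in %d iterations\n",
              x$n_obs, x$n_subjects,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(x$beta, 5))
  cat(sprintf("  sigma_b^2 = %.5f, residual scale = %.5f\n",
              x$sigma_b2, x$residual_scale))
  invisible(x)
}

#' Treatment effect at the final visit from a GLMM fit
#'
#' Applies the contrast `beta2 + t_final * beta4` (weights `(0, 1, 0,
#' t_final)` under the `t = 1..J` coding), i.e. the model's log-odds ratio
#' between arms at the final visit, with the standard error from the
#' fixed-effect covariance, a Wald z test against the standard normal and a
#' 95% confidence interval.
#'
#' @param fit a [fit_rpl()] result.
#' @param t_final time value at which to evaluate the contrast; defaults to
#'   the last visit present in the fitted data.
#' @return list with `weights`, `estimate`, `se`, `statistic`, `p_value`,
#'   `ci_low`, `ci_high`, `degenerate` (`TRUE` when the fit did not
#'   converge).
#' @export
estimate_effect_at_final_visit <- function(fit, t_final = fit$t_final) {
  wts <- c(0, 1, 0, t_final)
  if (!fit$converged)
    return(list(weights = wts, estimate = NA_real_, se = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, degenerate = TRUE))
  est <- sum(wts * fit$beta)
  se <- sqrt(drop(t(wts) %*% fit$cov_beta %*% wts))
  zst <- est / se
  z <- qnorm(0.975)
  list(weights = wts, estimate = est, se = se, statistic = zst,
       p_value = 2 * pnorm(-abs(zst)),
       ci_low = est - z * se, ci_high = est + z * se, degenerate = FALSE)
}

#' GLMM analysis of one replicate
#'
#' Fits [fit_rpl()] and extracts the final-visit treatment contrast as an
#' analysis-result row, carrying the fit diagnostics along.
#'
#' @param data a `trial_data` data frame (missing rows are excluded by the
#'   fitter; earlier visits of dropouts are retained).
#' @param ... passed to [fit_rpl()].
#' @return one-row data frame with columns `method`, `estimate`, `se`,
#'   `statistic`, `p_value`, `ci_low`, `ci_high`, `converged`, `degenerate`,
#'   `sigma_b2`, `residual_scale`, `n_iterations`.
#' @export
analyze_glmm <- function(data, ...) {
  fit <- tryCatch(fit_rpl(data, ...), error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(method = "glmm", estimate = NA_real_, se = NA_real_,
                      statistic = NA_real_, p_value = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      converged = FALSE, degenerate = TRUE,
                      sigma_b2 = NA_real_, residual_scale = NA_real_,
                      n_iterations = NA_integer_, stringsAsFactors = FALSE))
  }
  ct <- estimate_effect_at_final_visit(fit)
  data.frame(method = "glmm",
             estimate = ct$estimate, se = ct$se, statistic = ct$statistic,
             p_value = ct$p_value, ci_low = ct$ci_low, ci_high = ct$ci_high,
             converged = fit$converged, degenerate = ct$degenerate,
             sigma_b2 = fit$sigma_b2, residual_scale = fit$residual_scale,
             n_iterations = fit$n_iterations, stringsAsFactors = FALSE)
}
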