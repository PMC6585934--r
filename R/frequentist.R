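# Frequentist variant: ordinary least squares with year and stratum dummies.

#' Fit the panel model by OLS with fixed effects
#'
#' The frequentist counterpart of the Bayesian fit: ordinary least squares of
#' the change in log mortality on the change in log spending, optionally its
#' lag, and full sets of year and stratum dummies (treatment coding, one
#' reference level per block). Year and stratum heterogeneity is thus fixed
#' rather than random.
#'
#' @param frame A `model_frame`.
#' @param include_lag Include the lagged spending term?
#' @return An object of class `frequentist_fit`: list with `coefficients`,
#'   `vcov` (symmetric PSD), `sigma` (residual SD), `df_residual`, and the
#'   fitted `lm` object.
#' @export
fit_frequentist <- function(frame, include_lag = TRUE) {
  stopifnot(inherits(frame, "model_frame"))
  d <- as.data.frame(frame)
  d$year_f <- factor(d$year_id)
  d$stratum_f <- factor(d$stratum_id)
  terms <- c("dlog_c", if (include_lag) "dlog_c_lag",
             if (nlevels(d$year_f) > 1) "year_f",
             if (nlevels(d$stratum_f) > 1) "stratum_f")
  fml <- stats::reformulate(terms, response = "dlog_m")
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop_kthresh(paste("rank-deficient design; collinear columns:",
                       paste(bad, collapse = ", ")))
  }
  V <- vcov(fit)
  structure(list(coefficients = cf, vcov = V,
                 sigma = summary(fit)$sigma,
                 df_residual = fit$df.residual,
                 include_lag = include_lag, lm = fit),
            class = "frequentist_fit")
}

#' Sample elasticity draws from a frequentist fit
#'
#' Draws coefficient vectors for (alpha, beta) from the multivariate normal
#' sampling distribution implied by the OLS estimates and their covariance,
#' giving the translation step a draw set analogous to a posterior.
#'
#' @param fit A `frequentist_fit`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data frame with columns `alpha`, optionally `beta`, and
#'   `elasticity` (their sum).
#' @export
sample_frequentist <- function(fit, n = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "frequentist_fit"))
  keep <- c("dlog_c", if (fit$include_lag) "dlog_c_lag")
  mu <- fit$coefficients[keep]
  V <- fit$vcov[keep, keep, drop = FALSE]
  set.seed(seed %% .Machine$integer.max)
  L <- chol((V + t(V)) / 2)
  Z <- matrix(rnorm(n * length(mu)), n)
  draws <- sweep(Z %*% L, 2, mu, "+")
  out <- data.frame(alpha = draws[, 1])
  if (fit$include_lag) {
    out$beta <- draws[, 2]
    out$elasticity <- draws[, 1] + draws[, 2]
  } else out$elasticity <- draws[, 1]
  out
}
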