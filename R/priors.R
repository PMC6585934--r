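# Prior specifications for the panel model.

#' Prior specification
#'
#' Normal priors for the drift and the two elasticities, uniform priors for
#' the three standard deviations. A degenerate uniform (`lo == hi`) fixes
#' that standard deviation at the common value, which is how the conjugate
#' closed-form checks pin the sigmas.
#'
#' @param mu_prior,alpha_prior,beta_prior Length-2 numeric `c(mean, sd)`,
#'   sd > 0.
#' @param sigma_m_prior,sigma_gamma_prior,sigma_tau_prior Length-2 numeric
#'   `c(lo, hi)` with `0 <= lo <= hi`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_prior = c(0, sqrt(10)),
                       alpha_prior = c(0, sqrt(10)),
                       beta_prior = c(0, sqrt(10)),
                       sigma_m_prior = c(0, 1),
                       sigma_gamma_prior = c(0, 1),
                       sigma_tau_prior = c(0, 1)) {
  chk_norm <- function(x, nm) {
    if (length(x) != 2 || !all(is.finite(x)) || x[2] <= 0)
      stop_kthresh(sprintf("%s must be c(mean, sd) with sd > 0", nm))
  }
  chk_unif <- function(x, nm) {
    if (length(x) != 2 || !all(is.finite(x)) || x[1] < 0 || x[2] < x[1])
      stop_kthresh(sprintf("%s must be c(lo, hi) with 0 <= lo <= hi", nm))
  }
  chk_norm(mu_prior, "mu_prior")
  chk_norm(alpha_prior, "alpha_prior")
  chk_norm(beta_prior, "beta_prior")
  chk_unif(sigma_m_prior, "sigma_m_prior")
  chk_unif(sigma_gamma_prior, "sigma_gamma_prior")
  chk_unif(sigma_tau_prior, "sigma_tau_prior")
  structure(list(mu_prior = mu_prior, alpha_prior = alpha_prior,
                 beta_prior = beta_prior, sigma_m_prior = sigma_m_prior,
                 sigma_gamma_prior = sigma_gamma_prior,
                 sigma_tau_prior = sigma_tau_prior),
            class = "prior_spec")
}

#' Construct the study's prior styles
#'
#' `style = "vague"` gives the base-case priors: normal(0, variance 10) for
#' the drift and both elasticities ("variance of 10" is read literally as a
#' variance, so sd = sqrt(10)), and uniform(0, 1) for all three standard
#' deviations. `style = "elasticity_interval"` encodes external evidence on
#' the instantaneous elasticity as a normal prior whose mean is the reported
#' point estimate and whose sd is recovered from a reported 95% interval:
#' `sd = (hi - lo) / (2 * 1.959964)`; all other priors stay vague.
#'
#' @param style `"vague"` or `"elasticity_interval"`.
#' @param mean Prior mean for the instantaneous elasticity
#'   (elasticity_interval only).
#' @param ci95 Length-2 `c(lo, hi)` 95% interval, `lo < hi`
#'   (elasticity_interval only).
#' @return A [prior_spec()].
#' @examples
#' make_prior("vague")
#' # meta-analytic total-spending evidence
#' make_prior("elasticity_interval", mean = -0.13, ci95 = c(-0.20, -0.06))
#' @export
make_prior <- function(style = c("vague", "elasticity_interval"),
                       mean = NULL, ci95 = NULL) {
  style <- match.arg(style)
  if (style == "vague") return(prior_spec())
  if (is.null(mean) || is.null(ci95) || length(ci95) != 2 ||
      !all(is.finite(ci95)) || ci95[1] >= ci95[2])
    stop_kthresh("elasticity_interval needs 'mean' and ci95 = c(lo, hi) with lo < hi")
  sd <- (ci95[2] - ci95[1]) / (2 * qnorm(0.975))
  prior_spec(alpha_prior = c(mean, sd))
}
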