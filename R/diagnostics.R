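# Convergence diagnostics: split-chain potential scale reduction, effective
# sample size (Geyer initial-monotone-sequence estimator on split chains),
# and a lag-k autocorrelation table.

split_chains <- function(mat) {
  # mat: n x m (iterations x chains) -> n/2 x 2m
  n <- nrow(mat)
  h <- n %/% 2L
  if (h < 1) return(mat)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1L, n), , drop = FALSE])
}

rhat_split <- function(mat) {
  sm <- split_chains(mat)
  n <- nrow(sm); m <- ncol(sm)
  if (n < 2 || m < 2) return(NA_real_)
  mns <- colMeans(sm)
  vars <- apply(sm, 2, var)
  W <- mean(vars)
  B <- n * var(mns)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_split <- function(mat, max_lag = 500L) {
  sm <- split_chains(mat)
  n <- nrow(sm); m <- ncol(sm)
  total <- n * m
  vars <- apply(sm, 2, var)
  W <- mean(vars)
  mns <- colMeans(sm)
  B <- if (m > 1) n * var(mns) else 0
  var_hat <- (n - 1) / n * W + B / n
  if (!is.finite(var_hat) || var_hat <= 0) return(1)  # constant chains
  L <- min(n - 1L, max_lag)
  # mean autocovariance across chains at lags 0..L
  acov <- matrix(0, L + 1L, m)
  for (j in seq_len(m)) {
    a <- acf(sm[, j], lag.max = L, type = "covariance", plot = FALSE,
             demean = TRUE)
    acov[, j] <- a$acf[, 1, 1]
  }
  rho <- 1 - (W - rowMeans(acov)) / var_hat   # rho[1] is lag 0 (=1 approx)
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0
  prev_pair <- Inf
  k <- 2L
  repeat {
    if (k > length(rho)) break
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + pair
    prev_pair <- pair
    k <- k + 2L
  }
  tau_total <- 1 + 2 * tau
  min(total, total / max(tau_total, 1e-12))
}

#' Convergence diagnostics for posterior draws
#'
#' Computes, per parameter, the split-chain potential scale reduction
#' statistic (each retained chain is split in half; reported as `NA` for a
#' single chain), the effective sample size (Geyer initial-monotone paired
#' autocorrelation sum on split chains, capped at the retained draw count;
#' a numerically constant chain is reported as ESS 1 and flagged), and
#' pooled autocorrelations at lags 1..`n_lags`.
#'
#' @param draws A `posterior_draws` (or `mcmc_fit`).
#' @param n_lags Number of autocorrelation lags to tabulate.
#' @return An object of class `fit_diagnostics`: list with `summary` (data
#'   frame: parameter, rhat, ess, flag) and `autocorr` (matrix lags x
#'   parameters).
#' @export
diagnose <- function(draws, n_lags = 10L) {
  if (inherits(draws, "mcmc_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "posterior_draws"))
  pars <- setdiff(names(draws), c("chain", "iteration"))
  n_chains <- attr(draws, "n_chains") %||% length(unique(draws$chain))
  n_keep <- attr(draws, "n_keep") %||% max(draws$iteration)

  res <- lapply(pars, function(pn) {
    mat <- matrix(draws[[pn]], nrow = n_keep, ncol = n_chains)
    constant <- all(mat == mat[1])
    rh <- if (n_chains >= 2) rhat_split(mat) else NA_real_
    es <- if (constant) 1 else ess_split(mat)
    L <- min(n_lags, n_keep - 1L)
    ac <- if (constant || L < 1) rep(NA_real_, n_lags) else {
      a <- rowMeans(vapply(seq_len(n_chains), function(j) {
        acf(mat[, j], lag.max = L, plot = FALSE, demean = TRUE)$acf[-1, 1, 1]
      }, numeric(L)))
      c(a, rep(NA_real_, n_lags - L))
    }
    flag <- if (constant) "constant chain (degenerate)" else ""
    list(rhat = rh, ess = es, ac = ac, flag = flag)
  })
  summary <- data.frame(
    parameter = pars,
    rhat = vapply(res, `[[`, 0, "rhat"),
    ess = vapply(res, `[[`, 0, "ess"),
    flag = vapply(res, `[[`, "", "flag"),
    stringsAsFactors = FALSE
  )
  autocorr <- vapply(res, `[[`, numeric(n_lags), "ac")
  if (is.null(dim(autocorr))) autocorr <- matrix(autocorr, nrow = n_lags)
  dimnames(autocorr) <- list(paste0("lag_", seq_len(n_lags)), pars)
  structure(list(summary = summary, autocorr = autocorr),
            class = "fit_diagnostics")
}
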