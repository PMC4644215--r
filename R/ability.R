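#' EAP of exp(theta) at a given sum score
#'
#' By the Dutch identity, `E[exp(Theta) | X+ = s, b, lambda] =
#' lambda_(s+1)/lambda_s`.  Its posterior mean is estimated by averaging
#' that ratio over the retained draws.  The expectation for a perfect score
#' (`s = n`) cannot be estimated and returns `NA`.
#'
#' @param draws a `gibbs_draws` object from [gibbs_run()].
#' @param s sum score(s) in `0..n-1`; vectorized.
#' @return posterior mean(s) of `exp(Theta)` given `X+ = s`; `NA` where
#'   unavailable.
#' @export
eap_exp_theta <- function(draws, s) {
  draws <- retained(draws)
  n <- draws$n
  if (any(s < 0 | s > n)) stop("score out of range 0..n")
  vapply(s, function(si) {
    if (si > n - 1L) return(NA_real_)
    mean(draws$lambda[, si + 2L] / draws$lambda[, si + 1L])
  }, 0)
}

#' Posterior variance of exp(theta) at a given sum score, decomposed
#'
#' Total posterior variance of `exp(Theta)` given `X+ = s` splits into a
#' parameter-uncertainty component (variance over draws of
#' `lambda_(s+1)/lambda_s`, which vanishes as the number of respondents
#' grows) and a finite-test-length component (posterior mean of
#' `lambda_(s+2)/lambda_s - (lambda_(s+1)/lambda_s)^2`, which vanishes as
#' the number of items grows).  Variances over draws use the `1/K`
#' (population) denominator so a degenerate single-draw posterior reports
#' zero parameter uncertainty.
#'
#' @inheritParams eap_exp_theta
#' @param s a single sum score in `0..n-2`.
#' @return list with `parameter_uncertainty`, `finite_test`, and `total`
#'   (their sum); all `NA` when `s > n - 2`.
#' @export
posterior_variance_exp_theta <- function(draws, s) {
  draws <- retained(draws)
  n <- draws$n
  if (length(s) != 1L || s < 0 || s > n) stop("score out of range 0..n")
  if (s > n - 2L)
    return(list(parameter_uncertainty = NA_real_, finite_test = NA_real_,
                total = NA_real_, available = FALSE))
  r1 <- draws$lambda[, s + 2L] / draws$lambda[, s + 1L]
  r2 <- draws$lambda[, s + 3L] / draws$lambda[, s + 1L]
  pu <- mean((r1 - mean(r1))^2)
  ft <- mean(r2 - r1^2)
  list(parameter_uncertainty = pu, finite_test = ft, total = pu + ft,
       available = TRUE)
}

#' Log-normal back-transform of exp(theta) moments
#'
#' If the posterior of `theta` at a score is approximately normal with mean
#' `mu_s` and variance `sigma2_s`, then `E[exp(Theta)] = exp(mu + sigma2/2)`
#' and `E[exp(Theta)^2] = exp(2 mu + 2 sigma2)`; inverting gives
#' `sigma2_s = ln E2 - 2 ln E1` and `mu_s = 2 ln E1 - (ln E2)/2`.  These
#' are approximations, valid only where the normal approximation holds.
#'
#' @param E1 posterior mean of `exp(Theta)`, positive.
#' @param E2 posterior mean of `exp(Theta)^2`; must satisfy `E2 >= E1^2`.
#' @return list with `mu` and `sigma2`.
#' @export
lognormal_theta_summary <- function(E1, E2) {
  if (any(E1 <= 0)) stop("E1 must be positive")
  if (any(E2 < E1^2)) stop("inconsistent moments: E2 < E1^2")
  list(mu = 2 * log(E1) - log(E2) / 2, sigma2 = log(E2) - 2 * log(E1))
}

#' Score-indexed ability summary table
#'
#' Per sum score: the EAP of `exp(theta)`, the decomposed posterior
#' variance, and the approximate normal-scale summaries `mu_s`,
#' `sigma2_s`.  All quantities are computed per retained draw and then
#' aggregated (the estimands are posterior functionals of lambda ratios,
#' not ratios of aggregated lambdas).  The mean needs `s <= n - 1`, the
#' variance and the normal-scale approximations need `s <= n - 2`; rows
#' beyond that carry `NA`.  The `mu`/`sigma2` columns are approximations
#' under posterior normality of `theta`; the `approx` column flags them.
#'
#' @inheritParams eap_exp_theta
#' @return `data.frame` with one row per score `0..n`.
#' @export
ability_summary <- function(draws) {
  draws <- retained(draws)
  n <- draws$n
  out <- data.frame(score = 0:n, eap_exp_theta = NA_real_,
                    var_parameter = NA_real_, var_finite_test = NA_real_,
                    var_total = NA_real_, mu = NA_real_, sigma2 = NA_real_,
                    approx = NA)
  for (s in 0:n) {
    if (s <= n - 1L)
      out$eap_exp_theta[s + 1L] <- eap_exp_theta(draws, s)
    if (s <= n - 2L) {
      v <- posterior_variance_exp_theta(draws, s)
      out$var_parameter[s + 1L] <- v$parameter_uncertainty
      out$var_finite_test[s + 1L] <- v$finite_test
      out$var_total[s + 1L] <- v$total
      E1 <- out$eap_exp_theta[s + 1L]
      E2 <- mean(draws$lambda[, s + 3L] / draws$lambda[, s + 1L])
      if (E2 >= E1^2) {
        ln <- lognormal_theta_summary(E1, E2)
        out$mu[s + 1L] <- ln$mu
        out$sigma2[s + 1L] <- ln$sigma2
        out$approx[s + 1L] <- TRUE
      }
    }
  }
  out
}
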