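#' @keywords internal
check_item_params <- function(b) {
  if (!is.numeric(b) || length(b) < 1L || anyNA(b) ||
      any(!is.finite(b)) || any(b <= 0))
    stop("item easiness parameters must be positive and finite")
  invisible(b)
}

#' @keywords internal
check_score_params <- function(lambda, n) {
  if (!is.numeric(lambda) || anyNA(lambda) || any(lambda < 0))
    stop("score parameters must be non-negative")
  if (!missing(n) && length(lambda) != n + 1L)
    stop("score parameter vector must have length n + 1")
  if (all(lambda == 0))
    stop("at least one score parameter must be positive")
  invisible(lambda)
}

#' Log probability of a response pattern under the extended marginal Rasch
#' model
#'
#' Evaluates `log P(x | b, lambda)` with
#' `P(x) = prod_i b_i^(x_i) * lambda_(x+) / sum_s gamma_s(b) lambda_s`.
#' A pattern whose score has `lambda = 0` is impossible and yields `-Inf`.
#'
#' @param x binary response vector of length `n`.
#' @param b item easiness parameters, length `n`, all positive.
#' @param lambda score parameters `lambda_0..lambda_n`, non-negative.
#' @return the log probability (a single number).
#' @export
pattern_log_prob <- function(x, b, lambda) {
  check_item_params(b)
  n <- length(b)
  check_score_params(lambda, n)
  if (length(x) != n || anyNA(x) || !all(x %in% c(0, 1)))
    stop("x must be a binary vector matching the number of items")
  logz <- lse(esf_log(b) + log(lambda))
  sum(x * log(b)) + log(lambda[sum(x) + 1L]) - logz
}

#' Manifest score distribution
#'
#' The probability of each sum score,
#' `pi_s = gamma_s(b) lambda_s / sum_t gamma_t(b) lambda_t`.
#'
#' @inheritParams pattern_log_prob
#' @return numeric vector of length `n + 1` summing to one; element `s + 1`
#'   is `P(X+ = s)`.
#' @export
score_distribution <- function(b, lambda) {
  check_item_params(b)
  check_score_params(lambda, length(b))
  lp <- esf_log(b) + log(lambda)
  exp(lp - lse(lp))
}

#' Conditional probability of a pattern given its score
#'
#' `log [ prod_i b_i^(x_i) / gamma_(x+)(b) ]`: the conditional-likelihood
#' factor of the model, free of the score parameters.  This is the
#' distribution used by conditional maximum likelihood estimation.
#'
#' @inheritParams pattern_log_prob
#' @return the log conditional probability.
#' @export
conditional_pattern_log_prob <- function(x, b) {
  check_item_params(b)
  if (length(x) != length(b) || anyNA(x) || !all(x %in% c(0, 1)))
    stop("x must be a binary vector matching the number of items")
  sum(x * log(b)) - esf_log(b)[sum(x) + 1L]
}

#' Item-rest regression function
#'
#' Probability of a correct response to an item with easiness `b_i` given
#' that the remaining items yield rest score `s`:
#' `P = b_i tau_s / (1 + b_i tau_s)` where `tau_s` is the posterior mean of
#' `exp(theta)` at rest score `s` (computed on the model with the item
#' removed).  The probability depends on the other items only through the
#' rest score.
#'
#' @param b_i item easiness, positive.  Recycled against `tau_rest`.
#' @param tau_rest value(s) of `tau` at the rest score, non-negative.
#' @return probability (vectorized).
#' @export
item_rest_probability <- function(b_i, tau_rest) {
  if (any(b_i <= 0)) stop("item easiness must be positive")
  if (any(tau_rest < 0)) stop("tau must be non-negative")
  bt <- b_i * tau_rest
  ifelse(is.infinite(bt), 1, bt / (1 + bt))
}

#' Marginalize an item out of the model
#'
#' Removing item `i` from an extended marginal Rasch model gives another
#' extended marginal Rasch model over the remaining items, with score
#' parameters `lambda'_s = lambda_s + lambda_(s+1) * b_i` (taking
#' `lambda_(n+1) = 0`).
#'
#' @inheritParams pattern_log_prob
#' @param i index of the item to collapse out.
#' @return list with components `b` (length `n - 1`) and `lambda`
#'   (length `n`).
#' @export
collapse_item <- function(b, lambda, i) {
  check_item_params(b)
  n <- length(b)
  if (n < 2L) stop("need at least two items")
  check_score_params(lambda, n)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop("item index out of range")
  list(b = b[-i],
       lambda = lambda[1:n] + c(lambda[2:(n + 1L)]) * b[i])
}

#' Score parameters to EAP (tau) parameters and back
#'
#' `tau_s = lambda_(s+1) / lambda_s` is, by the Dutch identity, the
#' posterior expectation of `exp(theta)` for a respondent with sum score
#' `s` (`s = 0..n-1`; the expectation for a perfect score cannot be
#' estimated).  Ratios with a zero denominator are flagged unavailable
#' (`NA`).  `tau_to_lambda()` inverts the map given `lambda_0`.
#'
#' @param lambda score parameters `lambda_0..lambda_n`.
#' @return for `lambda_to_tau()`: numeric vector `tau_0..tau_(n-1)` with
#'   `NA` for unavailable entries.
#' @export
lambda_to_tau <- function(lambda) {
  check_score_params(lambda)
  num <- lambda[-1L]
  den <- lambda[-length(lambda)]
  tau <- num / den
  tau[den == 0] <- NA_real_
  tau
}

#' @rdname lambda_to_tau
#' @param tau tau parameters `tau_0..tau_(n-1)`, positive.
#' @param lambda0 value of `lambda_0` (default 1, the identified value).
#' @return for `tau_to_lambda()`: score parameters of length
#'   `length(tau) + 1`.
#' @export
tau_to_lambda <- function(tau, lambda0 = 1) {
  if (anyNA(tau) || any(tau < 0)) stop("tau must be non-negative")
  lambda0 * cumprod(c(1, tau))
}

#' Impose the identification constraints
#'
#' The likelihood is invariant under `(b, lambda) -> (c b, lambda_s / c^s)`
#' and under multiplying all `lambda_s` by a constant.  This function
#' rescales so that `b[ref_item] = 1` and `lambda_0 = 1`; pattern
#' probabilities are unchanged.  The map is idempotent.
#'
#' @inheritParams pattern_log_prob
#' @param ref_item index of the reference item (default 1).
#' @return list with rescaled `b` and `lambda`.
#' @export
rescale_identify <- function(b, lambda, ref_item = 1L) {
  check_item_params(b)
  n <- length(b)
  check_score_params(lambda, n)
  if (lambda[1L] <= 0) stop("lambda_0 must be positive to identify")
  cc <- 1 / b[ref_item]
  b2 <- b * cc
  lam2 <- lambda / cc^(0:n)
  list(b = b2, lambda = lam2 / lam2[1L])
}
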