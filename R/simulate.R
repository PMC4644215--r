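#' Ability distributions for simulation and quadrature
#'
#' A lightweight container holding a density and a sampler for the latent
#' ability.  The density must integrate to one on the quadrature grid (a
#' wide fixed grid on `[-8, 8]`); this is checked at construction.
#'
#' @param density function of `theta` returning the density.
#' @param sampler function of `m` returning `m` draws.
#' @param name character label.
#' @param ... parameters stored for provenance.
#' @return an object of class `ability_dist`.
#' @export
ability_dist <- function(density, sampler, name = "custom", ...) {
  g <- quad_grid()
  total <- sum(g$w * density(g$x))
  if (abs(total - 1) > 1e-8)
    stop("density must integrate to 1 on [-8, 8] (got ", total, ")")
  structure(list(density = density, sampler = sampler, name = name,
                 params = list(...)),
            class = "ability_dist")
}

#' @rdname ability_dist
#' @param mean,sd normal parameters (default standard normal).
#' @export
ability_normal <- function(mean = 0, sd = 1) {
  ability_dist(function(th) dnorm(th, mean, sd),
               function(m) rnorm(m, mean, sd),
               name = "normal", mean = mean, sd = sd)
}

# trapezoid grid on [-8, 8]; trapezoid weights on a smooth rapidly decaying
# integrand are spectrally accurate (Euler-Maclaurin), well below 1e-10
quad_grid <- function(nodes = 801L, lower = -8, upper = 8) {
  x <- seq(lower, upper, length.out = nodes)
  h <- x[2L] - x[1L]
  w <- rep(h, nodes); w[c(1L, nodes)] <- h / 2
  list(x = x, w = w)
}

#' Simulate from the latent-trait (marginal Rasch) route
#'
#' Each respondent gets an ability draw from `ability`; responses are then
#' independent Bernoulli with success probability
#' `logistic(theta - delta_i)`.  The defaults emulate the canonical
#' simulation design for this sampler: 30 items with difficulties uniform
#' on (-2, 2) and standard-normal abilities.
#'
#' @param m number of respondents.
#' @param delta item difficulties.
#' @param ability an [ability_dist()].
#' @return binary matrix `m x n` with item columns `item_1..item_n`;
#'   attributes `delta` and `theta` carry the truth.
#' @export
simulate_latent_rasch <- function(m, delta = runif(30, -2, 2),
                                  ability = ability_normal()) {
  stopifnot(m >= 1)
  n <- length(delta)
  theta <- ability$sampler(m)
  p <- plogis(outer(theta, delta, "-"))
  X <- matrix(rbinom(m * n, 1L, p), m, n,
              dimnames = list(NULL, paste0("item_", seq_len(n))))
  attr(X, "delta") <- delta
  attr(X, "theta") <- theta
  X
}

#' Simulate directly from the extended model
#'
#' Draws each respondent's sum score from the manifest score distribution
#' `pi`, then the pattern given the score by the sequential rule
#' `P(x_n = 1 | X+ = s) = b_n gamma_(s-1)(b^(n)) / gamma_s(b)`, recursing
#' over the remaining items.  This route needs no ability distribution and
#' is exact for any non-negative `lambda`.
#'
#' @param m number of respondents.
#' @inheritParams pattern_log_prob
#' @return binary matrix `m x n`.
#' @export
simulate_extended <- function(m, b, lambda) {
  check_item_params(b)
  n <- length(b)
  check_score_params(lambda, n)
  pi_s <- score_distribution(b, lambda)
  s <- sample.int(n + 1L, m, replace = TRUE, prob = pi_s) - 1L
  # prefix log-ESFs: lg[[k]] covers items 1..k
  lg <- vector("list", n + 1L)
  lg[[1L]] <- 0
  for (k in seq_len(n)) lg[[k + 1L]] <- esf_log_cpp(log(b[seq_len(k)]))
  X <- matrix(0L, m, n, dimnames = list(NULL, paste0("item_", seq_len(n))))
  for (k in n:1) {
    cur <- lg[[k + 1L]][s + 1L]                      # log gamma_s(b_1..k)
    prev <- c(-Inf, lg[[k]])[pmax(s, 0L) + 1L]       # log gamma_(s-1)(b_1..k-1)
    prev[s == 0L] <- -Inf
    p1 <- exp(log(b[k]) + prev - cur)
    p1[s > k - 1L] <- 1                              # must be correct
    x <- rbinom(m, 1L, pmin(p1, 1))
    X[, k] <- x
    s <- s - x
  }
  X
}

#' Score parameters implied by an ability distribution
#'
#' Computes `lambda_s = E[exp(s Theta) | X = 0]` by numerical integration
#' of the all-incorrect posterior, for the test with difficulties `delta`.
#' Together with `b = exp(-delta)` these reproduce the latent-route
#' manifest probabilities exactly (up to quadrature error).
#'
#' @param delta item difficulties.
#' @param ability an [ability_dist()].
#' @param nodes quadrature nodes.
#' @return numeric vector `lambda_0..lambda_n` (with `lambda_0 = 1`).
#' @export
lambda_from_ability <- function(delta, ability, nodes = 801L) {
  g <- quad_grid(nodes)
  logw <- logpost0(g$x, delta) + log(ability$density(g$x)) + log(g$w)
  l0 <- lse(logw)
  vapply(0:length(delta), function(s) exp(lse(s * g$x + logw) - l0), 0)
}

# log of prod_i (1 - logistic(theta - delta_i)) = sum_i log logistic(delta_i
# - theta): the all-incorrect likelihood
logpost0 <- function(theta, delta) {
  if (length(delta) == 0L) return(rep(0, length(theta)))
  rowSums(plogis(outer(-theta, -delta, "-"), log.p = TRUE))
}

#' Quadrature oracle for the EAP of exp(theta)
#'
#' `E[exp(Theta) | X+ = s]` computed by direct numerical integration of
#' the score-posterior of ability, independent of the sampler: the weight
#' at `theta` is `exp(s theta) / prod_i (1 + exp(theta - delta_i))` times
#' the ability density.  Monotone non-decreasing in `s` for any design.
#'
#' @param delta item difficulties.
#' @param ability an [ability_dist()].
#' @param s score(s) in `0..n-1` (`s = n` is unavailable and returns `NA`).
#' @param nodes quadrature nodes.
#' @return `E[exp(Theta) | X+ = s]`, vectorized over `s`.
#' @export
quadrature_tau <- function(delta, ability, s, nodes = 801L) {
  n <- length(delta)
  if (any(s < 0 | s > max(n, 0))) stop("score out of range 0..n")
  g <- quad_grid(nodes)
  base <- logpost0(g$x, delta) + log(ability$density(g$x)) + log(g$w)
  vapply(s, function(si) {
    # with no items the prior mean of exp(Theta) is still defined at s = 0
    if (n > 0L && si > n - 1L) return(NA_real_)
    exp(lse((si + 1) * g$x + base) - lse(si * g$x + base))
  }, 0)
}
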