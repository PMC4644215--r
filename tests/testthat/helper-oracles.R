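# Independent brute-force oracles; deliberately naive implementations that
# never touch the package's recursion or linearization code paths.

# ESF by direct subset enumeration
esf_bruteforce <- function(b) {
  n <- length(b)
  vapply(0:n, function(s) {
    if (s == 0) return(1)
    sum(apply(utils::combn(n, s), 2, function(idx) prod(b[idx])))
  }, 0)
}

# polytomous generalized ESF by enumerating all category patterns
esf_poly_bruteforce <- function(weights, b) {
  smax <- sum(vapply(weights, max, 0))
  grid <- expand.grid(lapply(weights, function(w) 0:length(w)))
  gam <- numeric(smax + 1)
  for (r in seq_len(nrow(grid))) {
    sc <- 0; pr <- 1
    for (i in seq_along(weights)) {
      j <- grid[r, i]
      if (j > 0) {
        sc <- sc + weights[[i]][j]
        pr <- pr * b[[i]][j]
      }
    }
    gam[sc + 1] <- gam[sc + 1] + pr
  }
  gam
}

# all 2^n patterns with their extended-model probabilities
all_patterns <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

pattern_probs_bruteforce <- function(b, lambda) {
  pats <- all_patterns(length(b))
  un <- apply(pats, 1, function(x) prod(b^x) * lambda[sum(x) + 1])
  list(patterns = pats, probs = un / sum(un))
}

lse_r <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# quadrature CDF oracle for a density known up to a constant on a log grid
grid_cdf <- function(logf, x) {
  f <- exp(logf - max(logf))
  h <- diff(x)
  inc <- h * (f[-1] + f[-length(f)]) / 2
  cdf <- c(0, cumsum(inc))
  cdf / cdf[length(cdf)]
}

# KS distance between draws and a (grid, cdf) oracle
ks_vs_grid <- function(draws, x, cdf) {
  emp <- stats::ecdf(draws)
  max(abs(emp(x) - cdf))
}

# a small complete-data fixture shared by several tests
make_fixture <- function(n = 5, m = 400, seed = 99) {
  set.seed(seed)
  delta <- seq(-1, 1, length.out = n)
  X <- simulate_latent_rasch(m, delta)
  list(X = X, delta = delta, stats = sufficient_statistics(X))
}

# crude effective sample size from the empirical autocorrelation
ess_acf <- function(x, max_lag = 30) {
  r <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  cut <- which(r < 0.05)[1]
  if (is.na(cut)) cut <- length(r) + 1
  r <- r[seq_len(cut - 1)]
  max(1, length(x) / (1 + 2 * sum(pmax(r, 0))))
}
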