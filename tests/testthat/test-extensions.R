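test_that("NEAT sufficient statistics pool anchors and split the rest", {
  X1 <- cbind(a1 = c(1, 0, 1), a2 = c(0, 0, 1),
              u1 = c(1, 1, 0), u2 = c(0, 1, 1))
  X2 <- cbind(a1 = c(1, 1, 0), a2 = c(1, 0, 0),
              v1 = c(0, 1, 1), v2 = c(1, 1, 0))
  st <- neat_sufficient_statistics(X1, X2)
  expect_equal(st$anchor_ids, c("a1", "a2"))
  expect_equal(st$anchor_totals, c(2 + 2, 1 + 1))
  expect_equal(st$unique1_totals, c(2, 2))
  expect_equal(st$unique2_totals, c(2, 2))
  expect_equal(unname(st$score_counts1), c(0, 0, 2, 1, 0))  # scores 2,2,3
  expect_equal(unname(st$score_counts2), c(0, 1, 0, 2, 0))  # scores 3,3,1
  expect_equal(c(st$m_xy, st$m_xz), c(3, 3))
  # pooled anchor totals are the sum of per-group anchor totals
  expect_equal(st$anchor_totals,
               as.numeric(colSums(X1[, 1:2]) + colSums(X2[, 1:2])))
  # empty second group reduces to complete-design statistics
  st0 <- neat_sufficient_statistics(X1, X1[0, ])
  expect_equal(st0$m_xz, 0)
  expect_equal(st0$anchor_totals, as.numeric(colSums(X1)))
  expect_error(neat_sufficient_statistics(X1[, 1:2],
                                          cbind(b9 = c(1, 0))),
               "anchor")
})

test_that("the anchor full conditional is concave with the stated linear tails", {
  set.seed(91)
  for (r in 1:5) {
    k <- runif(1, 2, 20); a1 <- runif(1, 0.2, 3); a2 <- runif(1, 0.2, 3)
    m1 <- sample(10:40, 1); m2 <- sample(10:40, 1)
    far <- anchor_log_conditional(c(-40, 40), k, a1, a2, m1, m2)
    expect_equal(far$slope[1], (m1 + m2) - k, tolerance = 1e-6)
    expect_equal(far$slope[2], -k, tolerance = 1e-6)
    grid <- seq(-6, 6, by = 0.05)
    lf <- anchor_log_conditional(grid, k, a1, a2, m1, m2)$logf
    expect_true(all(diff(diff(lf)) <= 1e-9))
    # analytic slope agrees with a numeric derivative
    num <- (lf[3:length(lf)] - lf[1:(length(lf) - 2)]) / 0.1
    ana <- anchor_log_conditional(grid[-c(1, length(grid))],
                                  k, a1, a2, m1, m2)$slope
    expect_equal(num, ana, tolerance = 1e-3)
  }
})

test_that("matched-slope Metropolis: exactness at a1 = a2, slope match, oracle law", {
  set.seed(92)
  # a1 = a2: the proposal IS the target, so every proposal is accepted
  for (r in 1:50) {
    up <- mh_update_anchor(runif(1, 0.2, 2), 5, 1.3, 1.3, 10, 7)
    expect_true(up$accepted)
  }
  # slope of the log proposal at the current point matches the target's
  b_i <- 0.7; k <- 5; a1 <- 0.5; a2 <- 2.8; m1 <- 12; m2 <- 9
  r1 <- a1 * b_i / (1 + a1 * b_i); r2 <- a2 * b_i / (1 + a2 * b_i)
  q <- (m1 * r1 + m2 * r2) / (m1 + m2)
  cc <- q / ((1 - q) * b_i)
  slope_g <- -k + (m1 + m2) * cc * b_i / (1 + cc * b_i)
  slope_f <- anchor_log_conditional(-log(b_i), k, a1, a2, m1, m2)$slope
  expect_equal(slope_g, slope_f, tolerance = 1e-12)
  # long-run Metropolis draws match the quadrature-normalized target
  draws <- numeric(2e4)
  b <- 1
  for (s in seq_along(draws)) {
    b <- mh_update_anchor(b, k, a1, a2, m1, m2)$b_i
    draws[s] <- b
  }
  grid <- exp(seq(log(1e-4), log(100), length.out = 4001))
  logf <- (k - 1) * log(grid) - m1 * log1p(a1 * grid) - m2 * log1p(a2 * grid)
  expect_lt(ks_vs_grid(draws[-(1:200)], grid, grid_cdf(logf, grid)), 0.02)
})

simulate_neat <- function(m1, m2, delta_anchor, delta_u1, delta_u2,
                          shift2 = 0.5) {
  th1 <- rnorm(m1); th2 <- rnorm(m2, shift2)
  mk <- function(th, delta, ids) {
    p <- plogis(outer(th, delta, "-"))
    matrix(rbinom(length(p), 1, p), nrow(p), dimnames = list(NULL, ids))
  }
  list(X1 = cbind(mk(th1, delta_anchor, paste0("A", seq_along(delta_anchor))),
                  mk(th1, delta_u1, paste0("U", seq_along(delta_u1)))),
       X2 = cbind(mk(th2, delta_anchor, paste0("A", seq_along(delta_anchor))),
                  mk(th2, delta_u2, paste0("V", seq_along(delta_u2)))))
}

test_that("NEAT Gibbs recovers anchors on two-population data, deterministically", {
  set.seed(93)
  da <- c(-0.5, 0.2, 0.8); du1 <- c(-1, 0.5, 1.2); du2 <- c(-0.7, 0, 0.9)
  dat <- simulate_neat(2500, 2500, da, du1, du2)
  st <- neat_sufficient_statistics(dat$X1, dat$X2)
  cfg <- chain_config(n_iter = 1500, burn_in = 300, seed = 94)
  d <- neat_gibbs_run(st, config = cfg)
  expect_true(all(d$b[, 1] == 1))
  expect_true(all(d$lambda[, 1] == 1) && all(d$eta[, 1] == 1))
  b_true <- exp(-(da - da[1]))
  pm <- colMeans(d$b); ps <- apply(d$b, 2, sd)
  expect_true(all(abs(pm - b_true)[-1] <= 4 * ps[-1]))
  c_true <- exp(-(du1 - da[1]))
  expect_true(all(abs(colMeans(d$c) - c_true) <= 4 * apply(d$c, 2, sd)))
  # acceptance rates are logged and healthy for the matched proposal
  expect_true(all(d$accept_rate[-1] > 0.8))
  d2 <- neat_gibbs_run(st, config = cfg)
  expect_identical(d$b, d2$b)
  expect_identical(d$eta, d2$eta)
})

test_that("NEAT with an empty second group matches the complete-design posterior", {
  set.seed(95)
  X <- simulate_latent_rasch(1500, c(-0.8, -0.2, 0.4, 1))
  colnames(X) <- paste0("A", 1:4)
  st_neat <- neat_sufficient_statistics(X, X[0, ])
  dn <- neat_gibbs_run(st_neat,
                       config = chain_config(n_iter = 3300, burn_in = 300,
                                             seed = 96))
  dg <- gibbs_run(sufficient_statistics(X),
                  config = chain_config(n_iter = 3300, burn_in = 300,
                                        seed = 97, identification = "fixed"))
  # same identified posterior sampled by two different algorithms:
  # quantile-quantile agreement for an item and a score parameter
  for (col in 2:4) {
    qn <- quantile(dn$b[, col], c(.1, .25, .5, .75, .9))
    qg <- quantile(dg$b[, col], c(.1, .25, .5, .75, .9))
    expect_lt(max(abs(qn - qg)), 0.5 * sd(dg$b[, col]))
  }
  ql <- quantile(dn$lambda[, 3], c(.25, .5, .75))
  qg <- quantile(dg$lambda[, 3], c(.25, .5, .75))
  expect_lt(max(abs(ql - qg)), 0.5 * sd(dg$lambda[, 3]))
})

test_that("polytomous sufficient statistics reduce and count correctly", {
  # binary data with unit weights reduce to the dichotomous statistics
  set.seed(98)
  X <- simulate_latent_rasch(200, c(-0.5, 0.5, 0))
  bank <- poly_bank(rep(list(1L), 3))
  ps <- poly_sufficient_statistics(X, bank)
  ds <- sufficient_statistics(X)
  expect_equal(unlist(ps$y_plus), ds$item_totals, ignore_attr = TRUE)
  expect_equal(ps$score_counts, ds$score_counts)
  # weighted scores: 2 items with weights (1,2), pattern (2,1) -> y++ = 3
  bank2 <- poly_bank(list(c(1L, 2L), c(1L, 2L)))
  X2 <- rbind(c(2, 1), c(0, 2), c(1, 1))
  ps2 <- poly_sufficient_statistics(X2, bank2)
  # by hand: (2,1) -> 2+1 = 3; (0,2) -> 2; (1,1) -> 2
  expect_equal(unname(ps2$score_counts), c(0, 0, 2, 1, 0))
  expect_equal(ps2$y_plus[[1]], c(1, 1))
  expect_equal(ps2$y_plus[[2]], c(2, 1))
  expect_error(poly_sufficient_statistics(rbind(c(3, 0)), bank2), "categories")
  # achievable lattice
  gap <- poly_bank(list(2L, c(2L, 4L)))
  expect_equal(achievable_scores(gap), c(0L, 2L, 4L, 6L))
})

test_that("polytomous full conditional: linear coefficient, reduction, oracle law", {
  set.seed(99)
  w <- list(c(1L, 2L), c(1L, 3L), 2L)
  bb <- lapply(w, function(wi) exp(runif(length(wi), -1, 1)))
  bank <- poly_bank(w, bb)
  smax <- sum(vapply(w, max, 0L))
  lambda <- exp(rnorm(smax + 1) * 0.4)
  # linear-coefficient check against brute-force expansion of sum gamma lambda
  for (i in 1:3) for (j in seq_along(w[[i]])) {
    S_at <- function(v) {
      b2 <- bb; b2[[i]][j] <- v
      sum(esf_poly_bruteforce(w, b2) * lambda)
    }
    coef <- (S_at(2) - S_at(1))    # slope in b_ij
    const <- S_at(0)
    cc <- gibbsrasch:::poly_fc_scale(bank, lambda, i, j)
    expect_equal(cc, coef / const, tolerance = 1e-10)
  }
  # J_i = 1, weight 1: identical draw to the dichotomous update
  bankd <- poly_bank(rep(list(1L), 4),
                     as.list(exp(runif(4, -1, 1))))
  b <- unlist(bankd$b)
  lam <- exp(rnorm(5) * 0.4)
  stp <- structure(list(y_plus = as.list(c(12, 9, 15, 7)),
                        score_counts = stats::setNames(rep(6, 5), 0:4),
                        m = 30, smax = 4L, achievable = 0:4,
                        weights = bankd$weights),
                   class = "poly_suffstats")
  std <- structure(list(item_totals = c(12, 9, 15, 7),
                        score_counts = stats::setNames(rep(6, 5), 0:4),
                        m = 30, n = 4L, item_ids = paste0("i", 1:4)),
                   class = "rasch_suffstats")
  set.seed(7); v_poly <- poly_sample_category(bankd, lam, stp, i = 2, j = 1)
  set.seed(7); v_dich <- sample_item(b, lam, std, i = 2)
  expect_equal(v_poly, v_dich, tolerance = 1e-12)
  # KS of draws against the quadrature-normalized conditional
  stats3 <- structure(list(y_plus = list(c(10, 6), c(8, 5), c(9)),
                           score_counts = stats::setNames(
                             c(4, 5, 6, 5, 4, 3, 3), 0:6),
                           m = 30, smax = smax, achievable = 0:smax,
                           weights = w),
                      class = "poly_suffstats")
  i <- 1; j <- 2
  k <- stats3$y_plus[[i]][j] + 1
  grid <- exp(seq(log(1e-4), log(60), length.out = 4001))
  logf <- vapply(grid, function(v) {
    b2 <- bb; b2[[i]][j] <- v
    (k - 1) * log(v) - 30 * log(sum(esf_poly_bruteforce(w, b2) * lambda))
  }, 0)
  draws <- vapply(1:1e5, function(r)
    poly_sample_category(bank, lambda, stats3, i = i, j = j), 0)
  expect_lt(ks_vs_grid(draws, grid, grid_cdf(logf, grid)), 0.01)
})

test_that("poly_gibbs_run recovers partial-credit parameters and matches the dichotomous path", {
  set.seed(101)
  # partial-credit-style items: weights (1,2), NRM category probabilities
  w <- rep(list(c(1L, 2L)), 4)
  delta <- list(c(0.4, 0.9), c(-0.3, 0.4), c(0.2, 1.1), c(-0.6, -0.2))
  m <- 2500
  th <- rnorm(m)
  X <- sapply(1:4, function(i) {
    eta <- cbind(0, outer(th, c(1, 2)) -
                   matrix(delta[[i]], m, 2, byrow = TRUE))
    p <- exp(eta - apply(eta, 1, max))
    p <- p / rowSums(p)
    apply(p, 1, function(pr) sample.int(3, 1, prob = pr) - 1L)
  })
  bank <- poly_bank(w)
  stp <- poly_sufficient_statistics(X, bank)
  dp <- poly_gibbs_run(stp, config = chain_config(n_iter = 1200,
                                                  burn_in = 200, seed = 102))
  # identified truth: b'_ij = b_ij * c^a_ij with c = 1/b_11
  b_t <- lapply(delta, exp_neg <- function(d) exp(-d))
  c0 <- 1 / b_t[[1]][1]
  truth <- unlist(lapply(1:4, function(i) b_t[[i]] * c0^c(1, 2)))
  pm <- colMeans(dp$b); ps <- apply(dp$b, 2, sd)
  expect_equal(unname(pm[1]), 1)  # reference category fixed
  expect_true(all(abs(pm - truth)[-1] <= 4 * ps[-1]))
  # seed determinism
  dp2 <- poly_gibbs_run(stp, config = chain_config(n_iter = 1200,
                                                   burn_in = 200, seed = 102))
  expect_identical(dp$b, dp2$b)
  # binary data through the polytomous path reproduces the dichotomous one
  set.seed(103)
  Xb <- simulate_latent_rasch(1500, c(-0.6, 0, 0.7))
  stb <- poly_sufficient_statistics(Xb, poly_bank(rep(list(1L), 3)))
  dpb <- poly_gibbs_run(stb, config = chain_config(n_iter = 3300,
                                                   burn_in = 300, seed = 104))
  dgb <- gibbs_run(sufficient_statistics(Xb),
                   config = chain_config(n_iter = 3300, burn_in = 300,
                                         seed = 105,
                                         identification = "fixed"))
  for (col in 2:3) {
    qp <- quantile(dpb$b[, col], c(.1, .5, .9))
    qg <- quantile(dgb$b[, col], c(.1, .5, .9))
    expect_lt(max(abs(qp - qg)), 0.5 * sd(dgb$b[, col]))
  }
})
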