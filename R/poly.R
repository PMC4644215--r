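#' Polytomous item bank with fixed integer scoring weights
#'
#' Nominal-response-model items whose integer category weights `a_ij` are
#' fixed and known, so the weighted total score `y_++` is sufficient for
#' ability.  Category 0 of every item has weight 0 and easiness 1
#' implicitly; categories `j = 1..J_i` carry positive integer weights and
#' positive easiness parameters `b_ij`.  Partial credit and OPLM-type
#' models are the special cases with consecutive weights.
#'
#' @param weights list (one element per item) of positive integer weight
#'   vectors.
#' @param b list of positive easiness vectors matching `weights`; defaults
#'   to all 1.
#' @return an object of class `poly_bank`.
#' @export
poly_bank <- function(weights, b = lapply(weights, function(w) rep(1, length(w)))) {
  if (!is.list(weights) || !length(weights)) stop("weights must be a non-empty list")
  for (w in weights) {
    if (anyNA(w) || any(w != round(w)) || any(w < 1))
      stop("category weights must be positive integers")
  }
  if (!is.list(b) || length(b) != length(weights) ||
      any(lengths(b) != lengths(weights)))
    stop("easiness list must match the weights list")
  for (bb in b)
    if (anyNA(bb) || any(!is.finite(bb)) || any(bb <= 0))
      stop("category easiness values must be positive and finite")
  structure(list(weights = lapply(weights, as.integer), b = b,
                 n = length(weights)),
            class = "poly_bank")
}

as_poly_bank <- function(x) {
  if (inherits(x, "poly_bank")) x else do.call(poly_bank, x)
}

#' Achievable weighted scores of a bank
#'
#' @param bank a [poly_bank()].
#' @return integer vector of achievable values of `y_++` (always includes
#'   0).
#' @export
achievable_scores <- function(bank) {
  bank <- as_poly_bank(bank)
  # subset-sum DP over the category weights
  smax <- sum(vapply(bank$weights, max, 0L))
  reach <- c(TRUE, rep(FALSE, smax))
  for (w in bank$weights) {
    new <- reach
    for (a in w) new <- new | c(rep(FALSE, a), reach[seq_len(smax + 1L - a)])
    reach <- new
  }
  which(reach) - 1L
}

#' Sufficient statistics for polytomous responses
#'
#' @param X integer matrix with entries in `0..J_i` per column (category
#'   chosen), persons in rows.
#' @param bank a [poly_bank()] giving the weights (easiness values are
#'   ignored here).
#' @return an object of class `poly_suffstats`: per-item-category counts
#'   `y_plus` (list), the histogram of the weighted total score on
#'   `0..max_score`, `m`, and the achievable-score set.
#' @export
poly_sufficient_statistics <- function(X, bank) {
  bank <- as_poly_bank(bank)
  X <- as.matrix(X)
  if (ncol(X) != bank$n) stop("X must have one column per item")
  if (anyNA(X)) stop("responses must be complete")
  y_plus <- vector("list", bank$n)
  wtot <- numeric(nrow(X))
  for (i in seq_len(bank$n)) {
    Ji <- length(bank$weights[[i]])
    xi <- X[, i]
    if (any(xi != round(xi)) || any(xi < 0) || any(xi > Ji))
      stop("item ", i, ": responses must be categories 0..", Ji)
    y_plus[[i]] <- vapply(seq_len(Ji), function(j) sum(xi == j), 0)
    wtot <- wtot + c(0L, bank$weights[[i]])[xi + 1L]
  }
  smax <- sum(vapply(bank$weights, max, 0L))
  structure(list(y_plus = y_plus,
                 score_counts = stats::setNames(
                   as.numeric(tabulate(wtot + 1L, nbins = smax + 1L)),
                   0:smax),
                 m = nrow(X), smax = smax,
                 achievable = achievable_scores(bank),
                 weights = bank$weights),
            class = "poly_suffstats")
}

# scale constant of the full conditional of b_ij: the normalizer
# sum_s gamma_s lambda_s is linear in b_ij with coefficient
# sum_s gamma_(s - a_ij)(bank^(i)) lambda_s
poly_fc_scale <- function(bank, lambda, i, j) {
  bank <- as_poly_bank(bank)
  smax <- sum(vapply(bank$weights, max, 0L))
  red <- poly_bank(bank$weights[-i], bank$b[-i])
  lgr <- as.numeric(esf_poly_log(red))
  loglam <- log(lambda)
  shift_lse <- function(a) {            # sum_s gamma_(s-a)^{(i)} lambda_s
    idx <- seq_along(loglam) - a        # position of s - a in lgr
    ok <- idx >= 1L & idx <= length(lgr)
    if (!any(ok)) return(-Inf)
    lse(lgr[idx[ok]] + loglam[ok])
  }
  a <- bank$weights[[i]]
  lognum <- shift_lse(a[j])
  terms <- shift_lse(0)                 # category-0 block
  for (h in seq_along(a))
    if (h != j) terms <- vlogadd(terms, log(bank$b[[i]][h]) + shift_lse(a[h]))
  exp(lognum - terms)
}

#' Single full-conditional draw for a polytomous category parameter
#'
#' The normalizer of the polytomous marginal model is linear in each
#' `b_ij`, so the full conditional is again a scaled Beta prime with
#' `k = y_+ij + alpha_ij`, `M = m`, and scale equal to the linearization
#' coefficient ratio.  Drawn through [sample_scaled_beta_prime()], the
#' same primitive as the dichotomous updates.
#'
#' @param bank a [poly_bank()] holding the current easiness state.
#' @param lambda score parameters over `0..max_score` (entries at
#'   unachievable scores are ignored).
#' @param stats a [poly_sufficient_statistics()] object.
#' @param prior optional list of per-item alpha vectors (default all 1).
#' @param i,j item and category (`j >= 1`) indices.
#' @return one draw of `b_ij`.
#' @export
poly_sample_category <- function(bank, lambda, stats, prior = NULL, i, j) {
  bank <- as_poly_bank(bank)
  alpha <- if (is.null(prior)) 1 else prior$alpha[[i]][j]
  k <- stats$y_plus[[i]][j] + alpha
  if (!(k > 0 && k < stats$m))
    stop("item ", i, " category ", j, ": need 0 < y_+ij + alpha_ij < m")
  cc <- poly_fc_scale(bank, lambda, i, j)
  sample_scaled_beta_prime(1L, k, stats$m, cc)
}

#' Gibbs sampler for the fixed-weights polytomous model
#'
#' Sweeps over every free item-category easiness parameter (conjugate
#' scaled Beta prime draws) and then over the free score parameters on the
#' achievable-score lattice.  Identification is imposed by constraint:
#' `b_11` and `lambda_0` are held at 1 and never sampled (the likelihood
#' is invariant under `b_ij -> c^(a_ij) b_ij`, `lambda_s -> lambda_s /
#' c^s` and under a common rescaling of lambda, and under a flat prior
#' those orbits make the unconstrained posterior improper).
#'
#' @param stats a [poly_sufficient_statistics()] object.
#' @param prior optional list with `alpha` (list of per-category vectors)
#'   and `beta` (vector over `0..max_score`); default all 1.
#' @param config a [chain_config()].
#' @return object of class `poly_draws` with `b` (matrix, columns
#'   `b_<i>_<j>`) and `lambda` (achievable scores only, columns
#'   `lambda_<s>`).
#' @export
poly_gibbs_run <- function(stats, prior = NULL, config = chain_config()) {
  stopifnot(inherits(stats, "poly_suffstats"))
  weights <- stats$weights
  n <- length(weights)
  smax <- stats$smax
  ach <- stats$achievable
  alpha <- prior$alpha %||% lapply(weights, function(w) rep(1, length(w)))
  beta <- prior$beta %||% rep(1, smax + 1L)
  ks <- stats$score_counts + beta
  kb <- lapply(seq_len(n), function(i) stats$y_plus[[i]] + alpha[[i]])
  bad_s <- ach[!(ks[ach + 1L] > 0 & ks[ach + 1L] < stats$m)]
  bad_b <- unlist(lapply(seq_len(n), function(i) {
    j <- which(!(kb[[i]] > 0 & kb[[i]] < stats$m))
    if (length(j)) paste0("item ", i, " cat ", j) else character(0)
  }))
  if (length(bad_s) || length(bad_b))
    stop("improper full conditionals: ",
         paste(c(if (length(bad_b)) bad_b,
                 if (length(bad_s)) paste("score", bad_s)), collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)

  bank <- poly_bank(weights, lapply(weights, function(w) runif(length(w))))
  bank$b[[1L]][1L] <- 1
  lambda <- rep(0, smax + 1L)
  lambda[ach + 1L] <- runif(length(ach))
  lambda[1L] <- 1
  keep_from <- if (config$keep_all) 1L else config$burn_in + 1L
  kept <- config$n_iter - keep_from + 1L
  bcols <- unlist(lapply(seq_len(n), function(i)
    paste0("b_", i, "_", seq_along(weights[[i]]))))
  Bm <- matrix(NA_real_, kept, length(bcols), dimnames = list(NULL, bcols))
  Lm <- matrix(NA_real_, kept, length(ach),
               dimnames = list(NULL, paste0("lambda_", ach)))
  row <- 0L
  for (it in seq_len(config$n_iter)) {
    for (i in seq_len(n)) for (j in seq_along(weights[[i]])) {
      if (i == 1L && j == 1L) next    # reference category, fixed at 1
      cc <- poly_fc_scale(bank, lambda, i, j)
      bank$b[[i]][j] <- sample_scaled_beta_prime(1L, kb[[i]][j], stats$m, cc)
    }
    lgf <- as.numeric(esf_poly_log(bank))
    loglam <- log(lambda)
    for (t in setdiff(ach, 0L)) {
      den <- lse((lgf + loglam)[-(t + 1L)])
      cc <- exp(lgf[t + 1L] - den)
      lambda[t + 1L] <- sample_scaled_beta_prime(1L, ks[t + 1L], stats$m, cc)
      loglam[t + 1L] <- log(lambda[t + 1L])
    }
    if (it >= keep_from) {
      row <- row + 1L
      Bm[row, ] <- unlist(bank$b)
      Lm[row, ] <- lambda[ach + 1L]
    }
  }
  structure(list(b = Bm, lambda = Lm, achievable = ach,
                 iteration = keep_from:config$n_iter,
                 burn_in = config$burn_in, n_iter = config$n_iter,
                 config = config, m = stats$m),
            class = "poly_draws")
}
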