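#' Two-sample ECDF comparison between successive iterations
#'
#' A chain is converged at iteration `t` when the cross-replication
#' distribution of a parameter at iteration `t` coincides with that at
#' `t + 1`.  This compares the two samples with a two-sample
#' Kolmogorov--Smirnov test.
#'
#' @param sample_t draws of one parameter across replicated chains at
#'   iteration `t` (length >= 2).
#' @param sample_t1 the same at iteration `t + 1`.
#' @return list with `statistic` (KS distance) and `p_value`.
#' @export
convergence_ecdf <- function(sample_t, sample_t1) {
  if (length(sample_t) < 2L || length(sample_t1) < 2L)
    stop("need at least 2 replications per iteration")
  ks <- suppressWarnings(ks.test(sample_t, sample_t1))
  list(statistic = unname(ks$statistic), p_value = unname(ks$p.value))
}

#' Scan successive-iteration ECDF comparisons over a whole trace matrix
#'
#' @param traces matrix of one parameter, replications in rows, iterations
#'   in columns.
#' @param alpha rejection level.
#' @return `data.frame` with one row per successive pair: iteration `t`,
#'   KS `statistic`, `p_value`, and `reject`.  The attribute
#'   `"converged_at"` holds the first iteration from which no later pair
#'   rejects.
#' @export
ecdf_convergence_scan <- function(traces, alpha = 0.05) {
  nit <- ncol(traces)
  if (nit < 2L) stop("need at least two iterations")
  out <- data.frame(t = seq_len(nit - 1L), statistic = NA_real_,
                    p_value = NA_real_)
  for (t in seq_len(nit - 1L)) {
    ks <- convergence_ecdf(traces[, t], traces[, t + 1L])
    out$statistic[t] <- ks$statistic
    out$p_value[t] <- ks$p_value
  }
  out$reject <- out$p_value < alpha
  last_rej <- if (any(out$reject)) max(out$t[out$reject]) else 0L
  attr(out, "converged_at") <- last_rej + 1L
  out
}

#' Autocorrelation of a single chain
#'
#' Sample autocorrelations at lags `0..max_lag` after discarding
#' `burn_in` initial iterations.
#'
#' @param chain numeric vector of draws of one parameter.
#' @param max_lag largest lag.
#' @param burn_in iterations to discard first.
#' @return numeric vector of autocorrelations, named by lag `0..max_lag`.
#' @export
autocorrelation <- function(chain, max_lag, burn_in = 0L) {
  x <- chain[(burn_in + 1L):length(chain)]
  if (length(x) <= max_lag)
    stop("chain too short for the requested maximum lag")
  r <- drop(acf(x, lag.max = max_lag, plot = FALSE,
                demean = TRUE)$acf)
  stats::setNames(r, 0:max_lag)
}

#' Autocorrelation estimated across replicated chains
#'
#' For each lag `k`, the correlation between iterations `t` and `t + k` is
#' computed across replications and averaged over `t`.  With many
#' replications this estimates the lag-`k` autocorrelation of the
#' stationary chain without relying on within-chain ergodic averages.
#'
#' @param traces matrix, replications in rows, iterations in columns.
#' @param max_lag largest lag.
#' @param burn_in initial iterations (columns) to discard.
#' @return numeric vector of autocorrelations, named by lag `0..max_lag`.
#' @export
replication_autocorrelation <- function(traces, max_lag, burn_in = 0L) {
  x <- traces[, (burn_in + 1L):ncol(traces), drop = FALSE]
  nit <- ncol(x)
  if (nit <= max_lag) stop("too few iterations for the requested lag")
  vapply(0:max_lag, function(k) {
    ts <- seq_len(nit - k)
    mean(vapply(ts, function(t) {
      if (k == 0L) return(1)
      cor(x[, t], x[, t + k])
    }, 0))
  }, 0) -> r
  stats::setNames(r, 0:max_lag)
}

#' Item-rest regression fit
#'
#' For every item, compares the observed proportion correct at each rest
#' score with the model-implied item-rest regression
#' `b_i tau_r / (1 + b_i tau_r)` with `tau_r = lambda_(r+1)/lambda_r`,
#' computed per retained draw and then averaged over draws (marginalizing
#' the joint over all patterns with item `i` correct and rest score `r`
#' shows the regression involves the full-model lambda ratio).  The
#' per-item discrepancy is the maximum over rest scores of the absolute
#' difference weighted by the cell's share of respondents.
#'
#' @param X complete binary response matrix used for the fit.
#' @param draws a `gibbs_draws` object fitted to `X`.
#' @return an object of class `item_rest_fit`: list with `table` (long
#'   `data.frame`: item, rest score, count, observed, expected, flag for
#'   empty cells) and `discrepancy` (named per-item statistic).
#' @export
item_rest_fit <- function(X, draws) {
  X <- as.matrix(X)
  d <- retained(draws)
  n <- d$n
  if (ncol(X) != n) stop("X does not match the fitted model")
  m <- nrow(X)
  rows <- list()
  disc <- stats::setNames(numeric(n), d$item_ids)
  # tau_r = lambda_(r+1)/lambda_r per draw, rest scores r = 0..n-1
  tau_mat <- d$lambda[, 2:(n + 1L), drop = FALSE] /
    d$lambda[, 1:n, drop = FALSE]
  for (i in seq_len(n)) {
    rest <- rowSums(X[, -i, drop = FALSE])
    cnt <- tabulate(rest + 1L, nbins = n)         # rest scores 0..n-1
    obs <- vapply(0:(n - 1L), function(s) {
      if (cnt[s + 1L] == 0L) return(NA_real_)
      mean(X[rest == s, i])
    }, 0)
    bt <- d$b[, i] * tau_mat                      # draws x rest scores
    expc <- colMeans(bt / (1 + bt))
    w <- cnt / m
    dd <- abs(obs - expc) * w
    disc[i] <- max(dd, na.rm = TRUE)
    rows[[i]] <- data.frame(item = d$item_ids[i], rest_score = 0:(n - 1L),
                            count = cnt, observed = obs, expected = expc,
                            empty = cnt == 0L)
  }
  structure(list(table = do.call(rbind, rows), discrepancy = disc),
            class = "item_rest_fit")
}

#' @export
print.item_rest_fit <- function(x, ...) {
  cat("Item-rest regression fit; per-item weighted max discrepancy:\n")
  print(round(x$discrepancy, 4))
  invisible(x)
}
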