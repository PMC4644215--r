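#' Sufficient statistics for a two-booklet NEAT design
#'
#' Two groups of respondents, possibly from different populations, each
#' take a shared anchor plus a unique item set.  Anchor item totals are
#' pooled across groups; unique-item totals and score histograms are kept
#' per group.  Each group carries its own score parameters (`lambda` for
#' group 1, `eta` for group 2).
#'
#' @param X1 binary matrix for group 1 (anchor + unique columns, named).
#' @param X2 binary matrix for group 2 (anchor + unique columns, named).
#'   May have zero rows, in which case the design reduces to a complete
#'   design for group 1.
#' @param anchor character vector of anchor column names; defaults to the
#'   columns the two matrices share.
#' @return an object of class `neat_suffstats`.
#' @export
neat_sufficient_statistics <- function(X1, X2,
                                       anchor = intersect(colnames(X1),
                                                          colnames(X2))) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (is.null(colnames(X1)) || is.null(colnames(X2)))
    stop("both matrices need item IDs as column names")
  if (length(anchor) == 0L)
    stop("design error: the anchor item set is empty")
  if (!all(anchor %in% colnames(X1)) || !all(anchor %in% colnames(X2)))
    stop("design error: anchor columns missing from a booklet")
  for (X in list(X1, X2))
    if (nrow(X) > 0 && (anyNA(X) || !all(X %in% c(0, 1))))
      stop("booklet responses must be 0/1 with no missing cells")
  u1 <- setdiff(colnames(X1), anchor)
  u2 <- setdiff(colnames(X2), anchor)
  n1 <- length(anchor) + length(u1)
  n2 <- length(anchor) + length(u2)
  tot <- function(X, cols) if (nrow(X)) as.numeric(colSums(X[, cols, drop = FALSE])) else numeric(length(cols)) * 0
  scounts <- function(X, nb) stats::setNames(
    as.numeric(tabulate(if (nrow(X)) rowSums(X) + 1L else integer(0),
                        nbins = nb + 1L)), 0:nb)
  structure(list(
    anchor_ids = anchor, unique1_ids = u1, unique2_ids = u2,
    anchor_totals = tot(X1, anchor) + tot(X2, anchor),
    unique1_totals = tot(X1, u1), unique2_totals = tot(X2, u2),
    score_counts1 = scounts(X1, n1), score_counts2 = scounts(X2, n2),
    m_xy = nrow(X1), m_xz = nrow(X2),
    n_anchor = length(anchor), n1 = n1, n2 = n2),
    class = "neat_suffstats")
}

#' Build NEAT statistics from an incomplete response matrix plus a design
#'
#' A two-booklet design file maps booklet names to item ID vectors; the
#' anchor is their intersection.  Every respondent row must have observed
#' cells exactly matching one booklet (everything else `NA`,
#' missing-by-design).
#'
#' @param X response matrix with `NA` for not-administered cells; item IDs
#'   as column names.
#' @param design named list of two character vectors of item IDs.
#' @return a [neat_sufficient_statistics()] object.
#' @export
neat_from_incomplete <- function(X, design) {
  if (length(design) != 2L)
    stop("design must name exactly two booklets")
  b1 <- design[[1L]]; b2 <- design[[2L]]
  if (!all(c(b1, b2) %in% colnames(X)))
    stop("design names items absent from the response matrix")
  obs <- !is.na(X)
  match1 <- apply(obs, 1, function(o) setequal(colnames(X)[o], b1))
  match2 <- apply(obs, 1, function(o) setequal(colnames(X)[o], b2))
  if (any(!match1 & !match2))
    stop("row(s) ", paste(utils::head(which(!match1 & !match2), 3),
                          collapse = ", "),
         " have observed cells matching neither booklet")
  anchor <- intersect(b1, b2)
  neat_sufficient_statistics(X[match1, b1, drop = FALSE],
                             X[match2, b2, drop = FALSE],
                             anchor = anchor)
}

#' Log full conditional of an anchor difficulty and its slope
#'
#' On the difficulty scale `delta = -log(b)` the anchor full conditional is
#' `log f = -(x_+i + alpha_i) delta - m_xy log(1 + a1 e^(-delta)) -
#' m_xz log(1 + a2 e^(-delta)) + const`.  It is concave with linear tails:
#' the slope tends to `-(x_+i + alpha_i)` as `delta -> +Inf` and to
#' `(m_xy + m_xz) - (x_+i + alpha_i)` as `delta -> -Inf`.
#'
#' @param delta evaluation point(s) on the difficulty scale.
#' @param k exponent `x_+i + alpha_i`.
#' @param a1,a2 positive linearization coefficients from the two booklets'
#'   ESFs and score parameters.
#' @param m_xy,m_xz group sizes.
#' @return list with `logf` (up to an additive constant) and `slope`, both
#'   vectorized over `delta`.
#' @export
anchor_log_conditional <- function(delta, k, a1, a2, m_xy, m_xz) {
  eb <- exp(-delta)
  logf <- -k * delta - m_xy * log1p(a1 * eb) - m_xz * log1p(a2 * eb)
  r1 <- a1 * eb / (1 + a1 * eb)
  r2 <- a2 * eb / (1 + a2 * eb)
  list(logf = logf, slope = -k + m_xy * r1 + m_xz * r2)
}

# a1, a2 for anchor item i (1-based among anchors): the scale constants of
# the two booklets' normalizers, linearized in b_i.  Uses the same ESF
# kernel as the complete-design item update.
anchor_coefficients <- function(b, cpar, dpar, lambda, eta, i) {
  a1 <- exp(item_fc_scale_cpp(log(c(b, cpar)), log(lambda), i))
  a2 <- exp(item_fc_scale_cpp(log(c(b, dpar)), log(eta), i))
  c(a1 = a1, a2 = a2)
}

# log proposal density on the b scale (normalizing Beta function omitted:
# it is common to forward and reverse): g(v) = c^k v^(k-1)/(1+cv)^M
rsbp_log_density <- function(logv, k, M, logc) {
  k * logc + (k - 1) * logv - M * log1p(exp(logc + logv))
}

#' Metropolis update of one anchor item in a NEAT design
#'
#' The proposal is the complete-design conditional shape
#' `g(delta) \propto e^(-k delta) / (1 + c e^(-delta))^(m_xy + m_xz)` with
#' `c` chosen so that the slope of `log g` at the current `delta` equals
#' the slope of the log target there (closed form via
#' `q = (m_xy r_1 + m_xz r_2)/(m_xy + m_xz)`, `r_j = a_j b/(1 + a_j b)`,
#' `c = q/((1-q) b)`).  The proposal is drawn through
#' the scaled-Beta-prime primitive on the easiness scale and accepted with
#' the usual Metropolis--Hastings ratio using the state-dependent proposal
#' densities on both sides.
#'
#' @param b_i current anchor easiness.
#' @param k exponent `x_+i + alpha_i`.
#' @param a1,a2 linearization coefficients (see
#'   [anchor_log_conditional()]).
#' @param m_xy,m_xz group sizes.
#' @return list with `b_i` (new value), `accepted`, and `degenerate`
#'   (`TRUE` when the slope match was impossible and the state was kept).
#' @export
mh_update_anchor <- function(b_i, k, a1, a2, m_xy, m_xz) {
  M <- m_xy + m_xz
  if (!(k > 0 && k < M))
    stop("anchor precondition violated: need 0 < x_+i + alpha_i < m_xy + m_xz")
  r1 <- a1 * b_i / (1 + a1 * b_i)
  r2 <- a2 * b_i / (1 + a2 * b_i)
  q <- (m_xy * r1 + m_xz * r2) / M
  if (!(q > 0 && q < 1)) {
    warning("degenerate slope match (q = ", q, "); keeping current value")
    return(list(b_i = b_i, accepted = FALSE, degenerate = TRUE))
  }
  c_fwd <- q / ((1 - q) * b_i)
  logv_new <- rsbp_cpp(1L, k, M, log(c_fwd), -Inf, Inf)
  b_new <- exp(logv_new)
  # reverse proposal matched at the proposed point
  r1n <- a1 * b_new / (1 + a1 * b_new)
  r2n <- a2 * b_new / (1 + a2 * b_new)
  qn <- (m_xy * r1n + m_xz * r2n) / M
  if (!(qn > 0 && qn < 1))
    return(list(b_i = b_i, accepted = FALSE, degenerate = TRUE))
  c_rev <- qn / ((1 - qn) * b_new)
  # log target on the b scale: the e^(-k delta) kernel picks up the
  # Jacobian 1/b, giving b^(k-1)
  target <- function(lv)
    (k - 1) * lv - m_xy * log1p(exp(log(a1) + lv)) -
      m_xz * log1p(exp(log(a2) + lv))
  log_alpha <- target(logv_new) - target(log(b_i)) +
    rsbp_log_density(log(b_i), k, M, log(c_rev)) -
    rsbp_log_density(logv_new, k, M, log(c_fwd))
  if (log(runif(1)) < log_alpha)
    list(b_i = b_new, accepted = TRUE, degenerate = FALSE)
  else
    list(b_i = b_i, accepted = FALSE, degenerate = FALSE)
}

#' Prior hyperparameters for a NEAT design
#'
#' @param stats a [neat_sufficient_statistics()] object.
#' @param alpha,beta positive scalars recycled over all item and score
#'   hyperparameters.
#' @return list of hyperparameter vectors, class `neat_prior`.
#' @export
neat_prior <- function(stats, alpha = 1, beta = 1) {
  structure(list(
    alpha_anchor = rep_len(alpha, stats$n_anchor),
    alpha_u1 = rep_len(alpha, length(stats$unique1_ids)),
    alpha_u2 = rep_len(alpha, length(stats$unique2_ids)),
    beta_lambda = rep_len(beta, stats$n1 + 1L),
    beta_eta = rep_len(beta, stats$n2 + 1L)), class = "neat_prior")
}

#' Metropolis-within-Gibbs sampler for the NEAT design
#'
#' Unique items and the two score parameter vectors have the same conjugate
#' scaled-Beta-prime full conditionals as the complete design (restricted
#' to their own group); each free anchor item gets exactly one
#' matched-slope Metropolis proposal per sweep.  Identification is imposed
#' by constraint: the reference anchor item is held at easiness 1 and
#' `lambda_0 = eta_0 = 1`, none of which are sampled (sampling them under
#' a flat prior leaves the posterior improper along the scale orbits).
#'
#' @param stats a [neat_sufficient_statistics()] object.
#' @param prior a [neat_prior()]; default uniform.
#' @param config a [chain_config()] (`constrained` is not supported here).
#' @return object of class `neat_draws` with matrices `b` (anchor), `c`,
#'   `d`, `lambda`, `eta`, the per-anchor acceptance rates, and provenance.
#' @export
neat_gibbs_run <- function(stats, prior = NULL, config = chain_config()) {
  stopifnot(inherits(stats, "neat_suffstats"))
  prior <- prior %||% neat_prior(stats)
  if (isTRUE(config$constrained))
    stop("the monotone-tau constraint is not implemented for NEAT designs")
  na <- stats$n_anchor; nc <- length(stats$unique1_ids)
  nd <- length(stats$unique2_ids)
  m1 <- stats$m_xy; m2 <- stats$m_xz; M <- m1 + m2
  ka <- stats$anchor_totals + prior$alpha_anchor
  kc <- stats$unique1_totals + prior$alpha_u1
  kd <- stats$unique2_totals + prior$alpha_u2
  kl <- stats$score_counts1 + prior$beta_lambda
  ke <- stats$score_counts2 + prior$beta_eta
  viol <- c(
    if (any(bad <- !(ka > 0 & ka < M)))
      paste("anchor:", paste(stats$anchor_ids[bad], collapse = ", ")),
    if (nc && any(bad <- !(kc > 0 & kc < m1)))
      paste("unique group 1:", paste(stats$unique1_ids[bad], collapse = ", ")),
    if (nd && any(bad <- !(kd > 0 & kd < m2)))
      paste("unique group 2:", paste(stats$unique2_ids[bad], collapse = ", ")),
    if (m1 && any(bad <- !(kl > 0 & kl < m1)))
      paste("group 1 scores:", paste(which(bad) - 1L, collapse = ", ")),
    if (m2 && any(bad <- !(ke > 0 & ke < m2)))
      paste("group 2 scores:", paste(which(bad) - 1L, collapse = ", ")))
  if (length(viol))
    stop("improper full conditionals under this prior; ",
         paste(viol, collapse = "; "))
  if (!is.null(config$seed)) set.seed(config$seed)

  b <- runif(na); b[config$ref_item] <- 1
  cpar <- runif(nc); dpar <- runif(nd)
  lambda <- c(1, runif(stats$n1)); eta <- c(1, runif(stats$n2))
  keep_from <- if (config$keep_all) 1L else config$burn_in + 1L
  kept <- config$n_iter - keep_from + 1L
  Bm <- matrix(NA_real_, kept, na)
  Cm <- matrix(NA_real_, kept, max(nc, 1L))[, seq_len(nc), drop = FALSE]
  Dm <- matrix(NA_real_, kept, max(nd, 1L))[, seq_len(nd), drop = FALSE]
  Lm <- matrix(NA_real_, kept, stats$n1 + 1L)
  Em <- matrix(NA_real_, kept, stats$n2 + 1L)
  acc <- numeric(na)
  row <- 0L
  for (it in seq_len(config$n_iter)) {
    for (i in setdiff(seq_len(na), config$ref_item)) {  # anchors: Metropolis
      aa <- anchor_coefficients(b, cpar, dpar, lambda, eta, i)
      up <- mh_update_anchor(b[i], ka[i], aa[1L], aa[2L], m1, m2)
      b[i] <- up$b_i
      acc[i] <- acc[i] + up$accepted
    }
    for (j in seq_len(nc)) {            # unique items: conjugate, own group
      cpar[j] <- exp(item_update_cpp(log(c(b, cpar)), log(lambda),
                                     na + j, kc[j], m1))
    }
    for (j in seq_len(nd)) {
      dpar[j] <- exp(item_update_cpp(log(c(b, dpar)), log(eta),
                                     na + j, kd[j], m2))
    }
    lg1 <- log(c(b, cpar))
    for (t in 1:stats$n1)
      lambda[t + 1L] <- exp(lambda_update_cpp(lg1, log(lambda), t,
                                              kl[t + 1L], m1, FALSE))
    if (m2 > 0) {
      lg2 <- log(c(b, dpar))
      for (t in 1:stats$n2)
        eta[t + 1L] <- exp(lambda_update_cpp(lg2, log(eta), t,
                                             ke[t + 1L], m2, FALSE))
    }
    if (it >= keep_from) {
      row <- row + 1L
      Bm[row, ] <- b; Lm[row, ] <- lambda; Em[row, ] <- eta
      if (nc) Cm[row, ] <- cpar
      if (nd) Dm[row, ] <- dpar
    }
  }
  colnames(Bm) <- stats$anchor_ids
  colnames(Lm) <- paste0("lambda_", 0:stats$n1)
  colnames(Em) <- paste0("eta_", 0:stats$n2)
  if (nc) colnames(Cm) <- stats$unique1_ids
  if (nd) colnames(Dm) <- stats$unique2_ids
  structure(list(b = Bm, c = Cm, d = Dm, lambda = Lm, eta = Em,
                 iteration = keep_from:config$n_iter,
                 burn_in = config$burn_in, n_iter = config$n_iter,
                 config = config,
                 accept_rate = stats::setNames(
                   ifelse(seq_len(na) == config$ref_item, NA,
                          acc / config$n_iter), stats$anchor_ids)),
            class = "neat_draws")
}

#' @export
print.neat_draws <- function(x, ...) {
  cat("NEAT Metropolis-within-Gibbs draws\n")
  cat(" anchor items:", ncol(x$b), " stored iterations:",
      length(x$iteration), "\n")
  cat(" anchor acceptance rates:",
      paste(round(x$accept_rate, 3), collapse = " "), "\n")
  invisible(x)
}
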