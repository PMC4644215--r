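#' Elementary symmetric functions in log space
#'
#' Computes `log(gamma_s(b))` for `s = 0..n`, where `gamma_s(b)` is the sum
#' over all size-`s` subsets of `b` of the product of the selected elements.
#' These are the normalizing combinatorics of the conditional Rasch
#' likelihood.  The computation uses the one-item-at-a-time recursion
#' `gamma_s(b) = gamma_s(b^(i)) + b_i gamma_{s-1}(b^(i))` carried out
#' entirely in log space, so no intermediate value can overflow even for
#' several hundred items.
#'
#' @param b numeric vector of positive, finite item easiness values.
#' @return numeric vector of length `length(b) + 1` with the log ESF values;
#'   element `s + 1` holds `log(gamma_s)`.  `gamma_0 = 1` always, so the
#'   first element is 0.
#' @seealso [esf_drop()], [esf_poly_log()]
#' @examples
#' exp(esf_log(c(1, 2, 3)))  # 1 6 11 6
#' @export
esf_log <- function(b) {
  if (length(b) < 1L)
    stop("need at least one item")
  if (!is.numeric(b) || anyNA(b) || any(!is.finite(b)) || any(b <= 0))
    stop("item easiness values must be positive and finite")
  esf_log_cpp(log(b))
}

#' Log ESFs with one item removed
#'
#' Log elementary symmetric functions of `b` with element `i` removed,
#' needed by the full conditional distribution of an item parameter.  The
#' reduced vector is recomputed from scratch rather than obtained by
#' reverse-updating the recursion: downdating suffers catastrophic
#' cancellation.  The resulting quadratic cost per sweep is accepted.
#'
#' @param b numeric vector of positive item easiness values, length >= 2.
#' @param i index of the item to remove.
#' @return numeric vector of length `length(b)`: log ESFs of `b[-i]`.
#' @export
esf_drop <- function(b, i) {
  if (length(b) < 2L)
    stop("need at least two items to drop one")
  if (length(i) != 1L || is.na(i) || i < 1L || i > length(b))
    stop("item index out of range")
  esf_log(b[-i])
}

#' Log ESFs for a polytomous item bank with integer score weights
#'
#' Generalized elementary symmetric functions
#' `gamma_s = sum over category patterns with weighted total s of
#' prod b_ij^(y_ij)`, computed by the corresponding one-item-at-a-time
#' recursion in log space.  Category 0 of every item has weight 0 and
#' easiness 1 implicitly.  Scores that no category pattern can reach are
#' reported as `-Inf` and flagged in the `"support"` attribute.
#'
#' @param bank a [poly_bank()] object (integer category weights plus
#'   positive category easiness values per item).
#' @return numeric vector of length `max_score + 1` of log generalized ESF
#'   values, with attribute `support`: a logical vector marking achievable
#'   scores.
#' @examples
#' bank <- poly_bank(weights = list(c(1, 2)), b = list(c(2, 5)))
#' exp(esf_poly_log(bank))  # 1 2 5
#' @export
esf_poly_log <- function(bank) {
  bank <- as_poly_bank(bank)
  smax <- sum(vapply(bank$weights, max, 0L))
  lg <- c(0, rep(-Inf, smax))
  for (i in seq_along(bank$weights)) {
    a <- bank$weights[[i]]
    logb <- log(bank$b[[i]])
    new <- lg  # category 0: weight 0, easiness 1
    for (j in seq_along(a)) {
      sh <- c(rep(-Inf, a[j]), lg[seq_len(smax + 1L - a[j])]) + logb[j]
      new <- vlogadd(new, sh)
    }
    lg <- new
  }
  structure(lg, support = is.finite(lg))
}
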