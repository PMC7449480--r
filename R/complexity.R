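#' Hurst exponent by corrected rescaled-range analysis
#'
#' Classical R/S analysis over a dyadic ladder of window sizes with the
#' Anis-Lloyd-Peters small-sample correction: the estimate is 0.5 plus the
#' slope of `log(R/S) - log(E[R/S under iid])` against `log(window)`, which
#' removes the well-known upward bias of raw R/S at the window sizes used
#' here. White noise maps to ~0.5, persistent (fractional) noise above 0.5.
#'
#' @param epoch an [epoched_signal()] or numeric vector.
#' @param min_window smallest window of the dyadic ladder.
#' @param corrected apply the Anis-Lloyd-Peters correction (default TRUE).
#' @return estimated Hurst exponent.
#' @export
hurst_exponent <- function(epoch, min_window = 16, corrected = TRUE) {
  x <- if (inherits(epoch, "epoched_signal")) epoch$samples else as.numeric(epoch)
  n <- length(x)
  if (n < 4 * min_window) stop("series too short for R/S analysis")
  if (stats::var(x) == 0) stop("zero-variance signal: Hurst exponent undefined")
  sizes <- min_window * 2^(0:floor(log2(n / (2 * min_window))))
  rs <- vapply(sizes, function(m) {
    nb <- floor(n / m)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * m + 1):(b * m)]
      z <- cumsum(seg - mean(seg))
      r <- max(z) - min(z)
      s <- stats::sd(seg)
      if (s == 0) NA_real_ else r / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  lr <- log(rs)
  if (corrected) lr <- lr - log(vapply(sizes, expected_rs, numeric(1)))
  fit <- stats::lm(lr ~ log(sizes))
  slope <- unname(stats::coef(fit)[2])
  if (corrected) 0.5 + slope else slope
}

# Anis-Lloyd expected R/S of an iid series of length n (Peters' finite-n form).
expected_rs <- function(n) {
  i <- seq_len(n - 1)
  fac <- if (n <= 340) {
    exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi)
  } else {
    1 / sqrt(n * pi / 2)
  }
  ((n - 0.5) / n) * fac * sum(sqrt((n - i) / i))
}

#' Approximate entropy (ApEn)
#'
#' Pincus' regularity statistic: the difference of average log template-match
#' frequencies at embedding dimensions `m` and `m + 1`, Chebyshev distance,
#' self-matches included. Low for regular signals (0 for a constant), higher
#' for irregular ones.
#'
#' @param epoch an [epoched_signal()] or numeric vector.
#' @param m embedding dimension.
#' @param r tolerance in signal units; when `NULL`, the conventional
#'   `0.2 * sd(x)` is used (for a non-degenerate signal).
#' @return non-negative entropy rate (nats).
#' @export
approximate_entropy <- function(epoch, m = 2, r = NULL) {
  x <- if (inherits(epoch, "epoched_signal")) epoch$samples else as.numeric(epoch)
  if (is.null(r)) {
    s <- stats::sd(x)
    r <- if (s > 0) 0.2 * s else 1e-12
  }
  if (r <= 0) stop("tolerance r must be positive")
  apen_cpp(x, as.integer(m), r)
}

#' Lempel-Ziv complexity of a median-binarized signal
#'
#' The signal is binarized at its median, parsed by the exhaustive-history
#' LZ76 production rule into `c(n)` words, and normalized as
#' `c(n) * log2(n) / n`, which tends to 1 for i.i.d. binary noise.
#'
#' @param epoch an [epoched_signal()] or numeric vector (length >= 2).
#' @return normalized complexity (dimensionless).
#' @seealso [lz76_word_count()] for the raw production count.
#' @export
lempel_ziv_complexity <- function(epoch) {
  x <- if (inherits(epoch, "epoched_signal")) epoch$samples else as.numeric(epoch)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  bits <- as.integer(x > stats::median(x))
  lz76_cpp(bits) * log2(n) / n
}

#' LZ76 production count of a binary sequence
#'
#' @param bits integer/logical vector of 0s and 1s.
#' @return the number of words in the exhaustive-history parse.
#' @export
lz76_word_count <- function(bits) lz76_cpp(as.integer(bits))

#' Normalized permutation entropy (PeEn)
#'
#' Shannon entropy of the distribution of ordinal patterns of `order`
#' consecutive (lagged) samples, normalized by `log(order!)`. Ties are broken
#' by order of occurrence. 0 for a monotone ramp; tends to 1 for i.i.d.
#' continuous noise.
#'
#' @param epoch an [epoched_signal()] or numeric vector.
#' @param order pattern length (>= 2).
#' @param lag sample lag between pattern elements.
#' @return value in `[0, 1]`.
#' @export
permutation_entropy <- function(epoch, order = 3, lag = 1) {
  x <- if (inherits(epoch, "epoched_signal")) epoch$samples else as.numeric(epoch)
  n <- length(x)
  if (order < 2) stop("order must be >= 2")
  if (n <= order * lag) stop("series too short for this order and lag")
  nw <- n - (order - 1) * lag
  idx <- outer(seq_len(nw), seq(0, (order - 1) * lag, by = lag), "+")
  w <- matrix(x[idx], nrow = nw)
  # rank of element j within its window, ties broken by position (equivalent
  # to rank(ties.method = "first")), vectorized over windows
  ranks <- matrix(1L, nw, order)
  for (j in seq_len(order)) for (k in seq_len(order)) if (k != j)
    ranks[, j] <- ranks[, j] + (w[, k] < w[, j] | (w[, k] == w[, j] & k < j))
  codes <- as.vector(ranks %*% (order + 1)^(seq_len(order) - 1))
  p <- tabulate(factor(codes))
  p <- p / sum(p)
  -sum(p * log(p)) / log(factorial(order))
}
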