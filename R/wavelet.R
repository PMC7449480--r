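# Orthogonal Daubechies filters (scaling coefficients, sum = sqrt(2)).
.wavelet_filters <- list(
  db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728),
  db2 = c(0.48296291314469025, 0.83651630373746899, 0.22414386804185735,
          -0.12940952255092145)
)

wavelet_filter_pair <- function(family) {
  h <- .wavelet_filters[[family]]
  if (is.null(h)) stop(sprintf("unknown wavelet family '%s'", family))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

# one periodized analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, h, g) {
  N <- length(x)
  half <- N / 2
  L <- length(h)
  M <- outer(2 * (seq_len(half) - 1), 0:(L - 1), "+") %% N + 1
  xm <- matrix(x[M], nrow = half)
  list(approx = as.vector(xm %*% h), detail = as.vector(xm %*% g))
}

# inverse of dwt_step
idwt_step <- function(approx, detail, h, g) {
  half <- length(approx)
  N <- 2 * half
  L <- length(h)
  y <- numeric(N)
  for (k in seq_len(half)) {
    pos <- (2 * (k - 1) + 0:(L - 1)) %% N + 1
    y[pos] <- y[pos] + approx[k] * h + detail[k] * g
  }
  y
}

#' Discrete wavelet decomposition of an averaged AEP
#'
#' Periodized orthogonal DWT (Mallat pyramid) of the averaged waveform down
#' to `depth` levels, producing detail levels `D1` (finest) through
#' `D<depth>` and the approximation `A<depth>`. With an orthogonal family the
#' total coefficient energy equals the waveform energy.
#'
#' @param aep an [average_sweeps()] result, or a numeric waveform.
#' @param family `"db4"` (default) or `"db2"`.
#' @param depth number of levels; the waveform length must be divisible by
#'   `2^depth`.
#' @return a `wavelet_decomposition`: list with `levels` (named list of
#'   coefficient vectors), `family`, `n`, `sampling_rate`, `window`.
#' @export
decompose <- function(aep, family = "db4", depth = 5) {
  if (inherits(aep, "averaged_aep")) {
    x <- aep$waveform; fs <- aep$sampling_rate; win <- aep$window
  } else {
    x <- as.numeric(aep); fs <- NA_real_; win <- c(0, length(x))
  }
  n <- length(x)
  if (depth < 1 || n %% 2^depth != 0 || n / 2^depth < 1)
    stop(sprintf("depth %d too large for waveform length %d", depth, n))
  fp <- wavelet_filter_pair(family)
  levels <- list()
  a <- x
  for (j in seq_len(depth)) {
    st <- dwt_step(a, fp$h, fp$g)
    levels[[paste0("D", j)]] <- st$detail
    a <- st$approx
  }
  levels[[paste0("A", depth)]] <- a
  structure(list(levels = levels, family = family, n = n,
                 sampling_rate = fs, window = win),
            class = "wavelet_decomposition")
}

#' Inverse wavelet transform
#'
#' @param dec a [decompose()] result.
#' @param keep optional character vector of level labels; all other levels
#'   are zeroed before inversion (the "retransformed" single-level waveform).
#' @return reconstructed numeric waveform.
#' @export
reconstruct <- function(dec, keep = NULL) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  fp <- wavelet_filter_pair(dec$family)
  lv <- dec$levels
  if (!is.null(keep)) {
    for (nm in names(lv)) if (!(nm %in% keep)) lv[[nm]] <- lv[[nm]] * 0
  }
  depth <- length(lv) - 1
  a <- lv[[paste0("A", depth)]]
  for (j in rev(seq_len(depth))) {
    a <- idwt_step(a, lv[[paste0("D", j)]], fp$h, fp$g)
  }
  a
}
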