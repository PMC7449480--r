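entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a feature over its best threshold split
#'
#' Scores a single feature against binary class labels: the gain is the class
#' entropy minus the weighted entropy of the two sides of a threshold split,
#' maximized over all candidate thresholds placed at midpoints between
#' consecutive distinct sorted feature values (the C4.5 convention). Entropy
#' is base 2, so a perfectly separating feature on balanced labels scores
#' 1 bit.
#'
#' @param values numeric feature values.
#' @param labels binary labels (factor/character/logical), same length.
#' @return list with `gain` (bits) and `threshold` (NA for a constant
#'   feature). A single-class input yields gain 0 with a warning.
#' @export
information_gain <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2)
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2) {
    warning("single-class labels: information gain is 0")
    return(list(gain = 0, threshold = NA_real_))
  }
  n <- length(values)
  o <- order(values)
  v <- values[o]
  pos <- (y[o] == 1L)
  h0 <- entropy_bits(table(y))
  # cumulative class counts left of each cut between positions i and i+1
  cl1 <- cumsum(pos)[-n]
  cl <- seq_len(n - 1)
  valid <- v[-1] != v[-n]          # cuts only between distinct values
  if (!any(valid)) return(list(gain = 0, threshold = NA_real_))
  cl1 <- cl1[valid]; cl <- cl[valid]
  n1 <- sum(pos)
  hsplit <- function(a, b) {       # entropy of a two-class count pair, vectorized
    tot <- a + b
    pa <- ifelse(tot > 0, a / tot, 0); pb <- 1 - pa
    -(ifelse(pa > 0, pa * log2(pa), 0) + ifelse(pb > 0, pb * log2(pb), 0))
  }
  hl <- hsplit(cl1, cl - cl1)
  hr <- hsplit(n1 - cl1, (n - cl) - (n1 - cl1))
  gains <- h0 - (cl / n) * hl - ((n - cl) / n) * hr
  best <- which.max(gains)
  cut_pos <- which(valid)[best]
  list(gain = max(0, gains[best]),
       threshold = (v[cut_pos] + v[cut_pos + 1]) / 2)
}

#' Rank features by information gain
#'
#' Scores every feature column with [information_gain()] and sorts
#' descending; ties keep the original column order (stable sort).
#'
#' @param x data frame or matrix of feature columns (no metadata).
#' @param labels binary labels.
#' @return a `feature_ranking` data frame: `rank`, `feature`, `gain_bits`,
#'   `threshold`.
#' @export
rank_features <- function(x, labels) {
  x <- as.data.frame(x)
  if (ncol(x) < 1) stop("no feature columns to rank")
  scored <- lapply(x, information_gain, labels = labels)
  gains <- vapply(scored, `[[`, numeric(1), "gain")
  thr <- vapply(scored, `[[`, numeric(1), "threshold")
  o <- order(-gains)               # base order() is stable: ties keep column order
  structure(data.frame(rank = seq_along(o), feature = names(x)[o],
                       gain_bits = unname(gains[o]), threshold = unname(thr[o]),
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

#' Top-n features of a ranking
#'
#' @param ranking a [rank_features()] result.
#' @param n how many features (1 <= n <= nrow(ranking)).
#' @return character vector of feature names in rank order.
#' @export
top_n_features <- function(ranking, n) {
  if (n < 1 || n > nrow(ranking)) stop("n out of range for this ranking")
  ranking$feature[seq_len(n)]
}
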