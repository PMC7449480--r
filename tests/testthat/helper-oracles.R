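# Independent brute-force oracles, deliberately written differently from the
# package implementations.

# exhaustive pairwise P_K: loop over all cross-state pairs
pk_oracle <- function(states, indicator) {
  u <- which(states == "unconscious" | states == 1)
  c_ <- which(states == "conscious" | states == 0)
  C <- D <- T_ <- 0
  for (i in u) for (j in c_) {
    if (indicator[i] > indicator[j]) C <- C + 1
    else if (indicator[i] < indicator[j]) D <- D + 1
    else T_ <- T_ + 1
  }
  (C + T_ / 2) / (C + D + T_)
}

# exhaustive-history LZ76 parse by literal substring search
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s); c <- 0; i <- 1
  while (i <= n) {
    k <- 1
    repeat {
      phrase <- substr(s, i, i + k - 1)
      hist <- substr(s, 1, i + k - 2)
      if (i + k - 1 > n) break
      if (!grepl(phrase, hist, fixed = TRUE)) break
      k <- k + 1
    }
    c <- c + 1
    i <- i + k
  }
  c
}

# naive double-loop ApEn (self-matches included, Chebyshev distance)
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1
    templ <- sapply(seq_len(nv), function(i) x[i:(i + mm - 1)])
    logs <- sapply(seq_len(nv), function(i) {
      cnt <- 0
      for (j in seq_len(nv))
        if (max(abs(templ[, i] - templ[, j])) <= r) cnt <- cnt + 1
      log(cnt / nv)
    })
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# permutation entropy by explicit pattern enumeration
peen_oracle <- function(x, order, lag) {
  n <- length(x)
  pats <- character(0)
  for (i in seq_len(n - (order - 1) * lag)) {
    w <- x[seq(i, by = lag, length.out = order)]
    pats <- c(pats, paste(order(w), collapse = "-"))
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p)) / log(factorial(order))
}

# information gain by explicit enumeration of all midpoint thresholds
ig_oracle <- function(values, labels) {
  H <- function(lab) {
    p <- table(lab) / length(lab)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  v <- sort(unique(values))
  if (length(v) < 2) return(list(gain = 0, threshold = NA_real_))
  cuts <- (v[-1] + v[-length(v)]) / 2
  h0 <- H(labels)
  best_g <- -Inf; best_t <- NA
  for (t in cuts) {
    l <- labels[values <= t]; r <- labels[values > t]
    g <- h0 - length(l) / length(labels) * H(l) - length(r) / length(labels) * H(r)
    if (g > best_g) { best_g <- g; best_t <- t }
  }
  list(gain = max(0, best_g), threshold = best_t)
}

# fractional Gaussian noise via circulant embedding of the fGn autocovariance
fgn_oracle <- function(n, H) {
  k <- 0:(n - 1)
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(gamma, gamma[(n - 1):2])
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0
  m <- length(circ)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(lambda / m) * z))[1:n] / sqrt(2)
}

# small fast cohort configs used across tests: study-condition effect sizes,
# reduced patient/sweep counts for runtime
fast_cohort <- function(n_patients = 6, seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = n_patients, sweeps_per_aep = 96,
                                seed = seed, ...))
}

# one-f_high EEG catalog keeps feature extraction quick where filter variants
# are not the thing under test
eeg_catalog_f49 <- function() {
  cat <- default_eeg_catalog()
  cat[cat$f_high == 49 & is.na(cat$band_low), , drop = FALSE]
}

# gaussian toy feature table: n_informative features shift with state
toy_feature_table <- function(n_patients = 8, points_per_state = 4,
                              n_informative = 5, n_noise = 5,
                              effect = 1.5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    off <- rnorm(1, 0, 0.3)
    for (s in c("conscious", "unconscious")) for (k in seq_len(points_per_state)) {
      shift <- if (s == "unconscious") effect else 0
      x <- c(rnorm(n_informative, off + shift), rnorm(n_noise))
      rec <- data.frame(patient_id = sprintf("P%02d", p), event = paste0("E", k),
                        state = s, stringsAsFactors = FALSE)
      rec[c(sprintf("EEG_inf_%02d", seq_len(n_informative)),
            sprintf("EEG_noise_%02d", seq_len(n_noise)))] <- as.list(x)
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# toy table whose noise features share a latent factor (correlated nuisance
# dimensions, as real spectral/wavelet parameters are)
toy_corr_table <- function(n_patients = 8, points_per_state = 4,
                           n_informative = 5, n_noise = 95, effect = 1.2,
                           rho = 0.6, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    off <- rnorm(1, 0, 0.3)
    for (s in c("conscious", "unconscious")) for (k in seq_len(points_per_state)) {
      shift <- if (s == "unconscious") effect else 0
      z <- rnorm(1)
      x <- c(rnorm(n_informative, off + shift),
             sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_noise))
      rec <- data.frame(patient_id = sprintf("P%02d", p), event = paste0("E", k),
                        state = s, stringsAsFactors = FALSE)
      rec[c(sprintf("EEG_inf_%02d", seq_len(n_informative)),
            sprintf("EEG_noise_%02d", seq_len(n_noise)))] <- as.list(x)
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
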