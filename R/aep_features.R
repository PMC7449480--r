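#' Average stimulus-locked AEP sweeps
#'
#' Optionally high-passes the sweeps at `highpass` Hz and averages them
#' pointwise. Filtering and averaging are both linear, so the filter is
#' applied once to the mean (identical result, one `filtfilt` instead of one
#' per sweep).
#'
#' @param sweep_set an [aep_sweep_set()], or a numeric matrix (one row per
#'   sweep) with `sampling_rate` given.
#' @param highpass pre-average high-pass edge in Hz; `NULL` disables it.
#' @param sampling_rate required when `sweep_set` is a bare matrix.
#' @param window `(from, to)` ms, required when `sweep_set` is a bare matrix.
#' @return an `averaged_aep`: list with `waveform` (uV), `sampling_rate`,
#'   `n_sweeps_used`, `window`, plus provenance metadata.
#' @export
average_sweeps <- function(sweep_set, highpass = 25, sampling_rate = NULL,
                           window = NULL) {
  if (inherits(sweep_set, "aep_sweep_set")) {
    m <- sweep_set$sweeps; fs <- sweep_set$sampling_rate; win <- sweep_set$window
    pid <- sweep_set$patient_id; ev <- sweep_set$event_label; st <- sweep_set$state
  } else {
    m <- as.matrix(sweep_set); fs <- sampling_rate; win <- window
    pid <- NA; ev <- NA; st <- NA
  }
  if (nrow(m) < 1) stop("empty sweep set")
  if (is.null(fs)) stop("sampling rate required")
  avg <- colMeans(m)
  if (!is.null(highpass) && highpass > 0) {
    hp <- signal::butter(2, highpass / (fs / 2), type = "high")
    avg <- as.numeric(signal::filtfilt(hp, avg))
  }
  structure(list(waveform = avg, sampling_rate = fs, n_sweeps_used = nrow(m),
                 window = win, patient_id = pid, event_label = ev, state = st),
            class = "averaged_aep")
}

#' Default AEP parameter catalog (80 columns)
#'
#' Five wavelet-derived parameter families over a depth-5 decomposition of a
#' 128-sample (0-128 ms at 1 kHz) averaged mid-latency AEP:
#' per level D1..D5, A5 the coefficient-maximum amplitude (`amp`), its
#' latency in ms (`lat`), the level energy (`en`), the maximum amplitude of
#' the single-level reconstruction (`rtmax`), and the variance of the second
#' finite difference of the coefficient sequence (`v2d`) — 30 parameters;
#' plus 50 selected raw coefficients: all of D3 (16), D4 (8), D5 (4) and A5
#' (4), and the 18 D2 coefficients whose support centers fall in the
#' mid-latency range (~20-92 ms). Which coefficients enter an AEP index is a
#' catalog choice; this one is an explicit, documented default.
#'
#' @return data frame with columns `name`, `kind`, `level`, `index`.
#' @export
default_aep_catalog <- function() {
  levels6 <- c("D1", "D2", "D3", "D4", "D5", "A5")
  summ <- expand.grid(kind = c("amp", "lat", "en", "rtmax", "v2d"),
                      level = levels6, stringsAsFactors = FALSE)
  summ$index <- NA_integer_
  summ$name <- sprintf("AEP_%s_%s", summ$kind, summ$level)
  coefs <- rbind(
    data.frame(level = "D3", index = 1:16),
    data.frame(level = "D4", index = 1:8),
    data.frame(level = "D5", index = 1:4),
    data.frame(level = "A5", index = 1:4),
    data.frame(level = "D2", index = 6:23)
  )
  coefs$kind <- "coef"
  coefs$name <- sprintf("AEP_c_%s_%02d", coefs$level, coefs$index)
  rbind(summ[, c("name", "kind", "level", "index")],
        coefs[, c("name", "kind", "level", "index")])
}

# time (ms) of the center of support of coefficient k at a given level:
# coefficient k (0-based) at level j draws on samples
# [2^j k, 2^j k + (2^j - 1)(L - 1)] of the periodized waveform, so its
# center is 2^j k + (2^j - 1)(L - 1)/2, taken modulo the window length
level_times_ms <- function(dec, level) {
  depth <- length(dec$levels) - 1
  j <- if (grepl("^A", level)) depth else as.integer(sub("D", "", level))
  L <- length(.wavelet_filters[[dec$family]])
  stride <- 2^j
  k0 <- seq_along(dec$levels[[level]]) - 1
  centers <- (stride * k0 + (stride - 1) * (L - 1) / 2) %% dec$n
  dec$window[1] + (centers + 0.5) * 1000 / dec$sampling_rate
}

#' Wavelet-derived AEP parameters
#'
#' Evaluates a parameter catalog against a wavelet decomposition of an
#' averaged AEP. Amplitude is `max(abs(coef))` of a level, latency the time
#' (ms post-stimulus, center of coefficient support) of that maximum —
#' reported as `NA` for an all-zero level, never 0. Energy is the sum of
#' squared coefficients; `rtmax` the maximum absolute amplitude of the
#' waveform reconstructed from that level alone; `v2d` the variance of the
#' second finite difference of the coefficient sequence.
#'
#' @param dec a [decompose()] result.
#' @param catalog see [default_aep_catalog()].
#' @return named numeric vector, one element per catalog row.
#' @export
aep_parameters <- function(dec, catalog = default_aep_catalog()) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  if (anyDuplicated(catalog$name)) stop("duplicate parameter names in catalog")
  out <- stats::setNames(numeric(nrow(catalog)), catalog$name)
  rt_cache <- list()
  for (i in seq_len(nrow(catalog))) {
    kind <- catalog$kind[i]
    lev <- catalog$level[i]
    coef <- dec$levels[[lev]]
    if (is.null(coef)) stop(sprintf("level %s absent from decomposition", lev))
    out[i] <- switch(kind,
      amp = max(abs(coef)),
      lat = if (all(coef == 0)) NA_real_ else
        level_times_ms(dec, lev)[which.max(abs(coef))],
      en = sum(coef^2),
      rtmax = {
        if (is.null(rt_cache[[lev]]))
          rt_cache[[lev]] <- max(abs(reconstruct(dec, keep = lev)))
        rt_cache[[lev]]
      },
      v2d = stats::var(diff(coef, differences = 2)),
      coef = coef[catalog$index[i]],
      stop(sprintf("unknown parameter kind '%s'", kind))
    )
  }
  out
}

#' AEP feature matrix over a cohort of sweep sets
#'
#' Averages each sweep set (25 Hz pre-average high-pass by default), wavelet
#' transforms it and evaluates the parameter catalog, yielding one row per
#' data point.
#'
#' @param sweep_sets list of [aep_sweep_set()].
#' @param catalog see [default_aep_catalog()].
#' @param highpass pre-average high-pass in Hz.
#' @param family,depth passed to [decompose()].
#' @return data frame with metadata columns `patient_id`, `event`, `state`
#'   and one column per catalog row.
#' @export
aep_feature_matrix <- function(sweep_sets, catalog = default_aep_catalog(),
                               highpass = 25, family = "db4", depth = 5) {
  if (length(sweep_sets) == 0) return(data.frame())
  rows <- lapply(sweep_sets, function(ss) {
    avg <- average_sweeps(ss, highpass = highpass)
    dec <- decompose(avg, family = family, depth = depth)
    pars <- aep_parameters(dec, catalog)
    rec <- data.frame(patient_id = ss$patient_id, event = ss$event_label,
                      state = ss$state, stringsAsFactors = FALSE)
    rec[names(pars)] <- as.list(unname(pars))
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
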