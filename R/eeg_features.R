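#' Default EEG parameter catalog (23 columns)
#'
#' The seven signal measures (WSMF, qWSMF, SEn, HEx, ApEn, LZc, PeEn) crossed
#' with the three low-pass variants `f_high` = 30, 49, 90 Hz give 21
#' parameters; two band-restricted spectral variants (beta-band WSMF and
#' delta/alpha-band spectral entropy, both at `f_high` = 49 Hz) complete the
#' 23-column catalog. The catalog is data: rows can be added, dropped or
#' re-parameterized without touching code.
#'
#' @return data frame with columns `name`, `measure`, `f_high`, `band_low`,
#'   `band_high` (NA = full analysis band 0.5 Hz to `f_high`).
#' @export
default_eeg_catalog <- function() {
  base <- expand.grid(measure = c("WSMF", "qWSMF", "SEn", "HEx", "ApEn", "LZc", "PeEn"),
                      f_high = c(30, 49, 90), stringsAsFactors = FALSE)
  base$band_low <- NA_real_
  base$band_high <- NA_real_
  extra <- data.frame(measure = c("WSMF", "SEn"), f_high = c(49, 49),
                      band_low = c(8, 0.5), band_high = c(30, 12),
                      stringsAsFactors = FALSE)
  cat <- rbind(base, extra)
  cat$name <- ifelse(is.na(cat$band_low),
                     sprintf("EEG_%s_f%d", cat$measure, cat$f_high),
                     sprintf("EEG_%s_b%g_%g_f%d", cat$measure, cat$band_low,
                             cat$band_high, cat$f_high))
  cat[, c("name", "measure", "f_high", "band_low", "band_high")]
}

# keep-every-k-th decimation; safe after low-pass filtering below the new
# Nyquist (f_high <= 90 Hz << 125 Hz at factor 4 from 1 kHz)
decimate_samples <- function(x, factor) x[seq(1, length(x), by = factor)]

compute_eeg_measure <- function(row, filtered, apen_decimate) {
  band <- c(if (is.na(row$band_low)) 0.5 else row$band_low,
            if (is.na(row$band_high)) row$f_high else row$band_high)
  switch(row$measure,
    WSMF = wsmf(estimate_spectrum(filtered, band)),
    qWSMF = qwsmf(filtered, band_a = c(8, 30), band_b = c(0.5, row$f_high)),
    SEn = spectral_entropy(estimate_spectrum(filtered, band)),
    HEx = hurst_exponent(filtered),
    ApEn = approximate_entropy(decimate_samples(filtered$samples, apen_decimate), m = 2),
    LZc = lempel_ziv_complexity(filtered),
    PeEn = permutation_entropy(filtered, order = 3, lag = 1),
    stop(sprintf("unknown EEG measure '%s'", row$measure))
  )
}

#' EEG feature matrix over a catalog of measure x filter variants
#'
#' Filters each epoch once per distinct `f_high`, evaluates every catalog
#' entry, and assembles one row per non-artifact data point. Epochs flagged
#' by [detect_artifacts()] are excluded up front; rows where any measure
#' errs (degenerate signal) are dropped and reported via a message.
#'
#' @param epochs list of [epoched_signal()].
#' @param catalog parameter catalog, see [default_eeg_catalog()].
#' @param exclude_artifacts drop epochs failing the artifact rules.
#' @param apen_decimate decimation factor applied before ApEn (see vignette).
#' @param low_cut high-pass edge in Hz shared by all variants.
#' @return data frame with metadata columns `patient_id`, `event`, `state`
#'   and one numeric column per catalog row; attribute `excluded` lists
#'   dropped data points.
#' @export
eeg_feature_matrix <- function(epochs, catalog = default_eeg_catalog(),
                               exclude_artifacts = TRUE, apen_decimate = 4,
                               low_cut = 0.5) {
  if (length(epochs) == 0)
    return(structure(data.frame(), excluded = data.frame()))
  if (anyDuplicated(catalog$name)) stop("duplicate feature names in catalog")
  excluded <- list()
  rows <- list()
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    if (exclude_artifacts) {
      rep <- detect_artifacts(e)
      if (rep$flagged) {
        excluded[[length(excluded) + 1]] <-
          data.frame(patient_id = e$patient_id, event = e$event_label,
                     state = e$state, reason = paste(rep$reasons, collapse = ";"),
                     stringsAsFactors = FALSE)
        next
      }
    }
    filtered <- lapply(stats::setNames(nm = unique(catalog$f_high)), function(fh)
      apply_filter(e, filter_spec(low_cut = low_cut, high_cut = fh)))
    vals <- vapply(seq_len(nrow(catalog)), function(j) {
      row <- catalog[j, ]
      tryCatch(compute_eeg_measure(row, filtered[[as.character(row$f_high)]],
                                   apen_decimate),
               error = function(err) NA_real_)
    }, numeric(1))
    rec <- data.frame(patient_id = e$patient_id, event = e$event_label,
                      state = e$state, stringsAsFactors = FALSE)
    rec[catalog$name] <- as.list(vals)
    rows[[length(rows) + 1]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) {
    bad <- !stats::complete.cases(out)
    if (any(bad)) {
      message(sprintf("dropping %d data point(s) with failed measures", sum(bad)))
      excluded[[length(excluded) + 1]] <-
        data.frame(patient_id = out$patient_id[bad], event = out$event[bad],
                   state = out$state[bad], reason = "measure_error",
                   stringsAsFactors = FALSE)
      out <- out[!bad, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  structure(out, excluded = if (length(excluded)) do.call(rbind, excluded)
            else data.frame())
}
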