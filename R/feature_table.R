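#' Assemble the combined EEG/AEP feature table for a cohort
#'
#' Runs artifact rejection and feature extraction on a generated (or loaded)
#' cohort and inner-joins the EEG and AEP rows on (patient_id, event, state).
#' A data point whose EEG epoch fails the artifact rules is dropped entirely
#' (its AEP row too), mirroring removal of the whole data point.
#'
#' @param cohort a [generate_cohort()] result.
#' @param eeg_catalog,aep_catalog parameter catalogs.
#' @param ... passed to [eeg_feature_matrix()].
#' @return data frame with metadata columns `patient_id`, `event`, `state`
#'   followed by 23 EEG and 80 AEP feature columns (for the default
#'   catalogs); attribute `excluded` carries the dropped data points.
#' @export
build_feature_table <- function(cohort, eeg_catalog = default_eeg_catalog(),
                                aep_catalog = default_aep_catalog(), ...) {
  eeg <- eeg_feature_matrix(cohort$epochs, catalog = eeg_catalog, ...)
  aep <- aep_feature_matrix(cohort$sweep_sets, catalog = aep_catalog)
  out <- merge(eeg, aep, by = c("patient_id", "event", "state"), sort = FALSE)
  out <- out[order(out$patient_id, out$event, out$state), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = attr(eeg, "excluded"))
}

#' Split a feature table into metadata and feature columns
#'
#' @param table a feature table as built by [build_feature_table()].
#' @return list with `meta` (patient_id, event, state) and `x` (numeric
#'   feature columns).
#' @export
split_feature_table <- function(table) {
  meta_cols <- intersect(c("patient_id", "event", "state"), names(table))
  list(meta = table[, meta_cols, drop = FALSE],
       x = table[, setdiff(names(table), meta_cols), drop = FALSE])
}

#' Select feature columns by modality and EEG filter variant
#'
#' EEG columns carry an `_f<f_high>` suffix; AEP columns are not affected by
#' the EEG low-pass. `modality = "combined"` keeps both.
#'
#' @param table feature table.
#' @param modality one of `"EEG"`, `"AEP"`, `"combined"`.
#' @param f_high optional EEG low-pass variant (30, 49 or 90); `NULL` keeps
#'   all EEG variants.
#' @return the table restricted to metadata plus the selected columns.
#' @export
select_modality <- function(table, modality = c("combined", "EEG", "AEP"),
                            f_high = NULL) {
  modality <- match.arg(modality)
  nm <- names(table)
  meta <- intersect(c("patient_id", "event", "state"), nm)
  eeg <- grep("^EEG_", nm, value = TRUE)
  if (!is.null(f_high)) eeg <- grep(sprintf("_f%d$", f_high), eeg, value = TRUE)
  aep <- grep("^AEP_", nm, value = TRUE)
  keep <- switch(modality, EEG = eeg, AEP = aep, combined = c(eeg, aep))
  table[, c(meta, keep), drop = FALSE]
}
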