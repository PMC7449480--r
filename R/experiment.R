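#' Run a classifier x n-features x modality x f_high experiment matrix
#'
#' For every combination of classifier spec, feature-subset size, modality
#' set and EEG low-pass variant, runs leave-one-patient-out cross-validation
#' on the feature table and records the patient-wise mean/SD P_K. A failed
#' cell is marked and the run continues. Per classifier family, modality and
#' f_high a "best" row (maximum mean P_K over n and, for SVMs, over the C
#' values present in `specs`) is appended, with ties resolved toward fewer
#' features and lower C.
#'
#' @param table feature table (see [build_feature_table()]).
#' @param specs list of [classifier_spec()] objects.
#' @param n_values integer vector of feature-subset sizes (default 1:20).
#' @param modalities subset of `c("EEG", "AEP", "combined")`.
#' @param f_high_values EEG filter variants to evaluate (`NA` = all columns).
#' @param rank_mode passed to [leave_one_patient_out()].
#' @return a results ledger data frame: `classifier`, `C`, `n_features`,
#'   `modality`, `f_high`, `pk_mean`, `pk_sd`, `n_patients`, `status`,
#'   `best` (logical).
#' @export
run_matrix <- function(table, specs, n_values = 1:20,
                       modalities = "combined", f_high_values = NA,
                       rank_mode = "fold") {
  rows <- list()
  for (mod in modalities) for (fh in f_high_values) {
    sub <- select_modality(table, mod, f_high = if (is.na(fh)) NULL else fh)
    p_avail <- ncol(split_feature_table(sub)$x)
    for (spec in specs) for (n in n_values) {
      if (n > p_avail) next
      cell <- tryCatch({
        preds <- leave_one_patient_out(sub, spec, n_features = n,
                                       rank_mode = rank_mode)
        pw <- patientwise_pk(preds)
        data.frame(pk_mean = pw$pk_mean, pk_sd = pw$pk_sd,
                   n_patients = pw$n_patients, status = "ok")
      }, error = function(e)
        data.frame(pk_mean = NA_real_, pk_sd = NA_real_,
                   n_patients = NA_integer_, status = paste0("failed: ", conditionMessage(e))))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(classifier = spec$family, C = spec$C, n_features = n,
                   modality = mod, f_high = fh, stringsAsFactors = FALSE),
        cell)
    }
  }
  ledger <- do.call(rbind, rows)
  ledger$best <- FALSE
  ok <- ledger$status == "ok"
  for (key in unique(paste(ledger$classifier, ledger$modality, ledger$f_high))) {
    sel <- ok & paste(ledger$classifier, ledger$modality, ledger$f_high) == key
    if (!any(sel)) next
    cand <- which(sel)
    cand <- cand[order(-ledger$pk_mean[cand], ledger$n_features[cand],
                       ledger$C[cand])]
    ledger$best[cand[1]] <- TRUE
  }
  rownames(ledger) <- NULL
  ledger
}

# pooled P_K of a bare feature column, orientation chosen on a reference set
feature_pk <- function(values, states, orient = 1) {
  prediction_probability(states, orient * values)$pk
}

#' Final evaluation on the held-back patients
#'
#' Trains the chosen compound indicator (default: RBF-kernel SVM on the 20
#' top-ranked features, ranking done on the working set only) on all working
#' patients and scores the held-back patients, reporting the pooled P_K with
#' a patient-level bootstrap CI. Alongside, the best single AEP parameter and
#' the two best single EEG parameters — by pooled working-set P_K, with their
#' sign orientation also fixed on the working set — are evaluated on the same
#' holdout as comparators.
#'
#' @param table full feature table.
#' @param plan a [make_split()] plan; held-back ids must not intersect the
#'   working ids (audited).
#' @param spec compound classifier spec (default `svm_rbf`, C = 1).
#' @param n_features compound feature count (default 20).
#' @param B,seed bootstrap settings.
#' @return data frame with one row per indicator: `indicator`, `pk`,
#'   `ci_low`, `ci_high`, `n_points`.
#' @export
final_holdout_evaluation <- function(table, plan,
                                     spec = classifier_spec("svm_rbf", C = 1),
                                     n_features = 20, B = 2000, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  if (length(plan$held_back) == 0) stop("holdout is empty")
  if (length(intersect(plan$working, plan$held_back)) > 0)
    stop("split plan leaks: working and held-back patients overlap")
  work <- table[table$patient_id %in% plan$working, , drop = FALSE]
  hold <- table[table$patient_id %in% plan$held_back, , drop = FALSE]
  if (nrow(hold) == 0) stop("no holdout data points")
  pw <- split_feature_table(work)
  ph <- split_feature_table(hold)
  n_features <- min(n_features, ncol(pw$x))
  rk <- rank_features(pw$x, pw$meta$state)
  feats <- top_n_features(rk, n_features)
  model <- train_classifier(spec, pw$x[, feats, drop = FALSE], pw$meta$state)
  sc <- score_classifier(model, ph$x[, feats, drop = FALSE])
  rows <- list()
  add_row <- function(name, indicator) {
    pk <- prediction_probability(ph$meta$state, indicator)$pk
    ci <- bootstrap_ci(ph$meta$state, indicator, ph$meta$patient_id,
                       B = B, seed = seed)
    data.frame(indicator = name, pk = pk, ci_low = ci[1], ci_high = ci[2],
               n_points = length(indicator), stringsAsFactors = FALSE)
  }
  # single-parameter comparators chosen and oriented on the working set
  single_pk <- vapply(pw$x, function(v)
    prediction_probability(pw$meta$state, v)$pk, numeric(1))
  strength <- pmax(single_pk, 1 - single_pk)
  eeg_cols <- grep("^EEG_", names(single_pk), value = TRUE)
  aep_cols <- grep("^AEP_", names(single_pk), value = TRUE)
  best_eeg <- eeg_cols[order(-strength[eeg_cols])][seq_len(min(2, length(eeg_cols)))]
  best_aep <- aep_cols[order(-strength[aep_cols])][seq_len(min(1, length(aep_cols)))]
  for (col in c(best_eeg, best_aep)) {
    orient <- if (single_pk[[col]] >= 0.5) 1 else -1
    rows[[length(rows) + 1]] <- add_row(col, orient * ph$x[[col]])
  }
  rows[[length(rows) + 1]] <- add_row(
    sprintf("compound_%s_n%d", spec$family, n_features), sc$indicator)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, features = feats)
}
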