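as_unconscious01 <- function(states) {
  if (is.logical(states)) return(as.integer(states))
  if (is.numeric(states)) {
    if (!all(states %in% c(0, 1))) stop("numeric states must be 0/1 (1 = unconscious)")
    return(as.integer(states))
  }
  s <- as.character(states)
  if (!all(s %in% .state_levels)) stop("states must be 'conscious'/'unconscious'")
  as.integer(s == "unconscious")
}

#' Prediction probability (P_K)
#'
#' Pairwise concordance between a graded indicator and the binary clinical
#' state, the standard performance statistic of anesthesia monitors. Over
#' all pairs of data points with different true states, a pair is concordant
#' when the indicator orders it as the states do (convention: "unconscious"
#' is the higher indicator), discordant when opposite, tied when the
#' indicators are equal; `pk = (C + T/2) / (C + D + T)`. 1 is perfect
#' concordance, 0.5 chance level, 0 perfect discordance. For binary states
#' this equals the area under the ROC curve with ties counted half.
#'
#' @param states binary states ("conscious"/"unconscious", logical, or 0/1
#'   with 1 = unconscious); both states must be present.
#' @param indicator numeric indicator, same length.
#' @return a `pk_result`: list with `pk` and `n_pairs`
#'   (concordant/discordant/tied counts).
#' @export
prediction_probability <- function(states, indicator) {
  u <- as_unconscious01(states)
  if (length(u) != length(indicator)) stop("states and indicator lengths differ")
  if (length(unique(u)) < 2)
    stop("P_K undefined: only one state present")
  iu <- indicator[u == 1]
  ic <- indicator[u == 0]
  cmp <- outer(iu, ic, "-")
  C <- sum(cmp > 0); D <- sum(cmp < 0); Tt <- sum(cmp == 0)
  structure(list(pk = (C + Tt / 2) / (C + D + Tt),
                 n_pairs = c(concordant = C, discordant = D, tied = Tt)),
            class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  cat(sprintf("P_K = %.4f  (C=%d, D=%d, T=%d)\n", x$pk,
              x$n_pairs[1], x$n_pairs[2], x$n_pairs[3]))
  invisible(x)
}

#' Patient-wise P_K: per-patient values, mean and SD
#'
#' Computes P_K within each patient (using that patient's cross-state pairs
#' only), then the unweighted mean and sample SD (n-1) across patients.
#' Patients lacking a conscious or an unconscious point have no defined P_K
#' and are excluded with a logged reason.
#'
#' @param predictions data frame with columns `patient_id`, `state`,
#'   `indicator` (rows with `NA` indicator are dropped first).
#' @return list with `per_patient` (named vector), `pk_mean`, `pk_sd`,
#'   `n_patients`, `excluded` (data frame patient_id/reason).
#' @export
patientwise_pk <- function(predictions) {
  predictions <- predictions[!is.na(predictions$indicator), , drop = FALSE]
  ids <- unique(predictions$patient_id)
  per <- c(); exc <- list()
  for (pid in ids) {
    d <- predictions[predictions$patient_id == pid, ]
    u <- as_unconscious01(d$state)
    if (length(unique(u)) < 2) {
      exc[[length(exc) + 1]] <- data.frame(patient_id = pid,
                                           reason = "single_state",
                                           stringsAsFactors = FALSE)
      next
    }
    per[pid] <- prediction_probability(d$state, d$indicator)$pk
  }
  if (length(per) == 0) stop("no patient has both states: patient-wise P_K undefined")
  list(per_patient = per, pk_mean = mean(per),
       pk_sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       n_patients = length(per),
       excluded = if (length(exc)) do.call(rbind, exc) else data.frame())
}

#' Leave-one-patient-out cross-validation
#'
#' In each fold the data of one patient form the test set; feature ranking
#' (by default) and training use the remaining patients only, so no
#' information from the test patient reaches the model. The concatenated
#' fold predictions cover every data point exactly once; an `audit`
#' attribute records the training patients of every fold for leakage checks.
#'
#' @param table feature table with metadata columns `patient_id`, `state`
#'   (see [build_feature_table()]).
#' @param spec a [classifier_spec()].
#' @param n_features number of top-ranked features given to the classifier.
#' @param rank_mode `"fold"` (re-rank inside each training fold, default) or
#'   `"global"` (one ranking on the whole table).
#' @return predictions data frame (`patient_id`, `event`, `state`,
#'   `indicator`, `fold`) with attribute `audit`.
#' @export
leave_one_patient_out <- function(table, spec, n_features = 10,
                                  rank_mode = c("fold", "global")) {
  rank_mode <- match.arg(rank_mode)
  parts <- split_feature_table(table)
  ids <- unique(parts$meta$patient_id)
  if (length(ids) < 2) stop("need at least 2 patients for leave-one-out")
  n_features <- min(n_features, ncol(parts$x))
  global_rank <- if (rank_mode == "global")
    rank_features(parts$x, parts$meta$state) else NULL
  preds <- list(); audit <- list()
  for (f in seq_along(ids)) {
    test_id <- ids[f]
    tr <- parts$meta$patient_id != test_id
    y_tr <- parts$meta$state[tr]
    if (length(unique(y_tr)) < 2) {
      warning(sprintf("fold %s skipped: single-class training data", test_id))
      next
    }
    rk <- if (rank_mode == "fold")
      rank_features(parts$x[tr, , drop = FALSE], y_tr) else global_rank
    feats <- top_n_features(rk, n_features)
    model <- train_classifier(spec, parts$x[tr, feats, drop = FALSE], y_tr)
    sc <- score_classifier(model, parts$x[!tr, feats, drop = FALSE])
    preds[[length(preds) + 1]] <- data.frame(
      patient_id = parts$meta$patient_id[!tr],
      event = if ("event" %in% names(parts$meta)) parts$meta$event[!tr] else NA,
      state = parts$meta$state[!tr],
      indicator = sc$indicator, fold = f, stringsAsFactors = FALSE)
    audit[[as.character(test_id)]] <- setdiff(ids, test_id)
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  structure(out, audit = audit)
}

#' Patient-level bootstrap confidence interval for pooled P_K
#'
#' Resamples patients (the independent units) with replacement `B` times,
#' recomputes the pooled P_K over all points of each resample, and reports
#' the 2.5/97.5 percentile interval. Resamples where only one state
#' survives are discarded; if all are degenerate, an error is raised.
#'
#' @param states,indicator,patient_ids aligned vectors over the test set.
#' @param B number of resamples (>= 100).
#' @param seed RNG seed.
#' @return numeric `c(lower, upper)` with attribute `pk_boot` (the resample
#'   values).
#' @export
bootstrap_ci <- function(states, indicator, patient_ids, B = 2000, seed = 1L) {
  if (B < 100) stop("use at least 100 bootstrap resamples")
  u <- as_unconscious01(states)
  ids <- unique(patient_ids)
  by_pat <- split(seq_along(u), patient_ids)
  set.seed(seed)
  pks <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(by_pat[as.character(take)], use.names = FALSE)
    if (length(unique(u[idx])) < 2) next
    pks[b] <- prediction_probability(u[idx], indicator[idx])$pk
  }
  pks <- pks[!is.na(pks)]
  if (length(pks) == 0) stop("all bootstrap resamples degenerate")
  ci <- unname(stats::quantile(pks, c(0.025, 0.975)))
  structure(ci, pk_boot = pks)
}

#' Patient-level working/held-back split
#'
#' Randomly holds back `n_heldback` patients as a final test set; the rest
#' form the working set for cross-validated model comparison. The plan can
#' be serialized so the holdout stays immutable across runs.
#'
#' @param patient_ids vector of patient ids (unique or not).
#' @param n_heldback how many patients to hold back.
#' @param seed RNG seed.
#' @return a `split_plan`: list with `working` and `held_back`.
#' @export
make_split <- function(patient_ids, n_heldback = 10, seed = 1L) {
  ids <- unique(patient_ids)
  if (n_heldback >= length(ids)) stop("n_heldback must be smaller than the cohort")
  set.seed(seed)
  held <- if (n_heldback > 0) sample(ids, n_heldback) else character(0)
  structure(list(working = setdiff(ids, held), held_back = held),
            class = "split_plan")
}

#' @rdname make_split
#' @param plan a `split_plan`.
#' @param path file path for the serialized plan (tab-separated).
#' @export
write_split <- function(plan, path) {
  df <- data.frame(patient_id = c(plan$working, plan$held_back),
                   role = c(rep("working", length(plan$working)),
                            rep("held_back", length(plan$held_back))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(plan)
}

#' @rdname make_split
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(working = df$patient_id[df$role == "working"],
                 held_back = df$patient_id[df$role == "held_back"]),
            class = "split_plan")
}
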