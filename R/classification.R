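.svm_families <- c("svm_linear", "svm_poly", "svm_rbf", "svm_sigmoid")
.all_families <- c(.svm_families, "naive_bayes", "naive_bayes_kernel",
                   "logistic", "mlp", "tree_c45", "bayes_net")
.c_grid <- c(0.01, 0.1, 1, 10, 100)

#' Classifier specification
#'
#' Uniform description of one classifier family plus its hyperparameters,
#' following the study conventions: SVM cost `C` on the grid
#' {0.01, 0.1, 1, 10, 100}, kernel gamma fixed by the rule `1/n_features`,
#' polynomial degree 3.
#'
#' @param family one of `"svm_linear"`, `"svm_poly"`, `"svm_rbf"`,
#'   `"svm_sigmoid"`, `"naive_bayes"`, `"naive_bayes_kernel"`, `"logistic"`,
#'   `"mlp"`, `"tree_c45"`, `"bayes_net"`.
#' @param C SVM cost (ignored otherwise).
#' @param degree polynomial kernel degree.
#' @param gamma_rule only `"1/n_features"` is supported.
#' @param seed seed fixing stochastic training (MLP weight init).
#' @param grid_mode when TRUE, reject `C` values off the canonical grid.
#' @param settings named list of pinned family-specific settings
#'   (`mlp_decay`, `mlp_maxit`, `tree_minsplit`, `tree_cp`, `nb_laplace`).
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(family, C = 1, degree = 3,
                            gamma_rule = "1/n_features", seed = 42L,
                            grid_mode = FALSE, settings = list()) {
  family <- match.arg(family, .all_families)
  if (C <= 0) stop("C must be positive")
  if (grid_mode && family %in% .svm_families && !(C %in% .c_grid))
    stop(sprintf("C = %g is not on the canonical grid {%s}", C,
                 paste(.c_grid, collapse = ", ")))
  if (gamma_rule != "1/n_features") stop("unsupported gamma rule")
  defaults <- list(mlp_decay = 0.01, mlp_maxit = 300, tree_minsplit = 10,
                   tree_cp = 0.01, nb_laplace = 1)
  settings <- utils::modifyList(defaults, settings)
  structure(list(family = family, C = C, degree = degree,
                 gamma_rule = gamma_rule, seed = as.integer(seed),
                 grid_mode = grid_mode, settings = settings),
            class = "classifier_spec")
}

.state_levels <- c("conscious", "unconscious")

as_state_factor <- function(labels) {
  f <- factor(as.character(labels), levels = .state_levels)
  if (anyNA(f)) stop("labels must be 'conscious'/'unconscious'")
  f
}

#' Train a classifier on a feature table
#'
#' Standardizes every feature by its training mean and SD (constant columns
#' get scale 1), then fits the requested family. Training is deterministic
#' given `spec$seed`.
#'
#' @param spec a [classifier_spec()].
#' @param x data frame of numeric feature columns (no metadata).
#' @param labels binary state labels, both classes present.
#' @return an opaque `doa_model` handle for [score_classifier()].
#' @export
train_classifier <- function(spec, x, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.data.frame(x)
  if (nrow(x) < 2) stop("need at least 2 training rows")
  y <- as_state_factor(labels)
  if (length(unique(y)) < 2) stop("degenerate single-class training input")
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, stats::sd, numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- as.data.frame(scale(x, center = ctr, scale = scl))
  p <- ncol(xs)
  set.seed(spec$seed)
  fit <- switch(spec$family,
    svm_linear = ,
    svm_poly = ,
    svm_rbf = ,
    svm_sigmoid = {
      kernel <- c(svm_linear = "linear", svm_poly = "polynomial",
                  svm_rbf = "radial", svm_sigmoid = "sigmoid")[[spec$family]]
      e1071::svm(as.matrix(xs), y, kernel = kernel, cost = spec$C,
                 gamma = 1 / p, degree = spec$degree, scale = FALSE)
    },
    naive_bayes = e1071::naiveBayes(xs, y),
    naive_bayes_kernel = fit_nb_kernel(xs, y),
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = cbind(y = y, xs), family = stats::binomial())),
    mlp = {
      size <- max(1, round((p + 2) / 2))
      nnet::nnet(y ~ ., data = cbind(y = y, xs), size = size,
                 decay = spec$settings$mlp_decay, maxit = spec$settings$mlp_maxit,
                 MaxNWts = 50000, trace = FALSE)
    },
    tree_c45 = rpart::rpart(y ~ ., data = cbind(y = y, xs), method = "class",
                            control = rpart::rpart.control(
                              minsplit = spec$settings$tree_minsplit,
                              cp = spec$settings$tree_cp)),
    bayes_net = fit_discrete_bayes(xs, y, laplace = spec$settings$nb_laplace)
  )
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 features = names(x)), class = "doa_model")
}

# kernel-density naive Bayes: per class and feature a Gaussian-kernel density
fit_nb_kernel <- function(xs, y) {
  classes <- levels(y)
  dens <- lapply(classes, function(cl) lapply(xs, function(col) {
    v <- col[y == cl]
    if (length(unique(v)) < 2)
      list(constant = TRUE, value = v[1])
    else {
      d <- stats::density(v, n = 512, cut = 3)
      list(constant = FALSE, x = d$x, y = d$y)
    }
  }))
  names(dens) <- classes
  list(type = "nb_kernel", dens = dens,
       prior = table(y) / length(y))
}

predict_nb_kernel <- function(fit, xs) {
  classes <- names(fit$dens)
  logp <- sapply(classes, function(cl) {
    ll <- log(fit$prior[[cl]])
    for (j in seq_along(xs)) {
      d <- fit$dens[[cl]][[j]]
      v <- xs[[j]]
      li <- if (d$constant) {
        ifelse(abs(v - d$value) < 1e-8, 1, 1e-9)
      } else {
        yi <- stats::approx(d$x, d$y, xout = v, yleft = 0, yright = 0)$y
        pmax(yi, 1e-9)
      }
      ll <- ll + log(li)
    }
    ll
  })
  logp <- matrix(logp, ncol = length(classes))
  m <- apply(logp, 1, max)
  pr <- exp(logp - m)
  pr[, 2] / rowSums(pr)            # P(second level) = P(unconscious)
}

# discrete Bayes net, class-parent structure: each feature binarized at its
# information-gain threshold, Laplace-smoothed CPTs
fit_discrete_bayes <- function(xs, y, laplace = 1) {
  thr <- vapply(xs, function(col)
    suppressWarnings(information_gain(col, y)$threshold), numeric(1))
  thr[is.na(thr)] <- 0
  cpt <- lapply(seq_along(xs), function(j) {
    b <- xs[[j]] > thr[j]
    t(vapply(levels(y), function(cl) {
      k <- sum(b & y == cl)
      n <- sum(y == cl)
      (c(n - k, k) + laplace) / (n + 2 * laplace)
    }, numeric(2)))
  })
  list(type = "discrete_bayes", thr = thr, cpt = cpt,
       prior = (table(y) + laplace) / (length(y) + 2 * laplace))
}

predict_discrete_bayes <- function(fit, xs) {
  classes <- names(fit$prior)
  logp <- sapply(seq_along(classes), function(ci) {
    ll <- rep(log(fit$prior[[ci]]), nrow(xs))
    for (j in seq_along(xs)) {
      b <- as.integer(xs[[j]] > fit$thr[j]) + 1L
      ll <- ll + log(fit$cpt[[j]][ci, b])
    }
    ll
  })
  logp <- matrix(logp, ncol = length(classes))
  m <- apply(logp, 1, max)
  pr <- exp(logp - m)
  pr[, 2] / rowSums(pr)
}

#' Score new rows with a trained model
#'
#' Returns a continuous indicator per row — the SVM decision value or the
#' model's class-1 probability, oriented so that higher means "more
#' unconscious" — plus the hard label. The graded indicator (not the hard
#' label) is what the prediction-probability statistic consumes.
#'
#' @param model a [train_classifier()] handle.
#' @param rows data frame with exactly the training feature columns.
#' @return data frame with columns `indicator` and `label`.
#' @export
score_classifier <- function(model, rows) {
  stopifnot(inherits(model, "doa_model"))
  rows <- as.data.frame(rows)
  if (!identical(sort(names(rows)), sort(model$features)))
    stop("feature columns do not match the training columns")
  rows <- rows[, model$features, drop = FALSE]
  xs <- as.data.frame(scale(rows, center = model$center, scale = model$scale))
  spec <- model$spec
  ind <- switch(spec$family,
    svm_linear = ,
    svm_poly = ,
    svm_rbf = ,
    svm_sigmoid = {
      pr <- stats::predict(model$fit, as.matrix(xs), decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # libSVM's decision value is positive for the class named first in the
      # column label; orient so higher = unconscious
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (first == "unconscious") as.numeric(dv) else -as.numeric(dv)
    },
    naive_bayes = {
      pr <- stats::predict(model$fit, xs, type = "raw")
      as.numeric(pr[, "unconscious"])
    },
    naive_bayes_kernel = predict_nb_kernel(model$fit, xs),
    logistic = as.numeric(stats::predict(model$fit, newdata = xs,
                                         type = "response")),
    mlp = as.numeric(stats::predict(model$fit, newdata = xs, type = "raw")),
    tree_c45 = as.numeric(stats::predict(model$fit, newdata = xs)[, "unconscious"]),
    bayes_net = predict_discrete_bayes(model$fit, xs)
  )
  if (any(!is.finite(ind))) stop("non-finite indicator produced")
  thr <- if (spec$family %in% .svm_families) 0 else 0.5
  data.frame(indicator = ind,
             label = ifelse(ind >= thr, "unconscious", "conscious"),
             stringsAsFactors = FALSE)
}

#' Pick the best SVM cost over the canonical grid
#'
#' Runs the full C grid under a caller-supplied evaluation protocol and
#' returns the maximizing spec and result; exact ties go to the lowest C.
#'
#' @param family an SVM family name.
#' @param evaluate function(spec) returning an object with a `pk_mean`
#'   element (e.g. a [patientwise_pk()] summary from a cross-validation run).
#' @param grid cost grid, default {0.01, 0.1, 1, 10, 100}.
#' @param ... passed to [classifier_spec()].
#' @return list with `spec` and `result`.
#' @export
best_over_C <- function(family, evaluate, grid = .c_grid, ...) {
  if (!(family %in% .svm_families))
    stop("best_over_C applies to SVM families only")
  if (length(grid) == 0) stop("empty C grid")
  best <- NULL
  for (C in sort(grid)) {
    spec <- classifier_spec(family, C = C, ...)
    res <- evaluate(spec)
    if (is.null(best) || res$pk_mean > best$result$pk_mean)
      best <- list(spec = spec, result = res)
  }
  best
}
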