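sep_toy <- function(n = 12, seed = 1, gap = 6) {
  set.seed(seed)
  lab <- rep(c("conscious", "unconscious"), each = n / 2)
  x <- data.frame(f1 = rnorm(n) + ifelse(lab == "unconscious", gap, 0),
                  f2 = rnorm(n) - ifelse(lab == "unconscious", gap, 0))
  list(x = x, lab = lab)
}

test_that("every classifier family separates an easy toy set with correctly oriented indicators", {
  toy <- sep_toy(n = 16, seed = 2)
  for (fam in c("svm_linear", "svm_poly", "svm_rbf", "svm_sigmoid",
                "naive_bayes", "naive_bayes_kernel", "logistic", "mlp",
                "tree_c45", "bayes_net")) {
    spec <- classifier_spec(fam, C = 1)
    model <- train_classifier(spec, toy$x, toy$lab)
    sc <- score_classifier(model, toy$x)
    # indicator higher for unconscious rows; hard labels perfect
    expect_gt(min(sc$indicator[toy$lab == "unconscious"]),
              max(sc$indicator[toy$lab == "conscious"]))
    expect_identical(sc$label, toy$lab)
  }
})

test_that("naive Bayes posterior matches the closed-form Gaussian Bayes rule", {
  x <- data.frame(f = c(0, 1, 2, 10, 11, 12))
  lab <- rep(c("conscious", "unconscious"), each = 3)
  model <- train_classifier(classifier_spec("naive_bayes"), x, lab)
  probe <- data.frame(f = 4)
  got <- score_classifier(model, probe)$indicator
  # hand computation in the standardized space the model uses
  mu <- mean(x$f); s <- sd(x$f)
  z <- (c(0, 1, 2, 10, 11, 12) - mu) / s
  zp <- (4 - mu) / s
  lik_c <- dnorm(zp, mean(z[1:3]), sd(z[1:3]))
  lik_u <- dnorm(zp, mean(z[4:6]), sd(z[4:6]))
  expect_equal(got, lik_u / (lik_u + lik_c), tolerance = 1e-6)
})

test_that("spec validation enforces the canonical C grid and gamma rule", {
  expect_error(classifier_spec("svm_rbf", C = 3, grid_mode = TRUE), "grid")
  expect_silent(classifier_spec("svm_rbf", C = 10, grid_mode = TRUE))
  expect_silent(classifier_spec("logistic", C = 3, grid_mode = TRUE))
  expect_error(classifier_spec("svm_rbf", C = -1), "positive")
  expect_error(classifier_spec("svm_rbf", gamma_rule = "fixed"), "gamma")
  expect_error(classifier_spec("boosting"), "arg")
})

test_that("scoring is stable for duplicated rows and strict about columns", {
  toy <- sep_toy(seed = 3)
  model <- train_classifier(classifier_spec("svm_linear"), toy$x, toy$lab)
  two <- toy$x[c(1, 1), ]
  sc <- score_classifier(model, two)
  expect_identical(sc$indicator[1], sc$indicator[2])
  expect_error(score_classifier(model, toy$x[, "f1", drop = FALSE]), "columns")
  expect_error(train_classifier(classifier_spec("logistic"), toy$x,
                                rep("conscious", 12)), "single-class")
})

test_that("MLP training is deterministic under the spec seed", {
  toy <- sep_toy(n = 20, seed = 4, gap = 2)
  m1 <- train_classifier(classifier_spec("mlp", seed = 9), toy$x, toy$lab)
  m2 <- train_classifier(classifier_spec("mlp", seed = 9), toy$x, toy$lab)
  expect_identical(score_classifier(m1, toy$x)$indicator,
                   score_classifier(m2, toy$x)$indicator)
})

test_that("best_over_C maximizes the evaluation and breaks ties toward low C", {
  # evaluation that rewards a specific C
  ev <- function(spec) list(pk_mean = c(`0.01` = 0.6, `0.1` = 0.9, `1` = 0.7,
                                        `10` = 0.9, `100` = 0.5)[[as.character(spec$C)]])
  best <- best_over_C("svm_rbf", ev)
  expect_equal(best$spec$C, 0.1)          # tie between 0.1 and 10 -> lowest C
  expect_equal(best$result$pk_mean, 0.9)
  # degenerate all-tie grid: lowest C wins
  best0 <- best_over_C("svm_linear", function(spec) list(pk_mean = 0.5))
  expect_equal(best0$spec$C, 0.01)
  expect_error(best_over_C("logistic", ev), "SVM")
  expect_error(best_over_C("svm_rbf", ev, grid = numeric(0)), "empty")
  # on data, the returned P_K dominates every grid member
  tab <- toy_feature_table(n_patients = 5, seed = 6, effect = 1)
  ev2 <- function(spec)
    patientwise_pk(leave_one_patient_out(tab, spec, n_features = 5))
  best2 <- best_over_C("svm_rbf", ev2)
  for (C in c(0.01, 0.1, 1, 10, 100)) {
    r <- ev2(classifier_spec("svm_rbf", C = C))
    expect_gte(best2$result$pk_mean, r$pk_mean - 1e-12)
  }
})
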