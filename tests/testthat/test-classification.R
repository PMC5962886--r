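make_toy_table <- function(n_per_class = 8, gap = 4, n_noise = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("control", "patient"), each = n_per_class)
  X <- cbind(sig1 = ifelse(labels == "patient", gap, 0) + rnorm(n, sd = 0.5),
             sig2 = ifelse(labels == "patient", -gap, 0) + rnorm(n, sd = 0.5),
             matrix(rnorm(n * n_noise), n, n_noise))
  feature_table(X, labels)
}

# small cost/gamma grids suited to a handful of standardized features;
# gammas stay low so held-out points keep nonvanishing kernel similarity
tiny_config <- function(seed = 1)
  classifier_config(c_grid = 2^c(0, 2, 4), g_grid = 2^c(-6, -4, -2),
                    inner_folds = 3, seed = seed)

test_that("feature standardization uses training statistics only", {
  train <- feature_table(cbind(f = c(1, 2, 3)), rep(c("control", "patient"),
                                                    length.out = 3))
  test <- feature_table(cbind(f = 2), "patient")
  std <- standardize_features(train, test)
  expect_equal(unname(drop(std$train$values)), c(-1, 0, 1))
  expect_equal(unname(drop(std$test$values)), 0)
  # test rows standardized with their own statistics would differ
  expect_false(isTRUE(all.equal(drop(std$test$values),
                                drop(scale(test$values)))))
  # constant training feature maps to zero, never NaN
  tr2 <- feature_table(cbind(f = c(2, 2, 2), g = c(1, 2, 3)),
                       rep(c("control", "patient"), length.out = 3))
  te2 <- feature_table(cbind(f = 5, g = 9), "control")
  std2 <- standardize_features(tr2, te2)
  expect_equal(unname(std2$train$values[, "f"]), c(0, 0, 0))
  expect_equal(unname(std2$test$values[1, "f"]), 0)
  expect_false(anyNA(std2$test$values))
})

test_that("grid search evaluates the full grid and breaks ties deterministically", {
  tab <- make_toy_table()
  cfg <- classifier_config(c_grid = 2^(-8:8), g_grid = 2^(-8:8))
  expect_identical(length(cfg$c_grid) * length(cfg$g_grid), 289L)
  # single grid point comes straight back
  one <- grid_search_cv(tab, classifier_config(c_grid = 2, g_grid = 0.5,
                                               inner_folds = 3, seed = 2))
  expect_equal(one$c, 2)
  expect_equal(one$g, 0.5)
  # separable toy: the chosen pair reaches perfect inner CV accuracy
  pick <- grid_search_cv(tab, tiny_config(seed = 3))
  expect_equal(pick$cv_accuracy, 1)
  # determinism
  pick2 <- grid_search_cv(tab, tiny_config(seed = 3))
  expect_identical(pick, pick2)
  expect_error(grid_search_cv(feature_table(cbind(1:4), rep("control", 4)),
                              tiny_config()),
               class = "hn_schema_error")
})

test_that("LOOCV separates a separable cohort and runs on a minimal one", {
  tab <- make_toy_table()
  ev <- loocv_evaluate(tab, tiny_config(seed = 4))
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$bac, 100)
  expect_identical(ev$tp + ev$tn + ev$fp + ev$fn, nrow(tab$values))
  # minimal 2 + 2 cohort: runs and reports 4 predictions
  mini <- feature_table(cbind(f = c(0, 0.1, 1, 1.1), g = c(1, 0.9, 0, 0.2)),
                        rep(c("control", "patient"), each = 2))
  evm <- loocv_evaluate(mini, tiny_config(seed = 5))
  expect_length(evm$predictions, 4L)
  expect_error(loocv_evaluate(feature_table(cbind(1:3), c("control", "control",
                                                          "patient")),
                              tiny_config()),
               class = "hn_schema_error")
})

test_that("a label-leaking canary feature is detected by perfect accuracy", {
  set.seed(60)
  n <- 16
  labels <- rep(c("control", "patient"), each = n / 2)
  noise <- matrix(rnorm(n * 3), n, 3)
  canary <- ifelse(labels == "patient", 1, 0)
  with_canary <- feature_table(cbind(canary, noise), labels)
  ev <- loocv_evaluate(with_canary, tiny_config(seed = 6))
  expect_equal(ev$accuracy, 100)
  # removing the canary drops accuracy to noise level
  ev0 <- loocv_evaluate(feature_table(noise, labels), tiny_config(seed = 6))
  expect_lt(ev0$accuracy, 100)
})

test_that("evaluation is deterministic given the seed", {
  tab <- make_toy_table(gap = 1.2, n_noise = 3, seed = 2)
  a <- loocv_evaluate(tab, tiny_config(seed = 7))
  b <- loocv_evaluate(tab, tiny_config(seed = 7))
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$accuracy, b$accuracy)
})

test_that("balanced accuracy is the symmetric mean of sensitivity and specificity", {
  expect_equal(compute_bac(84.21, 82.14), 83.175)
  expect_equal(compute_bac(100, 100), 100)
  expect_equal(compute_bac(92.10, 81.57), 86.835)
  expect_equal(compute_bac(30, 70), compute_bac(70, 30))
  expect_error(compute_bac(-1, 50), class = "hn_config_error")
  expect_error(compute_bac(50, 101), class = "hn_config_error")
})
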