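test_that("cohort write/read round-trips values through text exactly", {
  set.seed(1)
  subjects <- lapply(1:3, function(i) {
    roi_ts(matrix(rnorm(10 * 4), 10, 4), subject_id = sprintf("s%d", i),
           roi_labels = paste0("R", 1:4))
  })
  coh <- cohort(subjects, c("control", "patient", "control"))
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  back <- read_cohort(man)
  expect_length(back$subjects, 3L)
  expect_identical(back$labels, coh$labels)
  for (i in 1:3) {
    expect_equal(back$subjects[[i]]$data, coh$subjects[[i]]$data,
                 tolerance = 1e-12)
    expect_identical(back$subjects[[i]]$roi_labels, paste0("R", 1:4))
  }
})

test_that("manifest and table errors are specific", {
  dir <- withr::local_tempdir()
  # missing file
  writeLines("subject_id\tgroup\ttimeseries_path\ns1\tcontrol\tnope.tsv",
             file.path(dir, "manifest.tsv"))
  expect_error(read_cohort(file.path(dir, "manifest.tsv")), "nope.tsv",
               class = "hn_input_error")
  # inconsistent region count across subjects
  set.seed(2)
  s1 <- roi_ts(matrix(rnorm(40), 10, 4))
  s2 <- roi_ts(matrix(rnorm(50), 10, 5))
  expect_error(cohort(list(s1, s2), c("control", "patient")),
               class = "hn_schema_error")
  # non-numeric cell names its coordinates
  writeLines(c("A\tB", "1\t2", "x\t4"), file.path(dir, "bad.tsv"))
  err <- tryCatch(hypernet:::read_numeric_table(file.path(dir, "bad.tsv")),
                  error = identity)
  expect_s3_class(err, "hn_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "column 'A'")
  # refuse empty cohort
  expect_error(write_cohort(structure(list(subjects = list()), class = "cohort"),
                            dir),
               class = "hn_schema_error")
})

test_that("nuisance residualization is an orthogonal projection", {
  set.seed(3)
  ts <- roi_ts(matrix(rnorm(50 * 5), 50, 5))
  nuis <- nuisance_regressors(matrix(rnorm(50 * 6), 50, 6))
  res <- residualize_nuisance(ts, nuis)
  # residuals orthogonal to every nuisance column, and zero-mean
  expect_lt(max(abs(crossprod(res$data, nuis$data))), 1e-10)
  expect_lt(max(abs(colMeans(res$data))), 1e-10)
  # projection idempotence
  twice <- residualize_nuisance(res, nuis)
  expect_equal(twice$data, res$data, tolerance = 1e-10)
  # intercept-only (q = 0) demeans
  demean <- residualize_nuisance(ts, nuisance_regressors(matrix(0, 50, 0)))
  expect_equal(demean$data, sweep(ts$data, 2, colMeans(ts$data)),
               tolerance = 1e-12)
  # a column equal to a nuisance regressor is annihilated
  ts2 <- ts
  ts2$data[, 2] <- nuis$data[, 3]
  expect_lt(max(abs(residualize_nuisance(ts2, nuis)$data[, 2])), 1e-10)
  # rank-deficient design names the collinear column
  dup <- nuisance_regressors(cbind(nuis$data, dup_col = nuis$data[, 1]))
  expect_error(residualize_nuisance(ts, dup), "dup_col",
               class = "hn_numerical_error")
})

test_that("column standardization z-scores and preserves correlations", {
  expect_equal(drop(standardize_columns(cbind(a = c(1, 2, 3), b = c(5, 1, 0)))[, "a"]),
               c(-1, 0, 1))
  set.seed(4)
  mat <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(1, 5, 10, 0.1, 2, 3))
  std <- standardize_columns(mat)
  expect_equal(colMeans(std), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(std, 2, sd), rep(1, 6), tolerance = 1e-12)
  expect_equal(cor(std), cor(mat), tolerance = 1e-12)
  # idempotent
  expect_equal(standardize_columns(std), std, tolerance = 1e-12)
  # constant column refused by name
  mat[, 3] <- 7
  colnames(mat) <- paste0("R", 1:6)
  expect_error(standardize_columns(mat), "R3", class = "hn_numerical_error")
})
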