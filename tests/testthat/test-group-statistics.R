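test_that("KS statistic matches closed forms and stats::ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 0), c(1, 1)), 1)
  expect_equal(ks_statistic(c(1, 2), c(1.5, 2.5)), 0.5)
  expect_error(ks_statistic(numeric(0), 1), class = "hn_schema_error")
  set.seed(50)
  for (rep in 1:20) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b))$statistic))
  }
  # ties are handled like ks.test
  a <- c(1, 1, 2, 2); b <- c(1, 2, 2, 3)
  expect_equal(ks_statistic(a, b),
               unname(suppressWarnings(stats::ks.test(a, b))$statistic))
})

test_that("permutation p-values behave at the extremes and are deterministic", {
  labels <- rep(c("control", "patient"), each = 5)
  expect_equal(permutation_test(rep(1, 10), labels, n_perm = 200, seed = 1), 1)
  expect_error(permutation_test(rnorm(5), rep("control", 5)),
               class = "hn_schema_error")
  # perfect separation at n = 3 + 3: 2 of the 20 label splits reproduce
  # KS = 1, so p concentrates near 0.1
  sep <- c(0, 0, 0, 1, 1, 1)
  p <- permutation_test(sep, rep(c("control", "patient"), each = 3),
                        n_perm = 999, seed = 2)
  expect_gte(p, 1 / 1000)
  expect_lt(p, 0.2)
  p2 <- permutation_test(sep, rep(c("control", "patient"), each = 3),
                         n_perm = 999, seed = 2)
  expect_identical(p, p2)
})

test_that("BH step-up matches the hand calculation and p.adjust", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.04, 0.5), 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(bh_fdr(0.01, 0.05), TRUE)
  expect_error(bh_fdr(c(0, 0.5)), class = "hn_schema_error")
  set.seed(51)
  p <- runif(40)^2
  expect_identical(bh_fdr(p, 0.1), stats::p.adjust(p, "BH") <= 0.1)
})

test_that("select_features flags injected differences and not pure noise", {
  set.seed(52)
  n <- 40
  labels <- rep(c("control", "patient"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[labels == "patient", 1] <- X[labels == "patient", 1] + 3
  tab <- feature_table(X, labels)
  sel <- select_features(tab, n_perm = 300, q = 0.05, seed = 3)
  expect_true(sel$rejected[1])
  expect_lt(sum(sel$rejected[-1]), 3)
  expect_identical(nrow(sel), 10L)
})

test_that("Relief weights match the independent reference and its fixed points", {
  set.seed(53)
  n <- 24
  labels <- rep(c("control", "patient"), each = n / 2)
  X <- cbind(sep = ifelse(labels == "patient", 1, -1) + 0.01 * rnorm(n),
             matrix(rnorm(n * 5), n), const = 0)
  X <- scale(X[, colnames(X) != "const"])
  X <- cbind(X, const = 0)
  tab <- feature_table(X, labels)
  w <- relief_weights(tab, seed = 7)
  # constant feature contributes nothing; separator dominates
  expect_equal(unname(w["const"]), 0)
  expect_identical(names(which.max(w)), "sep")
  # matches the naive reference under the same visiting order
  order_idx <- hypernet:::with_seed(7, sample.int(n, n))
  expect_equal(unname(w), unname(bf_relief(X, labels, order_idx)))
  expect_error(relief_weights(feature_table(X[1:13, ], labels[1:13])),
               class = "hn_schema_error")
})

test_that("pure-noise Relief weights are centred at zero", {
  set.seed(54)
  means <- replicate(50, {
    n <- 20
    labels <- rep(c("control", "patient"), each = n / 2)
    tab <- feature_table(matrix(rnorm(n * 4), n, 4), labels)
    mean(relief_weights(tab, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("average hyper-edge follows the mean-degree and frequency rules", {
  # identical edges reproduce themselves
  expect_identical(average_hyperedge(list(c(2, 5, 7), c(2, 5, 7))),
                   c(2L, 5L, 7L))
  # d = ceil((2 + 4) / 2) = 3; counts 1:2, 2:2, 3:1, 4:1 -> tie-break low index
  expect_identical(average_hyperedge(list(c(1, 2), c(1, 2, 3, 4))),
                   c(1L, 2L, 3L))
  expect_error(average_hyperedge(list()), class = "hn_schema_error")
  # matches a brute-force tally on random inputs
  set.seed(55)
  for (rep in 1:20) {
    edges <- lapply(1:6, function(i) sort(sample.int(12, sample(2:6, 1))))
    got <- average_hyperedge(edges)
    d <- ceiling(mean(lengths(edges)))
    cnt <- sapply(1:12, function(v) sum(vapply(edges, function(e) v %in% e,
                                               logical(1))))
    expected <- sort(order(-cnt, 1:12)[seq_len(d)])
    expect_identical(got, as.integer(expected))
  }
})

test_that("group_average_hyperedge pulls the right edge from networks", {
  set.seed(56)
  mats <- lapply(1:3, function(i) matrix(rnorm(60 * 5), 60, 5))
  spec <- hyper_spec("lasso", lambda_grid = c(0.3, 0.6))
  nets <- lapply(mats, build_hypernetwork, spec = spec)
  avg <- group_average_hyperedge(nets, centroid = 2, lambda_fraction = 0.6)
  manual <- average_hyperedge(lapply(nets, function(n) n$edges[[4]]))
  expect_identical(avg, manual)
  expect_error(group_average_hyperedge(nets, 2, 0.45),
               class = "hn_config_error")
})
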