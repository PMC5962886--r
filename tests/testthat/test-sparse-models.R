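test_that("lambda_max closed forms hold", {
  p <- regression_problem(c(2, 0), cbind(c(1, 0), 0), 2)
  expect_equal(compute_lambda_max(p, "lasso"), 2)

  # response orthogonal to every column -> 0, any penalty fully sparse
  po <- regression_problem(c(0, 0, 1), cbind(c(1, 0, 0), c(0, 1, 0), 0), 3)
  expect_equal(compute_lambda_max(po, "lasso"), 0)
  expect_identical(solve_lasso(po, 0.5)$support, integer(0))

  # single group holding all columns: ||A'x||_2 with A'x = (3, 4) -> 5
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(15), 5, 3)))
  x <- Q %*% c(3, 4, 0)
  pg <- regression_problem(drop(x), cbind(Q[, 1:2], 0), 3)
  expect_equal(compute_lambda_max(pg, "group_lasso",
                                  group_structure(c(1, 1, 2))), 5)
})

test_that("solvers reproduce closed forms on orthonormal designs", {
  # lasso: soft threshold. a'x = 2, lambda = 0.5 * 2 -> coef 1
  p <- regression_problem(c(2, 0), cbind(c(1, 0), 0), 2)
  expect_equal(unname(solve_lasso(p, 0.5)$coefficients), c(1, 0),
               tolerance = 1e-8)
  # fraction 1 -> empty model
  expect_identical(solve_lasso(p, 1)$support, integer(0))

  # elastic net: ridge-shrunk soft threshold (2 - 1) / (1 + 2 * 0.5) = 0.5
  expect_equal(unname(solve_elastic_net(p, 0.5, 0.5)$coefficients), c(0.5, 0),
               tolerance = 1e-8)
  # lambda2 = 0 reduces exactly to the lasso
  set.seed(2)
  pr <- random_problem(30, 8)
  l <- solve_lasso(pr, 0.3)
  e <- solve_elastic_net(pr, 0.3, 0)
  expect_equal(e$coefficients, l$coefficients, tolerance = 1e-8)

  # group lasso: block soft threshold (1 - beta/||z||) z
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(20), 5, 4)))
  x <- Q %*% c(3, 4, 0, 0)
  pg <- regression_problem(drop(x), cbind(Q, 0), 5)
  gs <- group_structure(c(1, 1, 1, 1, 2))
  sg <- solve_group_lasso(pg, 2 / 5, gs)
  expect_equal(unname(sg$coefficients), c((1 - 2 / 5) * c(3, 4, 0, 0), 0),
               tolerance = 1e-8)
  expect_identical(solve_group_lasso(pg, 1, gs)$support, integer(0))
  # group orthogonal to the response stays entirely zero
  x2 <- Q %*% c(3, 4, 0, 0)
  pg2 <- regression_problem(drop(x2), cbind(Q, 0), 5)
  gs2 <- group_structure(c(1, 1, 2, 2, 3))
  expect_identical(intersect(solve_group_lasso(pg2, 0.3, gs2)$support, c(3L, 4L)),
                   integer(0))
})

test_that("solvers match exhaustive brute-force oracles on small problems", {
  set.seed(10)
  for (rep in 1:4) {
    pr <- random_problem(30, 8, centroid = sample(8, 1))
    lmax <- compute_lambda_max(pr, "lasso")
    for (f in c(0.2, 0.5, 0.8)) {
      sol <- solve_lasso(pr, f)
      expect_lt(sol$kkt_residual, 1e-6 * lmax + 1e-12)
      expect_equal(sol$objective_value, bf_enet_objective(pr, f * lmax, 0),
                   tolerance = 1e-8)
    }
    sol_e <- solve_elastic_net(pr, 0.4, 0.3)
    expect_equal(sol_e$objective_value,
                 bf_enet_objective(pr, 0.4 * lmax, 0.3), tolerance = 1e-8)
  }
})

test_that("group lasso matches group-subset enumeration oracle", {
  set.seed(11)
  for (rep in 1:3) {
    pr <- random_problem(30, 6, centroid = 6)
    gs <- group_structure(c(1, 1, 2, 2, 3, 3))
    lmax <- compute_lambda_max(pr, "group_lasso", gs)
    sol <- solve_group_lasso(pr, 0.4, gs)
    expect_lt(sol$kkt_residual, 1e-6 * lmax + 1e-12)
    oracle <- bf_group_objective(pr, 0.4 * lmax, gs)
    expect_lt(sol$objective_value, oracle + 1e-8)
  }
})

test_that("support size is non-increasing along the 0.1..0.9 fraction grid", {
  set.seed(12)
  for (rep in 1:3) {
    pr <- random_problem(50, 10, centroid = 2)
    sizes <- vapply(seq(0.1, 0.9, by = 0.1),
                    function(f) length(solve_lasso(pr, f)$support), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("grouping effect: elastic net ties duplicated columns, lasso picks one", {
  set.seed(13)
  T <- 100
  z <- rnorm(T)
  mat <- cbind(z, z, rnorm(T), 0.8 * z + 0.6 * rnorm(T))
  mat <- standardize_columns(mat)
  mat[, 2] <- mat[, 1]               # exact duplicates after scaling
  design <- mat; design[, 4] <- 0
  pr <- regression_problem(mat[, 4], design, 4)
  en <- solve_elastic_net(pr, 0.3, 0.2)
  expect_true(all(c(1L, 2L) %in% en$support))
  expect_lt(abs(en$coefficients[1] - en$coefficients[2]), 1e-6)
  la <- solve_lasso(pr, 0.3)
  expect_lte(sum(c(1L, 2L) %in% la$support), 1L)
})

test_that("solutions are invariant to column permutation", {
  set.seed(14)
  pr <- random_problem(40, 7, centroid = 3)
  perm <- sample(7)
  design_p <- pr$design[, perm]
  pr_p <- regression_problem(pr$response, design_p, which(perm == 3))
  for (solver in list(
    function(p) solve_lasso(p, 0.3),
    function(p) solve_elastic_net(p, 0.3, 0.2))) {
    a <- solver(pr)$coefficients
    b <- solver(pr_p)$coefficients
    expect_equal(unname(b), unname(a[perm]), tolerance = 1e-7)
  }
})

test_that("lasso/elastic net agree with glmnet on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  pr <- random_problem(60, 9, centroid = 5)
  n <- length(pr$response)
  lmax <- compute_lambda_max(pr, "lasso")
  for (f in c(0.2, 0.5)) {
    ours <- solve_lasso(pr, f)$coefficients
    g <- glmnet::glmnet(pr$design, pr$response, alpha = 1,
                        lambda = f * lmax / n, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(ours), as.numeric(g$beta), tolerance = 1e-5)
  }
})
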