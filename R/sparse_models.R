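#' Per-region sparse regression problem
#'
#' Represents one centroid region's regression: the region's time series as
#' response, and the full region matrix with the centroid's own column set
#' to zero as design. The zero column keeps coefficient indexing aligned
#' with region indexing and forces the centroid coefficient to zero.
#'
#' @param response numeric vector of length `T` (the centroid's series).
#' @param design numeric `T x R` matrix whose column `centroid_index` is all
#'   zeros.
#' @param centroid_index integer in `1:R`.
#' @return Object of class `regression_problem`.
#' @export
regression_problem <- function(response, design, centroid_index) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  if (length(response) != nrow(design))
    stop_hn("hn_schema_error", "response length != design rows")
  if (nrow(design) < 2L)
    stop_hn("hn_schema_error", "need at least 2 timepoints")
  m <- as.integer(centroid_index)
  if (m < 1L || m > ncol(design))
    stop_hn("hn_schema_error", "centroid index out of range")
  if (any(design[, m] != 0))
    stop_hn("hn_schema_error", "design column %d (centroid) must be all zeros", m)
  if (anyNA(design) || anyNA(response) ||
      any(!is.finite(design)) || any(!is.finite(response)))
    stop_hn("hn_numerical_error", "non-finite data in regression problem")
  structure(list(response = response, design = design, centroid_index = m),
            class = "regression_problem")
}

#' Build the regression problem for one centroid region
#'
#' Standardizes the time-series columns, takes region `m`'s column as the
#' response, and zeroes it in the design.
#'
#' @param ts an [roi_ts()] or numeric matrix.
#' @param m centroid region index.
#' @param standardize z-score the columns first (default `TRUE`).
#' @return A [regression_problem()].
#' @export
roi_regression_problem <- function(ts, m, standardize = TRUE) {
  mat <- ts_matrix(ts)
  if (standardize) mat <- standardize_columns(mat)
  design <- mat
  design[, m] <- 0
  regression_problem(mat[, m], design, m)
}

#' Group structure over regions for the group lasso
#'
#' @param assignment integer vector of length `R`, group ids in `1:k`; every
#'   region belongs to exactly one group.
#' @param k number of groups (default `max(assignment)`).
#' @return Object of class `group_structure` with fields `assignment`, `k`
#'   and `groups` (list of member index vectors).
#' @export
group_structure <- function(assignment, k = max(assignment)) {
  assignment <- as.integer(assignment)
  if (anyNA(assignment) || any(assignment < 1L) || any(assignment > k))
    stop_hn("hn_config_error", "group ids must lie in 1:%d", k)
  structure(list(assignment = assignment, k = as.integer(k),
                 groups = split(seq_along(assignment), assignment)),
            class = "group_structure")
}

as_group_structure <- function(groups) {
  if (inherits(groups, "group_structure")) return(groups)
  if (inherits(groups, "roi_partition"))
    return(group_structure(groups$assignment, groups$k))
  stop_hn("hn_config_error", "groups must be a group_structure or roi_partition")
}

#' Smallest penalty that zeroes the whole model
#'
#' For the lasso and elastic net this is `max_j |a_j' x|`; for the
#' (unweighted) group lasso, `max_i ||A_{G_i}' x||_2`. Penalty fractions in
#' `(0, 1]` are taken relative to this value, so a fraction of 1 always
#' yields the empty model and grids are comparable across regions and
#' subjects.
#'
#' @param problem a [regression_problem()].
#' @param method `"lasso"`, `"elastic_net"` or `"group_lasso"`.
#' @param groups a [group_structure()] (group lasso only).
#' @return Nonnegative scalar; 0 when the response is orthogonal to every
#'   column (any penalty then gives the all-zero solution).
#' @export
compute_lambda_max <- function(problem,
                               method = c("lasso", "elastic_net", "group_lasso"),
                               groups = NULL) {
  method <- match.arg(method)
  cvec <- drop(crossprod(problem$design, problem$response))
  if (method == "group_lasso") {
    gs <- as_group_structure(groups)
    if (length(gs$assignment) != ncol(problem$design))
      stop_hn("hn_config_error", "group assignment length != number of columns")
    max(vapply(gs$groups, function(ix) sqrt(sum(cvec[ix]^2)), numeric(1)))
  } else {
    max(abs(cvec))
  }
}

new_sparse_solution <- function(coef, problem, method, lambda_max, kkt,
                                lambda_fraction = NA_real_, lambda2 = 0,
                                beta_fraction = NA_real_, groups = NULL,
                                support_tol = 1e-8) {
  coef[abs(coef) <= support_tol] <- 0
  resid <- problem$response - drop(problem$design %*% coef)
  obj <- 0.5 * sum(resid^2)
  if (method == "lasso") {
    obj <- obj + lambda_fraction * lambda_max * sum(abs(coef))
  } else if (method == "elastic_net") {
    obj <- obj + lambda_fraction * lambda_max * sum(abs(coef)) +
      lambda2 * sum(coef^2)
  } else {
    gs <- as_group_structure(groups)
    obj <- obj + beta_fraction * lambda_max *
      sum(vapply(gs$groups, function(ix) sqrt(sum(coef[ix]^2)), numeric(1)))
  }
  if (!is.null(colnames(problem$design))) names(coef) <- colnames(problem$design)
  structure(list(
    coefficients = coef,
    support = which(coef != 0),
    method = method,
    lambda_fraction = lambda_fraction,
    lambda2 = lambda2,
    beta_fraction = beta_fraction,
    groups = if (is.null(groups)) NULL else as_group_structure(groups),
    lambda_max = lambda_max,
    kkt_residual = kkt,
    objective_value = obj,
    centroid_index = problem$centroid_index
  ), class = "sparse_solution")
}

#' @export
print.sparse_solution <- function(x, ...) {
  frac <- if (x$method == "group_lasso") x$beta_fraction else x$lambda_fraction
  cat(sprintf("<sparse_solution> %s, penalty fraction %.3g: %d of %d coefficients nonzero\n",
              x$method, frac, length(x$support), length(x$coefficients)))
  invisible(x)
}

# Cyclic coordinate descent for 0.5||x - A a||^2 + lam1 ||a||_1 + lam2 ||a||_2^2
# on precomputed Gram G = A'A and c = A'x. Maintains s = G a. Columns with
# G_jj = 0 (the zeroed centroid) stay at zero. Returns list(coef, kkt).
cd_enet <- function(G, cvec, lam1, lam2, tol, max_iter = 10000L,
                    init = NULL) {
  p <- length(cvec)
  a <- if (is.null(init)) numeric(p) else init
  s <- if (is.null(init)) numeric(p) else drop(G %*% a)
  d <- diag(G)
  active <- which(d > 0)
  for (it in seq_len(max_iter)) {
    for (j in active) {
      rho <- cvec[j] - s[j] + d[j] * a[j]
      new <- sign(rho) * max(abs(rho) - lam1, 0) / (d[j] + 2 * lam2)
      if (new != a[j]) {
        s <- s + G[, j] * (new - a[j])
        a[j] <- new
      }
    }
    grad <- s - cvec + 2 * lam2 * a
    viol <- ifelse(a != 0, abs(grad + lam1 * sign(a)),
                   pmax(abs(grad) - lam1, 0))
    viol[d == 0] <- 0
    if (max(viol) <= tol) return(list(coef = a, kkt = max(viol), iter = it))
  }
  list(coef = a, kkt = max(viol), iter = max_iter)
}

# Solved tighter than the 1e-6 * lambda_max contract so that exact
# structural properties (duplicate-column coefficient ties) hold to ~1e-6
# in the coefficients themselves.
solver_tol <- function(lambda_max) 1e-9 * max(lambda_max, 1e-3)

#' Solve the lasso-penalized regression for one centroid
#'
#' Minimizes `0.5 ||x - A a||_2^2 + lambda ||a||_1` with
#' `lambda = lambda_fraction * lambda_max` by cyclic coordinate descent on
#' the Gram matrix, to a KKT residual below `1e-6 * lambda_max`.
#'
#' @param problem a [regression_problem()].
#' @param lambda_fraction penalty fraction in `(0, 1]`.
#' @param support_tol magnitude below which a coefficient is declared zero.
#' @return A `sparse_solution` (coefficients, support, objective, KKT
#'   residual, penalty metadata).
#' @export
solve_lasso <- function(problem, lambda_fraction, support_tol = 1e-8) {
  check_fraction(lambda_fraction)
  G <- crossprod(problem$design)
  cvec <- drop(crossprod(problem$design, problem$response))
  lmax <- max(abs(cvec))
  if (lmax == 0 || lambda_fraction == 1) {
    return(new_sparse_solution(numeric(length(cvec)), problem, "lasso", lmax,
                               0, lambda_fraction = lambda_fraction,
                               support_tol = support_tol))
  }
  fit <- cd_enet(G, cvec, lambda_fraction * lmax, 0, solver_tol(lmax))
  new_sparse_solution(fit$coef, problem, "lasso", lmax, fit$kkt,
                      lambda_fraction = lambda_fraction,
                      support_tol = support_tol)
}

check_fraction <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop_hn("hn_config_error", "penalty fraction must lie in (0, 1]")
}

#' Solve the elastic-net-penalized regression for one centroid
#'
#' Minimizes `0.5 ||x - A a||_2^2 + lambda1 ||a||_1 + lambda2 ||a||_2^2`.
#' `lambda1 = lambda1_fraction * lambda_max` where `lambda_max` is the lasso
#' value, so `lambda2 = 0` reduces exactly to [solve_lasso()]. The ridge
#' term gives the grouping effect: identical columns receive identical
#' coefficients.
#'
#' @inheritParams solve_lasso
#' @param lambda1_fraction l1 penalty fraction in `(0, 1]`.
#' @param lambda2 nonnegative ridge penalty.
#' @return A `sparse_solution`.
#' @export
solve_elastic_net <- function(problem, lambda1_fraction, lambda2 = 0.2,
                              support_tol = 1e-8) {
  check_fraction(lambda1_fraction)
  if (lambda2 < 0) stop_hn("hn_config_error", "lambda2 must be nonnegative")
  G <- crossprod(problem$design)
  cvec <- drop(crossprod(problem$design, problem$response))
  lmax <- max(abs(cvec))
  if (lmax == 0 || lambda1_fraction == 1) {
    return(new_sparse_solution(numeric(length(cvec)), problem, "elastic_net",
                               lmax, 0, lambda_fraction = lambda1_fraction,
                               lambda2 = lambda2, support_tol = support_tol))
  }
  fit <- cd_enet(G, cvec, lambda1_fraction * lmax, lambda2, solver_tol(lmax))
  new_sparse_solution(fit$coef, problem, "elastic_net", lmax, fit$kkt,
                      lambda_fraction = lambda1_fraction, lambda2 = lambda2,
                      support_tol = support_tol)
}

# FISTA for 0.5||x - A a||^2 + beta * sum_g ||a_g||_2 on the Gram matrix.
fista_group <- function(G, cvec, beta, groups, tol, max_iter = 10000L) {
  p <- length(cvec)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  a <- numeric(p); y <- a; t_k <- 1
  prox <- function(v) {
    for (ix in groups) {
      nrm <- sqrt(sum(v[ix]^2))
      v[ix] <- if (nrm <= beta / L) 0 else v[ix] * (1 - beta / (L * nrm))
    }
    v
  }
  kkt_resid <- function(a) {
    grad <- drop(G %*% a) - cvec
    worst <- 0
    for (ix in groups) {
      nrm <- sqrt(sum(a[ix]^2))
      v <- if (nrm > 0) sqrt(sum((grad[ix] + beta * a[ix] / nrm)^2))
           else max(sqrt(sum(grad[ix]^2)) - beta, 0)
      worst <- max(worst, v)
    }
    worst
  }
  for (it in seq_len(max_iter)) {
    a_new <- prox(y - (drop(G %*% y) - cvec) / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- a_new + ((t_k - 1) / t_new) * (a_new - a)
    a <- a_new; t_k <- t_new
    if (it %% 10L == 0L || it == max_iter) {
      k <- kkt_resid(a)
      if (k <= tol) return(list(coef = a, kkt = k, iter = it))
    }
  }
  list(coef = a, kkt = kkt_resid(a), iter = max_iter)
}

#' Solve the group-lasso-penalized regression for one centroid
#'
#' Minimizes `0.5 ||x - A a||_2^2 + beta * sum_i ||a_{G_i}||_2` with
#' `beta = beta_fraction * lambda_max` (group-wise lambda_max), by FISTA
#' with block soft-thresholding. Group norms are unweighted; set
#' `size_weighted = TRUE` to scale each group's penalty by `sqrt(|G_i|)`.
#' A selected group enters with (generically) all its coefficients nonzero,
#' which is the group-level grouping effect.
#'
#' @inheritParams solve_lasso
#' @param beta_fraction penalty fraction in `(0, 1]`.
#' @param groups a [group_structure()] or [kmedoids()] partition.
#' @param size_weighted weight group norms by `sqrt(|G_i|)`.
#' @return A `sparse_solution`.
#' @export
solve_group_lasso <- function(problem, beta_fraction, groups,
                              size_weighted = FALSE, support_tol = 1e-8) {
  check_fraction(beta_fraction)
  gs <- as_group_structure(groups)
  if (length(gs$assignment) != ncol(problem$design))
    stop_hn("hn_config_error", "group assignment length != number of columns")
  G <- crossprod(problem$design)
  cvec <- drop(crossprod(problem$design, problem$response))
  glist <- gs$groups
  if (size_weighted) {
    # scale columns so weighted norms reduce to unweighted on scaled problem
    w <- sqrt(lengths(glist))
    lmax <- max(mapply(function(ix, wi) sqrt(sum(cvec[ix]^2)) / wi, glist, w))
  } else {
    lmax <- max(vapply(glist, function(ix) sqrt(sum(cvec[ix]^2)), numeric(1)))
  }
  if (lmax == 0 || beta_fraction == 1) {
    return(new_sparse_solution(numeric(length(cvec)), problem, "group_lasso",
                               lmax, 0, beta_fraction = beta_fraction,
                               groups = gs, support_tol = support_tol))
  }
  beta <- beta_fraction * lmax
  if (size_weighted) {
    fit <- fista_group_weighted(G, cvec, beta, glist, sqrt(lengths(glist)),
                                solver_tol(lmax))
  } else {
    fit <- fista_group(G, cvec, beta, glist, solver_tol(lmax))
  }
  new_sparse_solution(fit$coef, problem, "group_lasso", lmax, fit$kkt,
                      beta_fraction = beta_fraction, groups = gs,
                      support_tol = support_tol)
}

fista_group_weighted <- function(G, cvec, beta, groups, w, tol,
                                 max_iter = 10000L) {
  p <- length(cvec)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  a <- numeric(p); y <- a; t_k <- 1
  for (it in seq_len(max_iter)) {
    v <- y - (drop(G %*% y) - cvec) / L
    for (g in seq_along(groups)) {
      ix <- groups[[g]]; thr <- beta * w[g] / L
      nrm <- sqrt(sum(v[ix]^2))
      v[ix] <- if (nrm <= thr) 0 else v[ix] * (1 - thr / nrm)
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- v + ((t_k - 1) / t_new) * (v - a)
    a <- v; t_k <- t_new
    if (it %% 10L == 0L) {
      grad <- drop(G %*% a) - cvec
      worst <- 0
      for (g in seq_along(groups)) {
        ix <- groups[[g]]; bw <- beta * w[g]
        nrm <- sqrt(sum(a[ix]^2))
        vv <- if (nrm > 0) sqrt(sum((grad[ix] + bw * a[ix] / nrm)^2))
              else max(sqrt(sum(grad[ix]^2)) - bw, 0)
        worst <- max(worst, vv)
      }
      if (worst <= tol) return(list(coef = a, kkt = worst, iter = it))
    }
  }
  grad <- drop(G %*% a) - cvec
  worst <- 0
  for (g in seq_along(groups)) {
    ix <- groups[[g]]; bw <- beta * w[g]
    nrm <- sqrt(sum(a[ix]^2))
    vv <- if (nrm > 0) sqrt(sum((grad[ix] + bw * a[ix] / nrm)^2))
          else max(sqrt(sum(grad[ix]^2)) - bw, 0)
    worst <- max(worst, vv)
  }
  list(coef = a, kkt = worst, iter = max_iter)
}
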