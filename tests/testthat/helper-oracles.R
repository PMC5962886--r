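# Shared fixtures and independent brute-force oracles used across tests.
# Oracles are deliberately naive translations of the definitions, kept
# separate from the package's optimized implementations.

# 7-node, 4-edge toy hyper-graph used throughout (e1={1,2}, e2={3,4,6},
# e3={5,6}, e4={5,6,7}).
toy_edges <- function() list(c(1L, 2L), c(3L, 4L, 6L), c(5L, 6L), c(5L, 6L, 7L))
toy_net <- function() hypernetwork(toy_edges(), 7L)

# Random hyper-graph: every node appears in >= 0 edges, edges of size 1..max_size.
random_hypergraph <- function(n_nodes, n_edges, max_size = 4L) {
  edges <- lapply(seq_len(n_edges), function(i) {
    sort(sample.int(n_nodes, sample(seq_len(min(max_size, n_nodes)), 1L)))
  })
  hypernetwork(edges, n_nodes)
}

# --- brute-force hyper-graph oracles -----------------------------------------

bf_neighbors <- function(edges, v) {
  out <- integer(0)
  for (e in edges) if (v %in% e) out <- union(out, e)
  sort(setdiff(out, v))
}

bf_adjacency <- function(edges, n_nodes) {
  A <- matrix(0L, n_nodes, n_nodes)
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i == j) next
    A[i, j] <- sum(vapply(edges, function(e) (i %in% e) && (j %in% e), logical(1)))
  }
  A
}

bf_hcc <- function(edges, v) {
  N <- bf_neighbors(edges, v)
  Sv <- Filter(function(e) v %in% e, edges)
  nv <- length(N); sv <- length(Sv)
  h1 <- h2 <- 0
  if (nv > 1L) {
    pairs <- utils::combn(N, 2L)
    i1 <- i2 <- 0L
    for (p in seq_len(ncol(pairs))) {
      u <- pairs[1L, p]; t <- pairs[2L, p]
      if (any(vapply(edges, function(e) u %in% e && t %in% e && !(v %in% e),
                     logical(1)))) i1 <- i1 + 1L
      if (any(vapply(edges, function(e) u %in% e && t %in% e && v %in% e,
                     logical(1)))) i2 <- i2 + 1L
    }
    h1 <- 2 * i1 / (nv * (nv - 1))
    h2 <- 2 * i2 / (nv * (nv - 1))
  }
  h3 <- 0
  if (sv > 1L && nv > 0L) {
    h3 <- (2 * sum(vapply(Sv, length, integer(1)) - 1) - nv) / (nv * (sv - 1))
  }
  c(hcc1 = h1, hcc2 = h2, hcc3 = h3)
}

# --- sparse-solver oracles ---------------------------------------------------

# Exhaustive stationary-point enumeration for
# 0.5||x - A a||^2 + lam1 ||a||_1 + lam2 ||a||_2^2 (lam2 = 0 -> lasso).
# Enumerates supports and sign patterns; returns the minimal objective.
bf_enet_objective <- function(problem, lam1, lam2 = 0) {
  A <- problem$design; x <- problem$response
  G <- crossprod(A); cvec <- drop(crossprod(A, x))
  p <- ncol(A)
  cols <- which(diag(G) > 0)
  obj <- function(a) {
    0.5 * sum((x - A %*% a)^2) + lam1 * sum(abs(a)) + lam2 * sum(a^2)
  }
  best <- obj(numeric(p))
  for (sz in seq_along(cols)) {
    subsets <- utils::combn(cols, sz, simplify = FALSE)
    for (S in subsets) {
      for (bits in 0:(2^sz - 1)) {
        s <- 2 * ((bits %/% 2^(seq_len(sz) - 1)) %% 2) - 1
        M <- G[S, S, drop = FALSE] + diag(2 * lam2, sz)
        a_S <- tryCatch(solve(M, cvec[S] - lam1 * s), error = function(e) NULL)
        if (is.null(a_S) || any(sign(a_S) != s)) next
        a <- numeric(p); a[S] <- a_S
        best <- min(best, obj(a))
      }
    }
  }
  best
}

# Group-subset enumeration with quasi-Newton refinement for
# 0.5||x - A a||^2 + beta * sum_g ||a_g||_2. Returns minimal objective found;
# the solver's KKT residual certifies its own optimality independently.
bf_group_objective <- function(problem, beta, groups) {
  A <- problem$design; x <- problem$response
  glist <- groups$groups
  p <- ncol(A)
  obj_full <- function(a) {
    0.5 * sum((x - A %*% a)^2) +
      beta * sum(vapply(glist, function(ix) sqrt(sum(a[ix]^2)), numeric(1)))
  }
  best <- obj_full(numeric(p))
  ng <- length(glist)
  for (bits in 1:(2^ng - 1)) {
    act <- which(((bits %/% 2^(seq_len(ng) - 1)) %% 2) == 1)
    idx <- unlist(glist[act])
    idx <- idx[apply(A[, idx, drop = FALSE], 2L, function(cl) any(cl != 0))]
    if (length(idx) == 0L) next
    fn <- function(av) {
      a <- numeric(p); a[idx] <- av
      obj_full(a)
    }
    for (start in 1:3) {
      a0 <- stats::rnorm(length(idx), sd = 0.1 * start)
      fit <- stats::optim(a0, fn, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, fit$value)
    }
  }
  best
}

# Random standardized regression problem with the centroid column zeroed.
random_problem <- function(T = 30L, R = 6L, centroid = 1L) {
  mat <- matrix(stats::rnorm(T * R), T, R)
  mat <- standardize_columns(mat)
  design <- mat; design[, centroid] <- 0
  regression_problem(mat[, centroid], design, centroid)
}

# --- Relief reference --------------------------------------------------------

# Naive Relief computing distances on the fly, order fixed by `order_idx`.
bf_relief <- function(X, y, order_idx) {
  w <- numeric(ncol(X))
  for (i in order_idx) {
    d <- sqrt(rowSums(sweep(X, 2L, X[i, ])^2))
    same <- which(y == y[i] & seq_along(y) != i)
    other <- which(y != y[i])
    hit <- same[which.min(d[same])]
    miss <- other[which.min(d[other])]
    w <- w + (abs(X[i, ] - X[miss, ]) - abs(X[i, ] - X[hit, ])) / length(order_idx)
  }
  w
}

# Small two-block cohort used by several pipeline-level tests.
small_effect_config <- function(effect_size = 1.5, seed = 42L,
                                n_per_group = 20L) {
  sim_config(n_control = n_per_group, n_patient = n_per_group, n_rois = 20,
             n_timepoints = 150,
             block_partition = split(1:20, rep(1:4, each = 5)),
             affected_rois = 1:3, effect_size = effect_size, seed = seed)
}
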