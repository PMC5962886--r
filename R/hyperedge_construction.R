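#' Specification of a hyper-network construction
#'
#' Bundles the penalty method, the multi-level penalty grid and the
#' method-specific parameters. One hyper-edge is generated per centroid
#' region and grid level; the default 9-level grid on a 90-region subject
#' therefore yields 810 hyper-edges.
#'
#' @param method `"lasso"`, `"elastic_net"` or `"group_lasso"`.
#' @param lambda_grid strictly increasing penalty fractions in `(0, 1]`
#'   (default `seq(0.1, 0.9, by = 0.1)`).
#' @param lambda2 ridge penalty for the elastic net (default 0.2, the value
#'   giving the best classification in the original study design).
#' @param groups a [kmedoids()] partition or [group_structure()]
#'   (group lasso only).
#' @param size_weighted weight group-lasso norms by group size.
#' @return Object of class `hyper_spec`.
#' @export
hyper_spec <- function(method = c("lasso", "elastic_net", "group_lasso"),
                       lambda_grid = seq(0.1, 0.9, by = 0.1),
                       lambda2 = 0.2, groups = NULL, size_weighted = FALSE) {
  method <- match.arg(method)
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0) || any(lambda_grid > 1))
    stop_hn("hn_config_error", "lambda_grid values must lie in (0, 1]")
  if (is.unsorted(lambda_grid, strictly = TRUE))
    stop_hn("hn_config_error", "lambda_grid must be strictly increasing")
  if (method == "group_lasso" && is.null(groups))
    stop_hn("hn_config_error", "group_lasso requires a group structure")
  structure(list(method = method, lambda_grid = lambda_grid,
                 lambda2 = lambda2,
                 groups = if (is.null(groups)) NULL else as_group_structure(groups),
                 size_weighted = isTRUE(size_weighted)),
            class = "hyper_spec")
}

#' Hyper-edges of one centroid region across the penalty grid
#'
#' For each grid level, solves the sparse regression of region `m` on all
#' other regions and forms the hyper-edge from the centroid plus the
#' nonzero-coefficient regions. An empty support yields the retained,
#' flagged singleton `{m}`.
#'
#' @param ts an [roi_ts()] or numeric matrix (standardized internally).
#' @param m centroid region index.
#' @param spec a [hyper_spec()].
#' @return List of `hyper_edge` objects (fields `centroid`, `members`,
#'   `method`, `lambda_fraction`, `lambda2`, `singleton`), one per grid
#'   level in grid order.
#' @export
build_hyperedges_for_roi <- function(ts, m, spec) {
  mat <- standardize_columns(ts_matrix(ts))
  G <- crossprod(mat)
  edges_for_centroid(G, m, spec)
}

# Core per-centroid solver working on the (shared) Gram matrix of the
# standardized subject. Response = column m, design = matrix with column m
# zeroed, so A'A is G with row/col m zeroed and A'x is G[, m] zeroed at m.
edges_for_centroid <- function(G, m, spec) {
  m <- as.integer(m)
  Gm <- G
  Gm[m, ] <- 0; Gm[, m] <- 0
  cvec <- G[, m]; cvec[m] <- 0
  grid <- spec$lambda_grid
  if (spec$method == "group_lasso") {
    glist <- spec$groups$groups
    lmax <- if (spec$size_weighted)
      max(mapply(function(ix, w) sqrt(sum(cvec[ix]^2)) / w,
                 glist, sqrt(lengths(glist))))
    else max(vapply(glist, function(ix) sqrt(sum(cvec[ix]^2)), numeric(1)))
  } else {
    lmax <- max(abs(cvec))
  }
  tol <- solver_tol(lmax)
  supports <- vector("list", length(grid))
  init <- NULL
  for (i in rev(seq_along(grid))) {   # high to low penalty, warm-started
    f <- grid[i]
    if (lmax == 0 || f == 1) {
      coef <- numeric(length(cvec))
    } else if (spec$method == "group_lasso") {
      fit <- if (spec$size_weighted)
        fista_group_weighted(Gm, cvec, f * lmax, glist,
                             sqrt(lengths(glist)), tol)
      else fista_group(Gm, cvec, f * lmax, glist, tol)
      coef <- fit$coef
    } else {
      lam2 <- if (spec$method == "elastic_net") spec$lambda2 else 0
      fit <- cd_enet(Gm, cvec, f * lmax, lam2, tol, init = init)
      coef <- fit$coef
      init <- coef
    }
    supports[[i]] <- which(abs(coef) > 1e-8)
  }
  lapply(seq_along(grid), function(i) {
    members <- sort(unique(c(m, supports[[i]])))
    structure(list(centroid = m, members = members, method = spec$method,
                   lambda_fraction = grid[i],
                   lambda2 = if (spec$method == "elastic_net") spec$lambda2 else NA_real_,
                   singleton = length(members) == 1L),
              class = "hyper_edge")
  })
}

#' Build one subject's hyper-network
#'
#' Generates hyper-edges for every centroid region over the penalty grid
#' (centroid-major, grid-minor order) and assembles them into a
#' [hypernetwork()]. The edge count is always `R * length(lambda_grid)`;
#' duplicate and singleton edges are retained so the incidence-matrix shape
#' is fixed by the grid.
#'
#' @param ts an [roi_ts()] or numeric matrix (standardized internally).
#' @param spec a [hyper_spec()].
#' @return A [hypernetwork()] whose `meta` records the method, grid, and
#'   per-edge centroids, penalty fractions and singleton flags.
#' @export
build_hypernetwork <- function(ts, spec) {
  mat <- standardize_columns(ts_matrix(ts))
  R <- ncol(mat)
  G <- crossprod(mat)
  all_edges <- vector("list", R * length(spec$lambda_grid))
  centroids <- integer(length(all_edges))
  fractions <- numeric(length(all_edges))
  singleton <- logical(length(all_edges))
  pos <- 0L
  for (m in seq_len(R)) {
    es <- edges_for_centroid(G, m, spec)
    for (e in es) {
      pos <- pos + 1L
      all_edges[[pos]] <- e$members
      centroids[pos] <- m
      fractions[pos] <- e$lambda_fraction
      singleton[pos] <- e$singleton
    }
  }
  hypernetwork(all_edges, R, meta = list(
    method = spec$method, lambda_grid = spec$lambda_grid,
    lambda2 = if (spec$method == "elastic_net") spec$lambda2 else NA_real_,
    centroids = centroids, fractions = fractions, singleton = singleton,
    roi_labels = colnames(mat)))
}
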