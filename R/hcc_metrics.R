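#' Hyper-graph neighborhood of a node
#'
#' `N(v)`: all nodes other than `v` that share at least one hyper-edge with
#' `v`.
#'
#' @param net a [hypernetwork()].
#' @param v node index.
#' @return Sorted integer vector of neighbor indices.
#' @export
hyper_neighbors <- function(net, v) {
  co <- rowSums(net$incidence[, net$incidence[v, ] == 1L, drop = FALSE])
  setdiff(which(co > 0), v)
}

#' Star of a node: hyper-edges containing it
#'
#' `S(v)`: the set of hyper-edges of which `v` is a member.
#'
#' @param net a [hypernetwork()].
#' @param v node index.
#' @return Integer vector of edge indices.
#' @export
hyper_star <- function(net, v) {
  which(net$incidence[v, ] == 1L)
}

# Shared per-node machinery: co-membership counts overall (C) and within
# the star of v (Tv). For u, t in N(v):
#   some edge holds u,t but not v  <=>  C[u,t] - Tv[u,t] > 0
#   some edge holds u,t and v      <=>  Tv[u,t] > 0
hcc_node <- function(net, v, C = NULL) {
  H <- net$incidence
  if (is.null(C)) C <- tcrossprod(H)
  Sv <- which(H[v, ] == 1L)
  Tv <- tcrossprod(H[, Sv, drop = FALSE])
  N <- setdiff(which(C[v, ] > 0), v)
  nv <- length(N); sv <- length(Sv)
  out <- list(hcc1 = 0, hcc2 = 0, hcc3 = 0,
              deg1 = nv <= 1L, deg2 = nv <= 1L,
              deg3 = sv <= 1L || nv == 0L)
  if (nv > 1L) {
    Cn <- C[N, N, drop = FALSE]; Tn <- Tv[N, N, drop = FALSE]
    denom <- nv * (nv - 1)          # ordered pairs; matches the 2x unordered sum
    off <- upper.tri(Cn)
    out$hcc1 <- 2 * sum((Cn - Tn)[off] > 0) / denom
    out$hcc2 <- 2 * sum(Tn[off] > 0) / denom
  }
  if (!out$deg3) {
    sizes <- net$edge_degrees[Sv]
    out$hcc3 <- (2 * sum(sizes - 1) - nv) / (nv * (sv - 1))
  }
  out
}

#' First hyper-graph clustering coefficient
#'
#' Fraction of neighbor pairs of `v` that co-occur in at least one
#' hyper-edge *not* containing `v` (connections not facilitated by `v`).
#' Degenerate nodes (`|N(v)| <= 1`) return 0.
#'
#' @param net a [hypernetwork()].
#' @param v node index.
#' @return Value in `[0, 1]`.
#' @export
hcc1 <- function(net, v) hcc_node(net, v)$hcc1

#' Second hyper-graph clustering coefficient
#'
#' Fraction of neighbor pairs of `v` that co-occur in at least one
#' hyper-edge *containing* `v` (connections facilitated by `v`). Degenerate
#' nodes (`|N(v)| <= 1`) return 0.
#'
#' @inheritParams hcc1
#' @return Value in `[0, 1]`.
#' @export
hcc2 <- function(net, v) hcc_node(net, v)$hcc2

#' Third hyper-graph clustering coefficient
#'
#' Overlap among the hyper-edges of `v`:
#' `(2 * sum_{e in S(v)} (|e| - 1) - |N(v)|) / (|N(v)| * (|S(v)| - 1))`.
#' Degenerate nodes (`|S(v)| <= 1` or `|N(v)| = 0`, e.g. nodes appearing
#' only in singleton hyper-edges) return 0.
#'
#' @inheritParams hcc1
#' @return Nonnegative value (can exceed 1).
#' @export
hcc3 <- function(net, v) hcc_node(net, v)$hcc3

#' All clustering-coefficient features of a hyper-network
#'
#' Computes the three coefficients for every node. For an `R`-region network
#' the flattened feature vector has length `3 * R` (270 features at
#' `R = 90`).
#'
#' @param net a [hypernetwork()].
#' @return Object of class `hcc_vector`: numeric vectors `hcc1`, `hcc2`,
#'   `hcc3` of length `R`, logical `degenerate_flags` (an `R x 3` matrix),
#'   and `features`, the named flattened vector
#'   `(hcc1_1..hcc1_R, hcc2_1.., hcc3_1..)`.
#' @export
hcc_features <- function(net) {
  R <- net$n_nodes
  C <- tcrossprod(net$incidence)
  h1 <- h2 <- h3 <- numeric(R)
  flags <- matrix(FALSE, R, 3L, dimnames = list(NULL, c("hcc1", "hcc2", "hcc3")))
  for (v in seq_len(R)) {
    hv <- hcc_node(net, v, C)
    h1[v] <- hv$hcc1; h2[v] <- hv$hcc2; h3[v] <- hv$hcc3
    flags[v, ] <- c(hv$deg1, hv$deg2, hv$deg3)
  }
  labels <- net$meta$roi_labels
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(R))
  features <- c(h1, h2, h3)
  names(features) <- c(paste0("hcc1_", labels), paste0("hcc2_", labels),
                       paste0("hcc3_", labels))
  structure(list(hcc1 = h1, hcc2 = h2, hcc3 = h3,
                 degenerate_flags = flags, features = features),
            class = "hcc_vector")
}

#' Per-subject average clustering coefficients
#'
#' Arithmetic mean of each coefficient over all nodes. By default
#' degenerate nodes contribute their 0 value; `drop_degenerate = TRUE`
#' averages only over non-degenerate nodes per metric.
#'
#' @param vec an [hcc_features()] result.
#' @param drop_degenerate exclude flagged nodes from each mean.
#' @return Named numeric vector `c(mean_hcc1, mean_hcc2, mean_hcc3)`.
#' @export
average_hcc <- function(vec, drop_degenerate = FALSE) {
  stopifnot(inherits(vec, "hcc_vector"))
  if (length(vec$hcc1) == 0L)
    stop_hn("hn_schema_error", "cannot average over an empty network")
  one <- function(x, flag) {
    if (drop_degenerate) {
      keep <- !flag
      if (!any(keep)) return(NA_real_)
      mean(x[keep])
    } else mean(x)
  }
  c(mean_hcc1 = one(vec$hcc1, vec$degenerate_flags[, 1L]),
    mean_hcc2 = one(vec$hcc2, vec$degenerate_flags[, 2L]),
    mean_hcc3 = one(vec$hcc3, vec$degenerate_flags[, 3L]))
}
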