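#' Pairwise similarity between regions
#'
#' Similarity is the Pearson correlation of two regions' time series. For a
#' cohort, the time series are first averaged across subjects (element-wise,
#' requiring equal length) so that one similarity matrix, and hence one
#' partition, is shared by all subjects. Dissimilarity used downstream is
#' `1 - similarity` (or `1 - |similarity|` with `absolute = TRUE`).
#'
#' @param x an [roi_ts()], [cohort()] or numeric matrix.
#' @return Symmetric `R x R` correlation matrix with unit diagonal.
#' @export
roi_similarity <- function(x) {
  mat <- if (inherits(x, "cohort")) {
    Ts <- vapply(x$subjects, function(s) nrow(s$data), integer(1))
    if (length(unique(Ts)) != 1L)
      stop_hn("hn_schema_error",
              "cohort-level similarity needs equal time-series length across subjects")
    Reduce(`+`, lapply(x$subjects, `[[`, "data")) / length(x$subjects)
  } else ts_matrix(x)
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop_hn("hn_numerical_error", "zero-variance ROI in similarity computation")
  stats::cor(mat)
}

# k-means++-style seeding on a dissimilarity matrix: first medoid uniform,
# later medoids sampled proportional to dissimilarity to the nearest seed.
kpp_seed <- function(D, k) {
  R <- nrow(D)
  medoids <- integer(k)
  medoids[1L] <- sample.int(R, 1L)
  if (k > 1L) for (i in 2:k) {
    dmin <- apply(D[, medoids[seq_len(i - 1L)], drop = FALSE], 1L, min)
    dmin[medoids[seq_len(i - 1L)]] <- 0
    medoids[i] <- if (sum(dmin) > 0) sample.int(R, 1L, prob = dmin)
                  else sample(setdiff(seq_len(R), medoids[seq_len(i - 1L)]), 1L)
  }
  medoids
}

# One run: alternate nearest-medoid assignment and within-cluster medoid
# update until the cost stops decreasing.
kmedoids_once <- function(D, k, max_iter = 100L) {
  medoids <- kpp_seed(D, k)
  cost <- Inf
  assignment <- integer(nrow(D))
  for (it in seq_len(max_iter)) {
    dm <- D[, medoids, drop = FALSE]
    assignment <- max.col(-dm, ties.method = "first")
    for (g in seq_len(k)) {
      members <- which(assignment == g)
      if (length(members) == 0L) { members <- medoids[g]; assignment[members] <- g }
      within <- D[members, members, drop = FALSE]
      medoids[g] <- members[which.min(rowSums(within))]
    }
    new_cost <- sum(D[cbind(seq_len(nrow(D)), medoids[assignment])])
    if (new_cost >= cost - 1e-12) break
    cost <- new_cost
  }
  dm <- D[, medoids, drop = FALSE]
  assignment <- max.col(-dm, ties.method = "first")
  cost <- sum(dm[cbind(seq_len(nrow(D)), assignment)])
  list(assignment = assignment, medoids = medoids, cost = cost)
}

#' k-medoids partition of regions
#'
#' Partitions regions by k-medoids on a similarity matrix, with
#' k-means++-style seeding and multiple restarts; the minimum-cost run is
#' returned. Deterministic given `seed`.
#'
#' @param similarity symmetric similarity matrix (e.g. [roi_similarity()]).
#' @param k number of groups, `1 <= k <= R`.
#' @param seed integer RNG seed covering all restarts.
#' @param n_restarts number of seeded restarts (default 10).
#' @param absolute use `1 - |similarity|` as dissimilarity instead of
#'   `1 - similarity`.
#' @return Object of class `roi_partition` with fields `assignment`
#'   (group ids `1:k`), `medoids`, `cost`, `k`, `seed`.
#' @export
kmedoids <- function(similarity, k, seed = 1, n_restarts = 10,
                     absolute = FALSE) {
  similarity <- as.matrix(similarity)
  R <- nrow(similarity)
  if (k < 1 || k > R)
    stop_hn("hn_config_error", "k must lie in 1:%d, got %s", R, format(k))
  D <- if (absolute) 1 - abs(similarity) else 1 - similarity
  diag(D) <- 0
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- kmedoids_once(D, as.integer(k))
      if (is.null(best) || run$cost < best$cost) best <- run
    }
  })
  # relabel groups in order of first appearance for determinism
  relabel <- match(best$assignment, unique(best$assignment))
  medoids <- best$medoids[unique(best$assignment)]
  structure(list(assignment = relabel, medoids = medoids, cost = best$cost,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  cat(sprintf("<roi_partition> %d regions in %d groups, cost %.4g (seed %d)\n",
              length(x$assignment), x$k, x$cost, x$seed))
  invisible(x)
}

#' Write a partition as a two-column TSV
#'
#' @param partition an [kmedoids()] result.
#' @param roi_labels region labels (defaults to `ROI001...`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, roi_labels = NULL) {
  R <- length(partition$assignment)
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(R))
  utils::write.table(
    data.frame(roi_label = roi_labels, group_id = partition$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
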