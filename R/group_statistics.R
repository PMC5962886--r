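#' Subjects-by-features table with group labels
#'
#' @param values numeric matrix, one row per subject.
#' @param labels `"control"`/`"patient"` per subject.
#' @param feature_names optional column names.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop_hn("hn_schema_error", "feature table contains missing values")
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop_hn("hn_schema_error", "labels length != number of subjects")
  bad <- setdiff(unique(labels), c("control", "patient"))
  if (length(bad))
    stop_hn("hn_schema_error", "unknown group label(s): %s",
            paste(bad, collapse = ", "))
  if (is.null(feature_names))
    feature_names <- sprintf("f%03d", seq_len(ncol(values)))
  colnames(values) <- feature_names
  structure(list(values = values, labels = labels,
                 feature_names = feature_names),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%d control, %d patient)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "control"), sum(x$labels == "patient")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the two empirical distribution functions,
#' computed by a single merge pass (fast enough to sit inside permutation
#' loops). Agrees with `stats::ks.test`.
#'
#' @param a,b nonempty numeric vectors.
#' @return Statistic in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L)
    stop_hn("hn_schema_error", "both samples must be nonempty")
  w <- c(a, b)
  o <- order(w)
  steps <- ifelse(o <= n, 1 / n, -1 / m)
  z <- cumsum(steps)
  ws <- w[o]
  keep <- c(diff(ws) != 0, TRUE)   # evaluate only at distinct values (ties)
  max(abs(z[keep]))
}

#' Permutation p-value for a between-group KS comparison
#'
#' `p = (1 + #{permutations with KS >= observed}) / (1 + n_perm)` under
#' uniformly drawn label permutations; deterministic given `seed`.
#'
#' @param feature numeric vector, one value per subject.
#' @param labels `"control"`/`"patient"` per subject (both present).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_test <- function(feature, labels, n_perm = 10000, seed = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop_hn("hn_schema_error", "permutation test needs two groups")
  is_a <- labels == unique(labels)[1L]
  obs <- ks_statistic(feature[is_a], feature[!is_a])
  n_ge <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pl <- sample(is_a)
      if (ks_statistic(feature[pl], feature[!pl]) >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  (1 + n_ge) / (1 + n_perm)
}

#' Benjamini-Hochberg step-up rejection at level q
#'
#' @param pvals p-values in `(0, 1]`.
#' @param q FDR level in `(0, 1)` (default 0.05).
#' @return Logical rejection vector.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals <= 0) || any(pvals > 1))
    stop_hn("hn_schema_error", "p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1)
    stop_hn("hn_config_error", "q must lie in (0, 1)")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' KS permutation test with BH-FDR over a feature table
#'
#' Runs the between-group KS permutation test on every feature, sharing one
#' set of label permutations across features (all features see the same
#' resampled null), then applies the BH step-up correction.
#'
#' @param table a [feature_table()].
#' @param n_perm permutations (default 10000).
#' @param q FDR level (default 0.05).
#' @param seed RNG seed.
#' @return `data.frame` with columns `feature`, `ks_statistic`, `p_perm`,
#'   `rejected`.
#' @export
select_features <- function(table, n_perm = 10000, q = 0.05, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  labels <- table$labels
  if (min(base::table(factor(labels, c("control", "patient")))) < 2L)
    stop_hn("hn_schema_error", "need at least 2 subjects per group")
  X <- table$values
  is_a <- labels == "control"
  obs <- apply(X, 2L, function(f) ks_statistic(f[is_a], f[!is_a]))
  hits <- with_seed(seed, {
    h <- integer(ncol(X))
    for (i in seq_len(n_perm)) {
      pl <- sample(is_a)
      for (j in seq_len(ncol(X))) {
        if (ks_statistic(X[pl, j], X[!pl, j]) >= obs[j] - 1e-12)
          h[j] <- h[j] + 1L
      }
    }
    h
  })
  p <- (1 + hits) / (1 + n_perm)
  data.frame(feature = table$feature_names, ks_statistic = obs,
             p_perm = p, rejected = bh_fdr(p, q),
             stringsAsFactors = FALSE)
}

#' Relief feature weights for a two-class table
#'
#' Classic binary Relief: each sampled subject moves every feature's weight
#' by the difference between its distance to the nearest miss (closest
#' other-class subject) and to the nearest hit (closest same-class subject),
#' divided by the number of iterations. Distances are Euclidean on the
#' features as given, which are expected to be standardized. By default
#' every subject is used exactly once, in an order drawn from `seed`.
#'
#' @param table a [feature_table()] with standardized features and at least
#'   2 subjects per class.
#' @param n_iterations sampled instances (default: all subjects, without
#'   replacement).
#' @param seed RNG seed.
#' @return Named numeric weight vector, one entry per feature.
#' @export
relief_weights <- function(table, n_iterations = NULL, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  y <- table$labels
  if (min(base::table(factor(y, c("control", "patient")))) < 2L)
    stop_hn("hn_schema_error",
            "Relief needs >= 2 subjects per class (no near-hit otherwise)")
  n <- nrow(X)
  if (is.null(n_iterations)) n_iterations <- n
  D <- as.matrix(stats::dist(X))
  w <- numeric(ncol(X))
  with_seed(seed, {
    order_idx <- if (n_iterations <= n) sample.int(n, n_iterations)
                 else sample.int(n, n_iterations, replace = TRUE)
    for (i in order_idx) {
      same <- which(y == y[i]); same <- same[same != i]
      diff_cl <- which(y != y[i])
      hit <- same[which.min(D[i, same])]
      miss <- diff_cl[which.min(D[i, diff_cl])]
      w <- w + (abs(X[i, ] - X[miss, ]) - abs(X[i, ] - X[hit, ])) / n_iterations
    }
  })
  stats::setNames(w, table$feature_names)
}

#' Average hyper-edge of a group of subjects
#'
#' Summarizes one (centroid, penalty-level) hyper-edge across a group:
#' `d` is the mean edge degree over subjects rounded up; the `d` most
#' frequently occurring member regions (ties broken by lower region index)
#' form the average hyper-edge.
#'
#' @param edges list with one member-index vector per subject (each the
#'   subject's hyper-edge for the same centroid and penalty level).
#' @return Sorted integer vector of the `d` chosen regions.
#' @export
average_hyperedge <- function(edges) {
  if (length(edges) == 0L)
    stop_hn("hn_schema_error", "no subjects supplied")
  d <- ceiling(mean(lengths(edges)))
  counts <- table(unlist(edges))
  ids <- as.integer(names(counts))
  ord <- order(-as.integer(counts), ids)
  sort(ids[ord][seq_len(min(d, length(ids)))])
}

#' Average hyper-edge extracted from per-subject hyper-networks
#'
#' Convenience wrapper over [average_hyperedge()]: pulls the hyper-edge for
#' `(centroid, lambda_fraction)` out of each subject's network using its
#' construction metadata.
#'
#' @param networks list of [build_hypernetwork()] results for one group.
#' @param centroid centroid region index.
#' @param lambda_fraction penalty fraction (must be a grid value).
#' @return Sorted integer member vector.
#' @export
group_average_hyperedge <- function(networks, centroid, lambda_fraction) {
  edges <- lapply(networks, function(net) {
    hit <- which(net$meta$centroids == centroid &
                 abs(net$meta$fractions - lambda_fraction) < 1e-9)
    if (length(hit) != 1L)
      stop_hn("hn_config_error",
              "no unique hyper-edge for centroid %d at fraction %g",
              centroid, lambda_fraction)
    net$edges[[hit]]
  })
  average_hyperedge(edges)
}
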