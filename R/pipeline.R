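#' Extract clustering-coefficient features for a whole cohort
#'
#' Builds every subject's hyper-network under one construction
#' specification and assembles the flattened node features into a
#' [feature_table()] (3 features per region per subject).
#'
#' @param cohort a [cohort()].
#' @param spec a [hyper_spec()].
#' @param keep_networks also return the per-subject networks.
#' @return A [feature_table()]; with `keep_networks = TRUE`, a list
#'   `table`, `networks`.
#' @export
extract_features <- function(cohort, spec, keep_networks = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  nets <- lapply(cohort$subjects, build_hypernetwork, spec = spec)
  rows <- lapply(nets, function(n) hcc_features(n)$features)
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  tab <- feature_table(values, cohort$labels)
  if (keep_networks) list(table = tab, networks = nets) else tab
}

#' End-to-end pipeline configuration
#'
#' Collects every stage's parameters: simulation (or a manifest path),
#' construction method and grids, clustering `k` for the group lasso,
#' permutation-test settings, and the classifier configuration. Defaults
#' mirror the canonical analysis: 9-level penalty grid 0.1..0.9,
#' `lambda2 = 0.2`, `k = 48` with 10 clustering restarts, FDR `q = 0.05`,
#' SVM grids `2^(-8:8)`.
#'
#' @param method construction penalty.
#' @param simulation a [sim_config()], or `NULL` to read `manifest`.
#' @param manifest path to a cohort manifest (used when `simulation` is
#'   `NULL`).
#' @param lambda_grid penalty fractions.
#' @param lambda2 elastic-net ridge penalty.
#' @param k group count for the group-lasso clustering.
#' @param n_restarts clustering restarts.
#' @param n_perm permutations for feature selection.
#' @param q FDR level.
#' @param classifier a [classifier_config()].
#' @param seed master seed for clustering, permutation and classifier fold
#'   randomness.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("lasso", "elastic_net", "group_lasso"),
                            simulation = NULL, manifest = NULL,
                            lambda_grid = seq(0.1, 0.9, by = 0.1),
                            lambda2 = 0.2, k = 48, n_restarts = 10,
                            n_perm = 10000, q = 0.05,
                            classifier = classifier_config(), seed = 1) {
  method <- match.arg(method)
  if (is.null(simulation) && is.null(manifest))
    stop_hn("hn_config_error", "provide either a simulation config or a manifest path")
  structure(list(method = method, simulation = simulation,
                 manifest = manifest, lambda_grid = lambda_grid,
                 lambda2 = lambda2, k = k, n_restarts = n_restarts,
                 n_perm = n_perm, q = q, classifier = classifier,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full hyper-network classification pipeline
#'
#' Stages: obtain the cohort (simulate or read) -> for the group lasso,
#' cluster regions by k-medoids on the cohort-pooled similarity -> build
#' per-subject hyper-networks -> extract clustering-coefficient features ->
#' KS permutation selection with BH-FDR -> nested LOOCV RBF-SVM on the
#' selected features. When no feature survives selection, classification
#' is skipped with a warning and the evaluation is `NULL`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's artifact is
#'   written there (TSV/JSON) and hashed into the run manifest.
#' @return Object of class `run_manifest`: the config, per-stage results
#'   (`cohort`, `partition`, `features`, `selection`, `evaluation`), stage
#'   timings, and when `out_dir` is set, file paths with MD5 hashes.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation)
    coh <- sim$cohort; truth <- sim$truth
  } else {
    coh <- read_cohort(config$manifest)
  }
  timings["cohort"] <- lap(t0)

  partition <- NULL
  groups <- NULL
  if (config$method == "group_lasso") {
    t0 <- tic()
    partition <- kmedoids(roi_similarity(coh), k = config$k,
                          seed = config$seed, n_restarts = config$n_restarts)
    groups <- partition
    timings["clustering"] <- lap(t0)
  }
  spec <- hyper_spec(config$method, config$lambda_grid,
                     lambda2 = config$lambda2, groups = groups)

  t0 <- tic()
  feats <- extract_features(coh, spec)
  timings["features"] <- lap(t0)

  t0 <- tic()
  selection <- select_features(feats, n_perm = config$n_perm, q = config$q,
                               seed = config$seed)
  timings["selection"] <- lap(t0)

  evaluation <- NULL
  t0 <- tic()
  if (any(selection$rejected)) {
    sel <- feature_table(
      feats$values[, selection$rejected, drop = FALSE], feats$labels)
    evaluation <- loocv_evaluate(sel, config$classifier)
  } else {
    warning("no feature survived FDR selection; classification skipped")
  }
  timings["classification"] <- lap(t0)

  manifest <- structure(list(
    config = config, truth = truth, cohort = coh, partition = partition,
    features = feats, selection = selection, evaluation = evaluation,
    timings = timings, files = NULL,
    version = as.character(utils::packageVersion("hypernet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")

  if (!is.null(out_dir)) manifest$files <- write_run(manifest, out_dir)
  manifest
}

write_run <- function(manifest, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  paths["manifest"] <- write_cohort(manifest$cohort, file.path(out_dir, "cohort"))
  if (!is.null(manifest$partition))
    paths["partition"] <- write_partition(
      manifest$partition, file.path(out_dir, "partition.tsv"),
      manifest$cohort$subjects[[1L]]$roi_labels)
  ft <- file.path(out_dir, "features.tsv")
  utils::write.table(
    data.frame(subject_id = rownames(manifest$features$values),
               group = manifest$features$labels,
               manifest$features$values, check.names = FALSE),
    ft, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["features"] <- ft
  st <- file.path(out_dir, "selection.tsv")
  utils::write.table(manifest$selection, st, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["selection"] <- st
  if (!is.null(manifest$evaluation)) {
    ev <- file.path(out_dir, "evaluation.json")
    e <- manifest$evaluation
    jsonlite::write_json(list(
      accuracy = e$accuracy, sensitivity = e$sensitivity,
      specificity = e$specificity, bac = e$bac,
      predictions = as.list(e$predictions),
      confusion = list(tp = e$tp, tn = e$tn, fp = e$fp, fn = e$fn)
    ), ev, auto_unbox = TRUE, digits = NA)
    paths["evaluation"] <- ev
  }
  data.frame(stage = names(paths), path = unname(paths),
             md5 = unname(tools::md5sum(paths)), stringsAsFactors = FALSE)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> method %s, %d subjects, %d/%d features selected\n",
              x$config$method, length(x$cohort$subjects),
              sum(x$selection$rejected), nrow(x$selection)))
  if (!is.null(x$evaluation))
    cat(sprintf("  LOOCV accuracy %.2f%% (BAC %.3f%%)\n",
                x$evaluation$accuracy, x$evaluation$bac))
  invisible(x)
}

#' Sweep the group-lasso cluster count k
#'
#' Repeats the group-lasso pipeline for each `k` with distinct seeds
#' (clustering initialization is the randomness the repeats average over)
#' and reports mean and standard deviation of the LOOCV accuracy.
#'
#' @param config a [pipeline_config()] with `method = "group_lasso"`.
#' @param k_values cluster counts (default the arithmetic sweep 6, 12, ...,
#'   90 capped at R).
#' @param repeats runs per `k` (default 50 in the full design; use fewer
#'   for quick looks).
#' @return `data.frame` with columns `k`, `mean_accuracy`, `sd_accuracy`,
#'   `n_runs` (accuracy `NA` when nothing was selected in any run).
#' @export
sweep_k <- function(config, k_values = seq(6, 90, by = 6), repeats = 50) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$method != "group_lasso")
    stop_hn("hn_config_error", "sweep_k applies to the group lasso only")
  rows <- lapply(k_values, function(k) {
    accs <- vapply(seq_len(repeats), function(r) {
      cfg <- config
      cfg$k <- k
      cfg$seed <- derive_seed(config$seed, k * 1000L + r)
      res <- suppressWarnings(run_pipeline(cfg))
      if (is.null(res$evaluation)) NA_real_ else res$evaluation$accuracy
    }, numeric(1))
    ok <- accs[!is.na(accs)]
    data.frame(k = k,
               mean_accuracy = if (length(ok)) mean(ok) else NA_real_,
               sd_accuracy = if (length(ok) > 1) stats::sd(ok) else 0,
               n_runs = length(ok))
  })
  do.call(rbind, rows)
}

#' Enumerate the ascending-prefix lambda1 / lambda2 grid
#'
#' The multi-level elastic-net design pairs each ascending prefix of the
#' 9-level grid (`{0.1}`, `{0.1, 0.2}`, ..., `{0.1..0.9}`) with each
#' `lambda2` value, giving 81 configurations by default.
#'
#' @param lambda1_levels full ascending grid (default `seq(0.1, 0.9, 0.1)`).
#' @param lambda2_values ridge penalties (default `seq(0.1, 0.9, 0.1)`).
#' @return `data.frame` with columns `prefix_length`, `lambda1_max`,
#'   `lambda2`, one row per configuration in deterministic order.
#' @export
enumerate_lambda_grid <- function(lambda1_levels = seq(0.1, 0.9, by = 0.1),
                                  lambda2_values = seq(0.1, 0.9, by = 0.1)) {
  grid <- expand.grid(prefix_length = seq_along(lambda1_levels),
                      lambda2 = lambda2_values)
  grid <- grid[order(grid$prefix_length, grid$lambda2), ]
  grid$lambda1_max <- lambda1_levels[grid$prefix_length]
  rownames(grid) <- NULL
  grid[, c("prefix_length", "lambda1_max", "lambda2")]
}

#' Sweep the elastic-net multi-level penalty grid
#'
#' Runs the elastic-net pipeline for every (lambda1-prefix, lambda2)
#' configuration from [enumerate_lambda_grid()]. Single-level prefixes can
#' leave nodes in only one hyper-edge, making the third clustering
#' coefficient degenerate; a warning reports the degenerate fraction when
#' it is high.
#'
#' @param config a [pipeline_config()] with `method = "elastic_net"`.
#' @param lambda1_levels,lambda2_values grids (defaults as in the full
#'   design: 9 x 9 = 81 runs).
#' @return `data.frame`: `prefix_length`, `lambda1_max`, `lambda2`,
#'   `accuracy`, `n_selected`.
#' @export
sweep_lambda <- function(config,
                         lambda1_levels = seq(0.1, 0.9, by = 0.1),
                         lambda2_values = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$method != "elastic_net")
    stop_hn("hn_config_error", "sweep_lambda applies to the elastic net only")
  grid <- enumerate_lambda_grid(lambda1_levels, lambda2_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$lambda_grid <- lambda1_levels[seq_len(grid$prefix_length[i])]
    cfg$lambda2 <- grid$lambda2[i]
    if (length(cfg$lambda_grid) == 1L)
      warning(sprintf(
        "single-level grid {%g}: third clustering coefficient may be degenerate",
        cfg$lambda_grid), call. = FALSE)
    run <- suppressWarnings(run_pipeline(cfg))
    data.frame(grid[i, ],
               accuracy = if (is.null(run$evaluation)) NA_real_
                          else run$evaluation$accuracy,
               n_selected = sum(run$selection$rejected))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
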