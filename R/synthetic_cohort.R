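#' Configuration for the synthetic resting-state cohort generator
#'
#' The generator emulates a two-group, 90-region resting-state cohort with
#' 238 retained volumes per subject. Regions are organised in correlated
#' blocks (modules): each region is a mixture of its block's latent signal
#' and private noise, all components AR(1)-filtered white noise, so the
#' expected within-block correlation equals `within_block_corr` exactly. In
#' patients, the regions in `affected_rois` gain an extra signal shared with
#' a distant block, scaled by `effect_size`, shifting their cross-block
#' coupling and hence their hyper-edge memberships.
#'
#' @param n_control,n_patient subjects per group (defaults 28 and 38, a
#'   typical clinical cohort size).
#' @param n_rois number of regions (default 90, AAL-sized parcellation).
#' @param n_timepoints retained volumes per subject (default 238; `>= 20`).
#' @param block_partition list of disjoint integer vectors covering
#'   `1:n_rois`; default: 6 contiguous blocks of equal size.
#' @param within_block_corr expected correlation between regions of one
#'   block, in `[0, 1)` (default 0.6, a typical within-module resting-state
#'   coupling).
#' @param ar_coefficient lag-1 temporal autocorrelation of all signal
#'   components, in `(-1, 1)` (default 0.3, moderate BOLD autocorrelation at
#'   TR = 2 s).
#' @param affected_rois integer vector of regions carrying the injected
#'   group difference (default: first 3 regions of the first block).
#' @param effect_size nonnegative scale of the extra shared signal added in
#'   patients (default 1: added coupling comparable to the block signal).
#' @param tr_seconds repetition time recorded on each subject (default 2).
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_control = 28, n_patient = 38, n_rois = 90,
                       n_timepoints = 238, block_partition = NULL,
                       within_block_corr = 0.6, ar_coefficient = 0.3,
                       affected_rois = NULL, effect_size = 1,
                       tr_seconds = 2, seed = 1) {
  if (n_rois < 2 || n_timepoints < 20)
    stop_hn("hn_config_error", "need n_rois >= 2 and n_timepoints >= 20")
  if (is.null(block_partition)) {
    nb <- min(6L, n_rois)
    block_partition <- split(seq_len(n_rois),
                             rep(seq_len(nb), length.out = n_rois, each = ceiling(n_rois / nb))[seq_len(n_rois)])
    block_partition <- unname(lapply(block_partition, as.integer))
  }
  block_partition <- lapply(unname(block_partition), function(b) as.integer(b))
  flat <- sort(as.integer(unlist(block_partition)))
  if (!identical(flat, seq_len(n_rois)))
    stop_hn("hn_config_error",
            "block_partition must be disjoint and cover all %d ROIs", n_rois)
  if (is.null(affected_rois)) affected_rois <- block_partition[[1L]][seq_len(min(3L, length(block_partition[[1L]])))]
  affected_rois <- sort(as.integer(affected_rois))
  if (length(affected_rois) && (min(affected_rois) < 1 || max(affected_rois) > n_rois))
    stop_hn("hn_config_error", "affected_rois outside 1:%d", n_rois)
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop_hn("hn_config_error", "within_block_corr must lie in [0, 1)")
  if (abs(ar_coefficient) >= 1)
    stop_hn("hn_config_error", "ar_coefficient must lie in (-1, 1)")
  if (effect_size < 0)
    stop_hn("hn_config_error", "effect_size must be nonnegative")
  structure(list(
    n_control = as.integer(n_control), n_patient = as.integer(n_patient),
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    block_partition = block_partition,
    within_block_corr = within_block_corr,
    ar_coefficient = ar_coefficient,
    affected_rois = affected_rois, effect_size = effect_size,
    tr_seconds = tr_seconds, seed = as.integer(seed)
  ), class = "sim_config")
}

# Unit-variance stationary AR(1) series, one per column, with burn-in.
ar1_noise <- function(n, p, phi, burn = 100L) {
  innov <- matrix(stats::rnorm((n + burn) * p, sd = sqrt(1 - phi^2)),
                  n + burn, p)
  out <- matrix(0, n + burn, p)
  for (j in seq_len(p))
    out[, j] <- stats::filter(innov[, j], phi, method = "recursive")
  out[(burn + 1L):(burn + n), , drop = FALSE]
}

# Block of the partition that carries the patient coupling: the last block
# containing none of the affected regions (a "distant" module).
coupling_block <- function(config) {
  free <- which(!vapply(config$block_partition,
                        function(b) any(b %in% config$affected_rois),
                        logical(1)))
  if (length(free) == 0L) return(integer(0))
  config$block_partition[[max(free)]]
}

#' Simulate one subject's regional time series
#'
#' Deterministic given `(config, group, subject_seed)`. Patient subjects
#' receive the injected cross-block coupling described in [sim_config()];
#' controls do not. All columns are z-scored before return.
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed integer RNG seed for this subject.
#' @param subject_id identifier stored on the result.
#' @return An [roi_ts()] of size `n_timepoints x n_rois`.
#' @export
simulate_subject <- function(config, group = c("control", "patient"),
                             subject_seed = config$seed,
                             subject_id = sprintf("sim_%s_%d", group[1L], subject_seed)) {
  group <- match.arg(group)
  stopifnot(inherits(config, "sim_config"))
  T <- config$n_timepoints; R <- config$n_rois
  rho <- config$within_block_corr; phi <- config$ar_coefficient
  mat <- with_seed(subject_seed, {
    latents <- ar1_noise(T, length(config$block_partition), phi)
    noise <- ar1_noise(T, R, phi)
    x <- matrix(0, T, R)
    for (b in seq_along(config$block_partition)) {
      idx <- config$block_partition[[b]]
      x[, idx] <- sqrt(rho) * latents[, b] +
        sqrt(1 - rho) * noise[, idx, drop = FALSE]
    }
    if (group == "patient" && config$effect_size > 0 &&
        length(config$affected_rois)) {
      shared <- ar1_noise(T, 1L, phi)[, 1L]
      hit <- union(config$affected_rois, coupling_block(config))
      x[, hit] <- x[, hit, drop = FALSE] + config$effect_size * shared
    }
    x
  })
  ts <- roi_ts(mat, subject_id = subject_id,
               roi_labels = sprintf("ROI%03d", seq_len(R)),
               tr_seconds = config$tr_seconds)
  standardize_columns(ts)
}

# Deterministic 32-bit-safe per-subject seed derivation.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 83492791) * 7919 + index * 104729) %% 2147483647L
}

#' Expected correlation matrix implied by a simulation config
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"patient"`.
#' @return `n_rois x n_rois` target correlation matrix.
#' @export
target_correlation <- function(config, group = c("control", "patient")) {
  group <- match.arg(group)
  R <- config$n_rois
  cov <- diag(1 - config$within_block_corr, R)
  for (b in config$block_partition)
    cov[b, b] <- cov[b, b] + config$within_block_corr
  if (group == "patient" && config$effect_size > 0 &&
      length(config$affected_rois)) {
    ind <- rep(0, R)
    ind[union(config$affected_rois, coupling_block(config))] <- config$effect_size
    cov <- cov + outer(ind, ind)
  }
  stats::cov2cor(cov)
}

#' Simulate a full two-group cohort
#'
#' Subjects are generated with per-subject seeds derived deterministically
#' from `config$seed`, controls first.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (a [cohort()]) and `truth` (the
#'   ground-truth structure: block partition, affected regions and per-group
#'   target correlation matrices).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_control < 1L || config$n_patient < 1L)
    stop_hn("hn_config_error", "both groups need at least one subject")
  labels <- c(rep("control", config$n_control), rep("patient", config$n_patient))
  subjects <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    subjects[[i]] <- simulate_subject(
      config, labels[i], subject_seed = derive_seed(config$seed, i),
      subject_id = sprintf("%s%02d", substr(labels[i], 1, 3), i))
  }
  truth <- structure(list(
    block_partition = config$block_partition,
    affected_rois = config$affected_rois,
    target_correlation = list(
      control = target_correlation(config, "control"),
      patient = target_correlation(config, "patient"))
  ), class = "ground_truth")
  list(cohort = cohort(subjects, labels), truth = truth)
}
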