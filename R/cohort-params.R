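# Cohort-level generating parameters. Defaults define the study conditions
# the synthetic cohort emulates: 24 scanned subjects, remote-only recognition
# priming, group-level mPFC differentiation of remotely learned overlapping
# pairs that nevertheless correlates positively with priming, and a
# post-remote-learning increase in posterior-hippocampus/LOC rest coupling.

#' Cohort generating parameters
#'
#' Bundles every knob of the synthetic cohort. The three subject latents —
#' recognition priming (ms, remote session), the change in integration-model
#' fit in mPFC for remote sequences (Fisher-z units of same-pair pattern
#' correlation), and the change in posterior-hippocampus/LOC rest coupling
#' (Fisher-z) — are drawn from a multivariate normal with the given means,
#' SDs and correlation matrix; everything downstream is linear-additive in
#' them. Between-subject SDs are deliberately generous relative to trial/scan
#' measurement noise so that individual differences remain recoverable from
#' 6-minute rest scans and 36-cell similarity matrices.
#'
#' @param n_subjects cohort size.
#' @param latent_means,latent_sds named length-3 vectors for
#'   `priming`, `integration`, `coupling`.
#' @param latent_corr 3x3 correlation matrix (must be symmetric positive
#'   definite).
#' @param learning list: `base_rt_ms`, `session_slowdown` (log-units added for
#'   the remote session), `rep_decay` and `pred_extra_decay` (log-unit drops
#'   across the full learning curve), `rt_noise_sd` (log scale),
#'   `response_window_ms`, `accuracy_base`, `accuracy_pred_gain`.
#' @param recognition list: `base_rt_ms`, `rt_noise_sd` (log scale),
#'   `hit_rate`, `fa_rate`, `priming_recent_ms` (usually 0).
#' @param explicit list: `p_correct` (2AFC), `subject_logit_sd`,
#'   `rating_effect_C`, `rating_effect_AB`, `rating_noise_sd` (Experiment 1).
#' @param patterns list: `n_voxels`, `rho_same_pre` (pre-learning same-pair
#'   pattern correlation), `est_noise_sd` (pattern-mode estimation noise, SD
#'   per voxel relative to unit signal), `glm_noise_sd` (time-series noise),
#'   `drift_amp`, `baseline_signal`, `roi_session_effects` (tibble: roi,
#'   session, pair_class, delta_mean, delta_sd, latent flag — non-latent
#'   ROI/session change effects).
#' @param rest list: `n_volumes`, `TR`, `n_voxels`, `voxel_noise_sd`,
#'   `baseline_r`, `effects` (tibble: scan, pair, delta_mean, delta_sd,
#'   latent flag), nuisance amplitudes `motion_amp`, `spike_amp`,
#'   `tissue_amp`, `drift_amp`, `spike_rate`.
#' @param rois ROI labels.
#' @param rest_pairs ROI pairs analysed for coupling.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_subjects = 24,
    latent_means = c(priming = 60, integration = -0.10, coupling = 0.25),
    latent_sds = c(priming = 90, integration = 0.20, coupling = 0.80),
    latent_corr = matrix(c(1, 0.6, 0.6,
                           0.6, 1, 0.4,
                           0.6, 0.4, 1), 3, 3,
                         dimnames = list(c("priming", "integration", "coupling"),
                                         c("priming", "integration", "coupling"))),
    learning = list(base_rt_ms = 1000, session_slowdown = 0.05,
                    rep_decay = 0.15, pred_extra_decay = 0.08,
                    rt_noise_sd = 0.15, response_window_ms = 2000,
                    accuracy_base = 0.93, accuracy_pred_gain = 0.05),
    recognition = list(base_rt_ms = 800, rt_noise_sd = 0.015,
                       hit_rate = 0.97, fa_rate = 0.03,
                       priming_recent_ms = 0),
    explicit = list(p_correct = 0.63, subject_logit_sd = 0.4,
                    rating_effect_C = 0.04, rating_effect_AB = 0.3,
                    rating_noise_sd = 0.15),
    patterns = list(n_voxels = 250, rho_same_pre = 0.15, est_noise_sd = 0.12,
                    glm_noise_sd = 1.2, drift_amp = 2, baseline_signal = 100,
                    roi_session_effects = NULL),
    rest = list(n_volumes = 180, TR = 2, n_voxels = 20, voxel_noise_sd = 0.2,
                baseline_r = 0.3, effects = NULL,
                motion_amp = 0.6, spike_amp = 3, tissue_amp = 0.5,
                drift_amp = 1, spike_rate = 0.02),
    rois = c("mPFC", "LOC", "antHPC", "postHPC"),
    rest_pairs = c("postHPC-LOC", "antHPC-LOC", "mPFC-LOC",
                   "postHPC-mPFC", "antHPC-mPFC")) {
  if (is.null(patterns$roi_session_effects)) {
    # non-latent change effects in same-pair similarity (Fisher-z units):
    # LOC integrates recently learned pairs immediately; mPFC shows a weak
    # (non-latent) recent-session drift; hippocampal ROIs change little for C
    # pairs but antHPC integrates recent AB pairs.
    patterns$roi_session_effects <- tibble::tibble(
      roi = c("mPFC", "LOC", "LOC", "antHPC", "postHPC",
              "antHPC", "LOC"),
      session = c("recent", "recent", "remote", "recent", "recent",
                  "recent", "recent"),
      pair_class = c("C", "C", "C", "C", "C", "AB", "AB"),
      delta_mean = c(-0.05, 0.12, 0, 0, 0, 0.10, 0.10),
      delta_sd = c(0.15, 0.15, 0.15, 0.10, 0.10, 0.10, 0.10))
  }
  if (is.null(rest$effects)) {
    # non-latent coupling changes (Fisher-z units); the postHPC-LOC
    # post-remote change is latent-driven and lives outside this table
    rest$effects <- tibble::tibble(
      scan = c("post_recent", "post_recent"),
      pair = c("mPFC-LOC", "postHPC-LOC"),
      delta_mean = c(0.15, 0.05),
      delta_sd = c(0.30, 0.30))
  }
  nm <- c("priming", "integration", "coupling")
  stopifnot(identical(names(latent_means), nm), identical(names(latent_sds), nm),
            all(latent_sds >= 0))
  if (!isSymmetric(unname(latent_corr))) stop("latent correlation matrix must be symmetric")
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) stop("latent correlation matrix must be positive definite")
  out <- list(n_subjects = n_subjects, latent_means = latent_means,
              latent_sds = latent_sds, latent_corr = latent_corr,
              learning = learning, recognition = recognition,
              explicit = explicit, patterns = patterns, rest = rest,
              rois = rois, rest_pairs = rest_pairs)
  class(out) <- "cohort_params"
  out
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("<cohort_params: %d subjects, latents (mean/sd): priming %g/%g ms, integration %g/%g, coupling %g/%g>\n",
              x$n_subjects, x$latent_means[1], x$latent_sds[1],
              x$latent_means[2], x$latent_sds[2],
              x$latent_means[3], x$latent_sds[3]))
  invisible(x)
}

#' Draw per-subject latent effect sizes
#'
#' Multivariate-normal draws of (priming, delta-integration, delta-coupling)
#' with the configured means, SDs and cross-subject correlations — the ground
#' truth that parameter-recovery analyses target.
#'
#' @param params a [cohort_params()].
#' @param seed integer seed.
#' @param n_subjects optional override of `params$n_subjects`.
#' @param empirical if `TRUE`, condition the draw so the sample mean and
#'   covariance equal the targets exactly (`MASS::mvrnorm(empirical = TRUE)`).
#'   Used by parameter-recovery analyses to isolate measurement fidelity from
#'   the finite-sample error of the draw itself; leave `FALSE` (iid draws)
#'   for power and calibration runs.
#' @return tibble with `subject`, `priming`, `integration`, `coupling`.
#' @export
sample_subject_latents <- function(params, seed, n_subjects = NULL,
                                   empirical = FALSE) {
  stopifnot(inherits(params, "cohort_params"))
  n <- n_subjects %||% params$n_subjects
  D <- diag(params$latent_sds)
  Sigma <- D %*% params$latent_corr %*% D
  with_seed(seed, {
    L <- MASS::mvrnorm(n, mu = params$latent_means, Sigma = Sigma,
                       empirical = empirical)
    if (n == 1) L <- matrix(L, 1, dimnames = list(NULL, names(params$latent_means)))
    tibble::tibble(subject = sprintf("sub%03d", seq_len(n)),
                   priming = unname(L[, "priming"]),
                   integration = unname(L[, "integration"]),
                   coupling = unname(L[, "coupling"]))
  })
}
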