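# Resting-state coupling: nuisance GLM, zero-phase band-pass, ROI mean
# courses, Fisher-z Pearson coupling, and pre/post change scores.

#' Build the nuisance model matrix for a rest scan
#'
#' Columns: 6 motion parameters and their temporal derivatives, one-hot spike
#' (stick) regressors for flagged volumes, white-matter and CSF mean signals
#' and their derivatives, and an intercept. Derivatives are backward
#' differences with the first element set to 0.
#'
#' @param nuisance tibble/data.frame with columns `mot1`..`mot6`, `spike`
#'   (0/1 indicator of sudden head movement), `wm`, `csf`. Any subset works;
#'   missing pieces are skipped.
#' @return numeric matrix with one row per volume.
#' @export
nuisance_model_matrix <- function(nuisance) {
  nz <- as.data.frame(nuisance)
  n <- nrow(nz)
  deriv <- function(x) c(0, diff(x))
  cols <- list(intercept = rep(1, n))
  mot <- grep("^mot", names(nz), value = TRUE)
  for (m in mot) {
    cols[[m]] <- nz[[m]]
    cols[[paste0(m, "_d")]] <- deriv(nz[[m]])
  }
  if ("spike" %in% names(nz)) {
    spikes <- which(nz$spike != 0)
    for (s in spikes) {
      v <- numeric(n); v[s] <- 1
      cols[[paste0("spike_", s)]] <- v
    }
  }
  for (tis in intersect(c("wm", "csf"), names(nz))) {
    cols[[tis]] <- nz[[tis]]
    cols[[paste0(tis, "_d")]] <- deriv(nz[[tis]])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Regress nuisance signals out of a time series
#'
#' Least-squares residuals per row (voxel or ROI mean course) after projecting
#' out the nuisance model. Exact linear contamination by nuisance columns is
#' annihilated.
#'
#' @param ts numeric vector or voxels x volumes matrix.
#' @param nuisance nuisance table (see [nuisance_model_matrix()]) or a
#'   ready-made model matrix.
#' @return residuals with the input's shape.
#' @export
nuisance_regress <- function(ts, nuisance) {
  X <- if (is.matrix(nuisance) && is.numeric(nuisance)) nuisance else
    nuisance_model_matrix(nuisance)
  vec <- is.null(dim(ts))
  Y <- if (vec) matrix(ts, ncol = 1) else t(as.matrix(ts))
  if (nrow(Y) != nrow(X)) stop("nuisance rows must align with volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance model; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  R <- qr.resid(qrX, Y)
  if (vec) as.numeric(R) else t(R)
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' the pass band keeps its phase. Defaults retain 0.01-0.1 Hz, the band
#' carrying gray-matter resting-state coupling.
#'
#' @param ts numeric vector or voxels x volumes matrix.
#' @param TR repetition time, seconds.
#' @param low,high band edges, Hz; `high` must stay below Nyquist.
#' @return filtered series, same shape.
#' @export
bandpass <- function(ts, TR, low = 0.01, high = 0.1) {
  if (TR <= 0) stop("TR must be positive")
  if (high <= low) stop("high edge must exceed low edge")
  ny <- 1 / (2 * TR)
  if (high >= ny) stop("high edge must be below Nyquist (", ny, " Hz)")
  bf <- signal::butter(2, c(low, high) / ny, type = "pass")
  f1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.null(dim(ts))) f1(ts) else t(apply(as.matrix(ts), 1, f1))
}

#' Mean ROI time course
#' @param ts voxels x volumes matrix (>= 1 voxel).
#' @return per-volume mean across voxels.
#' @export
roi_mean <- function(ts) {
  m <- as.matrix(ts)
  if (nrow(m) == 0) stop("empty ROI: no voxels")
  colMeans(m)
}

#' Inter-ROI coupling estimate
#'
#' Pearson correlation between two ROI mean courses with its Fisher z.
#' Perfect correlations are capped (see [fisher_z()]) and flagged degenerate,
#' as are constant inputs.
#'
#' @param tsA,tsB numeric vectors, equal length >= 10.
#' @return list of class `coupling_estimate`: `r`, `z`, `n_volumes`,
#'   `degenerate`.
#' @export
coupling <- function(tsA, tsB) {
  if (length(tsA) != length(tsB)) stop("time courses must have equal length")
  if (length(tsA) < 10) stop("need at least 10 volumes")
  if (stats::sd(tsA) == 0 || stats::sd(tsB) == 0) {
    return(structure(list(r = NA_real_, z = NA_real_, n_volumes = length(tsA),
                          degenerate = TRUE), class = "coupling_estimate"))
  }
  r <- stats::cor(tsA, tsB)
  structure(list(r = r, z = fisher_z(r), n_volumes = length(tsA),
                 degenerate = abs(r) >= 1), class = "coupling_estimate")
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf("<coupling: r = %.4f, z = %.4f over %d volumes%s>\n", x$r, x$z,
              x$n_volumes, if (isTRUE(x$degenerate)) ", DEGENERATE" else ""))
  invisible(x)
}

#' Pre-to-post change in coupling
#'
#' `delta_z = z_post - z_pre`. In the study design the single pre-learning
#' scan is the baseline for both sessions: the post-remote scan (same day) and
#' the post-recent scan (next day) are each differenced against it.
#'
#' @param pre,post [coupling()] estimates.
#' @return change in Fisher z.
#' @export
coupling_change <- function(pre, post) {
  if (is.null(pre$z) || is.null(post$z)) stop("inputs must carry $z")
  post$z - pre$z
}

#' Variance-ratio F test for two change-score vectors
#'
#' Compares the variance of two paired sets of coupling changes (e.g. same-day
#' vs across-day change scores) with an F ratio on (n-1, n-1) degrees of
#' freedom, two-sided.
#'
#' @param deltas_a,deltas_b equal-length numeric vectors (n >= 3).
#' @return list with `F`, `df`, `p`.
#' @export
change_variance_test <- function(deltas_a, deltas_b) {
  if (length(deltas_a) != length(deltas_b)) stop("vectors must be paired/equal length")
  n <- length(deltas_a)
  if (n < 3) stop("need at least 3 pairs")
  f <- stats::var(deltas_a) / stats::var(deltas_b)
  p <- 2 * min(stats::pf(f, n - 1, n - 1), 1 - stats::pf(f, n - 1, n - 1))
  list(F = f, df = c(n - 1, n - 1), p = min(p, 1))
}

#' Process one rest scan into an ROI mean course
#'
#' The standard order: nuisance regression first, then zero-phase band-pass of
#' the residuals, then the ROI mean. `order = "filter_then_regress"` swaps the
#' first two steps (exposed because the two orders are not equivalent on
#' contaminated data).
#'
#' @param ts voxels x volumes matrix for one ROI.
#' @param nuisance nuisance table for the scan.
#' @param TR repetition time, seconds.
#' @param low,high band edges, Hz.
#' @param order processing order.
#' @return ROI mean course (numeric vector).
#' @export
process_rest_scan <- function(ts, nuisance, TR, low = 0.01, high = 0.1,
                              order = c("regress_then_filter",
                                        "filter_then_regress")) {
  order <- match.arg(order)
  # nuisance projection and the zero-phase filter are the same linear operator
  # for every voxel, so the ROI mean commutes with both; taking it first is
  # exactly equivalent and avoids per-voxel filtering
  m <- roi_mean(ts)
  if (order == "regress_then_filter") {
    bandpass(nuisance_regress(m, nuisance), TR, low, high)
  } else {
    nuisance_regress(bandpass(m, TR, low, high), nuisance)
  }
}
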