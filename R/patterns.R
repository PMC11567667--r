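# Pattern-similarity pipeline: single-trial-class GLM over exposure scans,
# cross-scan Pearson similarity matrices, point-biserial fit to the binary
# integration model, and pre/post change scores.

#' Double-gamma HRF specification
#'
#' Canonical two-gamma haemodynamic response: a positive response gamma minus
#' a scaled undershoot gamma. Defaults are the canonical parameterization
#' (delays 6 s and 16 s, unit dispersions, undershoot ratio 6).
#'
#' @param response_delay,undershoot_delay gamma peak delays, seconds.
#' @param response_dispersion,undershoot_dispersion gamma dispersions, seconds.
#' @param undershoot_ratio response/undershoot amplitude ratio.
#' @param duration kernel length, seconds.
#' @return list of class `hrf_spec`.
#' @export
hrf_spec <- function(response_delay = 6, undershoot_delay = 16,
                     response_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 6, duration = 32) {
  if (response_dispersion <= 0 || undershoot_dispersion <= 0) {
    stop("HRF dispersions must be positive")
  }
  if (response_delay <= 0 || undershoot_delay <= 0 || undershoot_ratio <= 0) {
    stop("HRF delays and undershoot ratio must be positive")
  }
  out <- list(response_delay = response_delay, undershoot_delay = undershoot_delay,
              response_dispersion = response_dispersion,
              undershoot_dispersion = undershoot_dispersion,
              undershoot_ratio = undershoot_ratio, duration = duration)
  class(out) <- "hrf_spec"
  out
}

#' Sample the double-gamma HRF kernel
#'
#' @param spec an [hrf_spec()].
#' @param dt sampling interval, seconds (> 0).
#' @return numeric kernel sampled at `0, dt, 2 dt, ...`, peak-normalized.
#' @export
hrf_kernel <- function(spec = hrf_spec(), dt = 0.1) {
  if (!inherits(spec, "hrf_spec")) stop("spec must be an hrf_spec")
  if (dt <= 0) stop("sampling interval must be positive")
  t <- seq(0, spec$duration, by = dt)
  a1 <- spec$response_delay / spec$response_dispersion
  a2 <- spec$undershoot_delay / spec$undershoot_dispersion
  h <- stats::dgamma(t, shape = a1, scale = spec$response_dispersion) -
    stats::dgamma(t, shape = a2, scale = spec$undershoot_dispersion) /
      spec$undershoot_ratio
  h / max(h)
}

# boxcar event train convolved with the HRF, sampled at TR
convolve_events <- function(onsets, n_volumes, TR, spec, boxcar = 3,
                            oversample = 10) {
  dt <- TR / oversample
  n_fine <- n_volumes * oversample
  u <- numeric(n_fine)
  for (on in onsets) {
    i0 <- floor(on / dt) + 1
    i1 <- min(n_fine, floor((on + boxcar) / dt))
    if (i0 <= n_fine) u[i0:max(i0, i1)] <- 1
  }
  k <- hrf_kernel(spec, dt)
  x <- stats::convolve(u, rev(k), type = "open")[seq_len(n_fine)]
  x[seq(1, n_fine, by = oversample)] * dt
}

#' Build the exposure-scan GLM design matrix
#'
#' One regressor per object (3-s boxcars at its non-target presentations,
#' HRF-convolved) plus a junk regressor for key-press (pound-sign) trials,
#' temporal derivatives of each, optional nuisance columns, and an intercept.
#'
#' @param trial_order exposure trial-order tibble.
#' @param n_volumes scan length in volumes.
#' @param TR repetition time, seconds.
#' @param spec an [hrf_spec()].
#' @param boxcar regressor boxcar duration, seconds (3 even though stimuli
#'   last 2 s, following the estimation convention this pipeline targets).
#' @param nuisance optional numeric matrix of nuisance columns (volumes rows).
#' @param derivatives include temporal derivatives of task regressors.
#' @return list with `X` (design matrix), `object_cols` (named indices of the
#'   object regressors), and `col_map` (tibble describing every column).
#' @export
build_design_matrix <- function(trial_order, n_volumes, TR, spec = hrf_spec(),
                                boxcar = 3, nuisance = NULL, derivatives = TRUE) {
  dur <- max(trial_order$onset + trial_order$duration)
  if (dur > n_volumes * TR) {
    stop(sprintf("trial order (%.1f s) exceeds scan duration (%.1f s)",
                 dur, n_volumes * TR))
  }
  objs <- unique(trial_order$object_id)
  cols <- list(); kinds <- character(0); names_ <- character(0)
  for (ob in objs) {
    ons <- trial_order$onset[trial_order$object_id == ob & !trial_order$target_flag]
    cols[[length(cols) + 1L]] <- convolve_events(ons, n_volumes, TR, spec, boxcar)
    kinds <- c(kinds, "object"); names_ <- c(names_, ob)
  }
  junk_ons <- trial_order$onset[trial_order$target_flag]
  junk <- convolve_events(junk_ons, n_volumes, TR, spec, boxcar)
  has_junk <- length(junk_ons) > 0
  if (has_junk) {
    cols[[length(cols) + 1L]] <- junk
    kinds <- c(kinds, "junk"); names_ <- c(names_, "junk")
  } else {
    warning("no key-press trials; junk regressor dropped")
  }
  if (derivatives) {
    nt <- length(cols)
    for (i in seq_len(nt)) {
      d <- c(0, diff(cols[[i]]))
      cols[[length(cols) + 1L]] <- d
      kinds <- c(kinds, paste0(kinds[i], "_deriv"))
      names_ <- c(names_, paste0(names_[i], "_deriv"))
    }
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes) stop("nuisance rows must equal n_volumes")
    for (j in seq_len(ncol(nuisance))) {
      cols[[length(cols) + 1L]] <- nuisance[, j]
      kinds <- c(kinds, "nuisance")
      names_ <- c(names_, colnames(nuisance)[j] %||% paste0("nuis", j))
    }
  }
  cols[[length(cols) + 1L]] <- rep(1, n_volumes)
  kinds <- c(kinds, "intercept"); names_ <- c(names_, "intercept")
  X <- do.call(cbind, cols)
  colnames(X) <- make.unique(names_)
  object_cols <- which(kinds == "object")
  names(object_cols) <- names_[object_cols]
  list(X = X, object_cols = object_cols,
       col_map = tibble::tibble(column = seq_along(kinds), name = colnames(X),
                                kind = kinds))
}

#' Fit the per-object GLM and extract beta / t patterns
#'
#' Ordinary least squares per voxel; `t = beta / SE(beta)` with residual
#' degrees of freedom `volumes - rank`. Returns one beta and one t vector per
#' object (rows), the pattern-matrix inputs for similarity analysis.
#'
#' @param timeseries voxels x volumes numeric matrix.
#' @param design result of [build_design_matrix()].
#' @return list with `beta` and `tstat` (objects x voxels matrices, rows named
#'   by object), `df`, and `sigma` (per-voxel residual SD).
#' @export
fit_trial_glm <- function(timeseries, design) {
  X <- design$X
  Y <- t(as.matrix(timeseries)) # volumes x voxels
  if (nrow(Y) != nrow(X)) stop("volumes in timeseries must match design rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y) # p x voxels
  res <- Y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  oc <- design$object_cols
  se <- sqrt(outer(diag(XtXinv)[oc], sigma2))
  b <- beta[oc, , drop = FALSE]
  tt <- b / se
  rownames(b) <- rownames(tt) <- names(oc)
  list(beta = b, tstat = tt, df = df, sigma = sqrt(sigma2))
}

#' Cross-scan pattern-similarity matrix
#'
#' Pearson correlations between every scan-1 pattern (rows, e.g. C1 objects)
#' and every scan-2 pattern (columns, e.g. C2 objects). Patterns are used as
#' extracted — no mean-level normalization — and only cross-scan pairs enter
#' the matrix, so similarity cannot be driven by within-scan temporal
#' proximity.
#'
#' @param patterns1,patterns2 objects x voxels matrices with rownames; rows
#'   must be aligned to sequence order (row i of each shares sequence i).
#' @return `similarity_matrix`: correlation matrix rows = scan-1 objects,
#'   columns = scan-2 objects.
#' @export
similarity_matrix <- function(patterns1, patterns2) {
  p1 <- as.matrix(patterns1); p2 <- as.matrix(patterns2)
  if (ncol(p1) != ncol(p2)) stop("patterns must have equal voxel counts")
  sd1 <- apply(p1, 1, stats::sd); sd2 <- apply(p2, 1, stats::sd)
  if (any(sd1 == 0)) stop("zero-variance pattern: ",
                          paste(rownames(p1)[sd1 == 0], collapse = ", "))
  if (any(sd2 == 0)) stop("zero-variance pattern: ",
                          paste(rownames(p2)[sd2 == 0], collapse = ", "))
  m <- stats::cor(t(p1), t(p2))
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Binary integration model matrix
#'
#' Ones where the row and column objects come from the same (overlapping)
#' sequence, zeros elsewhere. With rows/columns aligned to sequence order this
#' is the identity pattern: 6 ones, 30 zeros for a 6x6 matrix.
#'
#' @param n number of sequences (matrix dimension).
#' @return n x n binary matrix.
#' @export
integration_model <- function(n = 6) diag(n)

#' Fit the neural integration model to a similarity matrix
#'
#' Vectorizes all cells of the similarity matrix and computes the
#' point-biserial correlation (a Pearson correlation with the binary
#' same-sequence model vector), plus its Fisher z. A high value means objects
#' sharing an AB stem are more similar than objects from different sequences.
#'
#' @param sim_matrix square similarity matrix, rows/columns sequence-aligned.
#' @param model optional binary model matrix (defaults to same-sequence).
#' @return list of class `model_fit`: `r`, `z`, `n_cells`, `degenerate`.
#' @export
integration_fit <- function(sim_matrix, model = NULL) {
  m <- unclass(as.matrix(sim_matrix))
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (is.null(model)) model <- integration_model(nrow(m))
  sim_v <- as.vector(m); mod_v <- as.vector(model)
  if (stats::sd(sim_v) == 0) {
    return(structure(list(r = NA_real_, z = NA_real_, n_cells = length(sim_v),
                          degenerate = TRUE), class = "model_fit"))
  }
  r <- stats::cor(sim_v, mod_v)
  structure(list(r = r, z = fisher_z(r), n_cells = length(sim_v),
                 degenerate = abs(r) >= 1), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: r = %.4f, z = %.4f, %d cells%s>\n", x$r, x$z,
              x$n_cells, if (isTRUE(x$degenerate)) ", DEGENERATE" else ""))
  invisible(x)
}

#' Pre-to-post change in integration-model fit
#'
#' `delta_z = z_post - z_pre`. Positive values mean the fit increased
#' (integration); negative values mean overlapping pairs became relatively
#' less similar (differentiation).
#'
#' @param fit_pre,fit_post [integration_fit()] results (or anything with `$z`).
#' @return the change in Fisher z.
#' @export
change_score <- function(fit_pre, fit_post) {
  if (is.null(fit_pre$z) || is.null(fit_post$z)) stop("fits must carry $z")
  fit_post$z - fit_pre$z
}

#' Mean similarity for overlapping vs non-overlapping pairs
#'
#' @param sim_matrix square similarity matrix, sequence-aligned.
#' @param model optional binary model matrix.
#' @return named vector: `overlapping` (same-sequence cells) and
#'   `non_overlapping` (all other cells).
#' @export
overlap_means <- function(sim_matrix, model = NULL) {
  m <- unclass(as.matrix(sim_matrix))
  if (is.null(model)) model <- integration_model(nrow(m))
  c(overlapping = mean(m[model == 1]), non_overlapping = mean(m[model == 0]))
}

#' BOLD-difference control: partial integration fit
#'
#' Controls for the possibility that two objects look similar because their
#' average BOLD levels are close: for every cell, the absolute difference of
#' the two objects' mean pattern values is computed, and the model fit is
#' re-estimated as the partial correlation of similarity with the binary model
#' given that control vector.
#'
#' @param patterns1,patterns2 the pattern matrices behind `sim_matrix`.
#' @param sim_matrix their [similarity_matrix()].
#' @param model optional binary model matrix.
#' @return `model_fit` with partial `r`/`z`, plus `control_degenerate` flag
#'   (constant control falls back to the plain fit).
#' @export
bold_difference_control <- function(patterns1, patterns2, sim_matrix,
                                    model = NULL) {
  m <- unclass(as.matrix(sim_matrix))
  if (is.null(model)) model <- integration_model(nrow(m))
  mu1 <- rowMeans(as.matrix(patterns1)); mu2 <- rowMeans(as.matrix(patterns2))
  ctrl <- abs(outer(mu1, mu2, `-`))
  sim_v <- as.vector(m); mod_v <- as.vector(model); ctrl_v <- as.vector(ctrl)
  ctrl_scale <- max(abs(ctrl_v), 1)
  if (stats::sd(ctrl_v) <= 1e-10 * ctrl_scale ||
      isTRUE(all.equal(abs(stats::cor(ctrl_v, sim_v)), 1))) {
    fit <- integration_fit(sim_matrix, model)
    fit$control_degenerate <- TRUE
    return(fit)
  }
  pr <- partial_corr(sim_v, mod_v, cbind(ctrl_v))
  structure(list(r = pr$r, z = fisher_z(pr$r), n_cells = length(sim_v),
                 degenerate = abs(pr$r) >= 1, control_degenerate = FALSE),
            class = "model_fit")
}

#' Z-score each voxel across patterns
#'
#' Standardizes every voxel across the supplied patterns (within one phase),
#' down-weighting inordinately noisy voxels. Zero-variance voxels are dropped
#' with a message.
#'
#' @param pattern_set objects x voxels matrix (>= 2 rows).
#' @return transformed matrix (possibly fewer columns).
#' @export
voxel_zscore_control <- function(pattern_set) {
  p <- as.matrix(pattern_set)
  if (nrow(p) < 2) stop("need at least 2 patterns to z-score across")
  s <- apply(p, 2, stats::sd)
  if (any(s == 0)) {
    message(sum(s == 0), " zero-variance voxel(s) dropped")
    p <- p[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  scale(p, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Integration fit for A/B patterns
#'
#' Same contract as [similarity_matrix()] + [integration_fit()], with A
#' patterns (scan 1) as rows and B patterns (scan 2) as columns: tests whether
#' A and B objects from the same sequence are more similar than A/B pairs from
#' different sequences.
#'
#' @param patterns_A,patterns_B sequence-aligned pattern matrices.
#' @return `model_fit`.
#' @export
ab_integration_fit <- function(patterns_A, patterns_B) {
  integration_fit(similarity_matrix(patterns_A, patterns_B))
}

#' High-pass filter a voxel time-series matrix
#'
#' Zero-phase second-order Butterworth high-pass, applied per voxel; used on
#' exposure scans before the GLM to remove slow drifts.
#'
#' @param timeseries voxels x volumes matrix.
#' @param TR repetition time, seconds.
#' @param cutoff cutoff frequency, Hz.
#' @return filtered matrix of the same shape.
#' @export
highpass <- function(timeseries, TR, cutoff = 0.01) {
  ts <- as.matrix(timeseries)
  ny <- 1 / (2 * TR)
  if (cutoff <= 0 || cutoff >= ny) stop("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(2, cutoff / ny, type = "high")
  t(apply(ts, 1, function(v) as.numeric(signal::filtfilt(bf, v))))
}
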