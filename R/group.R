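# Across-subject inference: brain-behavior correlations, comparison of
# correlations (independent and dependent-nonoverlapping), partial
# correlations, two-predictor regression with semi-partial R2, and Bonferroni
# bookkeeping.

#' Across-subject Pearson correlation
#'
#' @param x,y numeric vectors (n >= 4, finite).
#' @return list with `r`, `df` (n - 2), `p` (two-sided), `n`, `degenerate`.
#' @export
brain_behavior_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, df = n - 2L, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
       n = n, degenerate = FALSE)
}

#' Compare two correlations
#'
#' `mode = "independent"`: classic Fisher-z difference test for correlations
#' from independent samples. `mode = "dependent"`: two dependent correlations
#' with no variable in common (e.g. cor(x1, y1) vs cor(x2, y2) measured on the
#' same subjects), using the Raghunathan-Rosenthal-Rubin modification of the
#' Pearson-Filon statistic; this needs the four cross-correlations among the
#' variables, supplied as `cross = c(r13, r14, r23, r24)` where the compared
#' correlations are r12 and r34.
#'
#' @param rA,rB the two correlations (|r| < 1).
#' @param nA sample size behind `rA` (and behind `rB` in dependent mode).
#' @param nB sample size behind `rB` (independent mode only).
#' @param mode `"independent"` or `"dependent"`.
#' @param cross cross-correlations `c(r13, r14, r23, r24)` (dependent mode).
#' @return list with `z`, `p` (two-sided), `mode`.
#' @export
compare_correlations <- function(rA, rB, nA, nB = nA,
                                 mode = c("independent", "dependent"),
                                 cross = NULL) {
  mode <- match.arg(mode)
  if (abs(rA) >= 1 || abs(rB) >= 1) stop("correlations must lie strictly inside (-1, 1)")
  zA <- atanh(rA); zB <- atanh(rB)
  if (mode == "independent") {
    if (nA < 4 || nB < 4) stop("need n >= 4 in both samples")
    z <- (zA - zB) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  } else {
    if (is.null(cross) || length(cross) != 4) {
      stop("dependent mode needs cross = c(r13, r14, r23, r24)")
    }
    if (nA < 4) stop("need n >= 4")
    r12 <- rA; r34 <- rB
    r13 <- cross[1]; r14 <- cross[2]; r23 <- cross[3]; r24 <- cross[4]
    # Pearson-Filon covariance of two nonoverlapping correlations
    k <- 0.5 * r12 * r34 * (r13^2 + r14^2 + r23^2 + r24^2) +
      r13 * r24 + r14 * r23 -
      (r12 * r13 * r14 + r12 * r23 * r24 + r34 * r13 * r23 + r34 * r14 * r24)
    cbar <- k / ((1 - r12^2) * (1 - r34^2))
    cbar <- min(max(cbar, -1 + 1e-12), 1 - 1e-12)
    z <- (zA - zB) * sqrt((nA - 3) / (2 - 2 * cbar))
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)), mode = mode)
}

#' Compare cor(x1, y1) with cor(x2, y2) measured on the same subjects
#'
#' Convenience front-end to [compare_correlations()] in dependent mode: the
#' two correlations share no variable but come from the same sample, so the
#' four cross-correlations are computed from the data.
#'
#' @param x1,y1,x2,y2 numeric vectors over the same subjects.
#' @return list with `z`, `p`, `rA`, `rB`.
#' @export
compare_correlations_data <- function(x1, y1, x2, y2) {
  keep <- is.finite(x1) & is.finite(y1) & is.finite(x2) & is.finite(y2)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  rA <- stats::cor(x1, y1); rB <- stats::cor(x2, y2)
  out <- compare_correlations(
    rA, rB, nA = length(x1), mode = "dependent",
    cross = c(stats::cor(x1, x2), stats::cor(x1, y2),
              stats::cor(y1, x2), stats::cor(y1, y2)))
  out$rA <- rA; out$rB <- rB
  out
}

#' Partial correlation
#'
#' Correlation of `x` and `y` after removing the covariates by least squares
#' from both; equals the Pearson correlation of the two residual vectors. With
#' no covariates this is the plain Pearson correlation. p uses a t reference
#' with `n - 2 - k` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariate columns (may be
#'   NULL or zero-column).
#' @return list with `r`, `df`, `p`, `degenerate`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 3) stop("need n > k + 3 observations")
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    qrZ <- qr(Z)
    if (qrZ$rank < ncol(Z)) stop("collinear covariates")
    rx <- qr.resid(qrZ, x); ry <- qr.resid(qrZ, y)
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  if (stats::sd(rx) < .Machine$double.eps^0.75 ||
      stats::sd(ry) < .Machine$double.eps^0.75) {
    return(list(r = NA_real_, df = n - 2L - k, p = NA_real_, degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Two-predictor regression with semi-partial R-squared
#'
#' OLS of `y` on the predictor columns; each predictor's semi-partial R2 is
#' the drop in R2 when it is removed from the full model (equivalently the
#' squared semi-partial correlation), the unique variance it explains.
#'
#' @param y outcome vector.
#' @param X matrix/data.frame of predictors (typically two columns).
#' @return list of class `regression_summary`: `coefficients` tibble
#'   (estimate, t, df, p, semipartial_R2 per predictor), `R2`, `n`.
#' @export
regression_semipartial <- function(y, X) {
  X <- as.matrix(X)
  keep <- is.finite(y) & apply(is.finite(X), 1, all)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 3) stop("need n > k + 3 observations")
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("collinear predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df_ <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df_)
  sm <- summary(fit)
  R2 <- sm$r.squared
  co <- sm$coefficients[-1, , drop = FALSE]
  sp <- vapply(seq_len(ncol(X)), function(j) {
    r2_reduced <- if (ncol(X) == 1) 0 else
      summary(stats::lm(y ~ ., data = df_[, -(j + 1), drop = FALSE]))$r.squared
    R2 - r2_reduced
  }, numeric(1))
  structure(list(
    coefficients = tibble::tibble(
      predictor = colnames(X),
      estimate = co[, 1], t = co[, 3], df = fit$df.residual, p = co[, 4],
      semipartial_R2 = sp),
    R2 = R2, n = n), class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("<regression_summary: n = %d, R2 = %.3f>\n", x$n, x$R2))
  print(x$coefficients)
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * family_size)`, with accept/reject decisions at `alpha`.
#' Adjust from unrounded p values; both raw and adjusted are reported.
#'
#' @param p_values raw p values in `[0, 1]`.
#' @param family_size number of tests in the family (>= 1).
#' @param alpha decision threshold.
#' @return tibble with `p`, `p_adjusted`, `significant`.
#' @export
bonferroni_adjust <- function(p_values, family_size, alpha = 0.05) {
  if (family_size < 1) stop("family_size must be >= 1")
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p values must lie in [0, 1]")
  }
  adj <- pmin(1, p_values * family_size)
  tibble::tibble(p = p_values, p_adjusted = adj, significant = adj < alpha)
}
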