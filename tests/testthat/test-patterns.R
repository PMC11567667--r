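test_that("the double-gamma kernel has canonical shape and rejects bad specs", {
  k <- hrf_kernel(hrf_spec(), dt = 0.1)
  t_peak <- (which.max(k) - 1) * 0.1
  expect_gt(t_peak, 4); expect_lt(t_peak, 8)
  expect_equal(max(k), 1) # peak-normalized
  expect_lt(min(k), 0)    # undershoot present
  expect_gt((which.min(k) - 1) * 0.1, t_peak)
  expect_error(hrf_spec(response_dispersion = 0), "positive")
  expect_error(hrf_kernel(hrf_spec(), dt = 0), "positive")
  # convolving with a unit impulse reproduces the kernel
  imp <- c(1, rep(0, 399))
  conv <- stats::convolve(imp, rev(k), type = "open")[seq_along(imp)]
  expect_equal(conv[seq_along(k)], k, tolerance = 1e-12)
})

test_that("design matrices hold one convolved regressor per object plus controls", {
  sets <- two_session_sets()
  ex <- generate_exposure_orders(sets, seed = 2)
  ord <- ex$scan1
  TR <- 2
  n_vol <- ceiling((max(ord$onset + ord$duration) + 20) / TR)
  des <- build_design_matrix(ord, n_vol, TR)
  n_obj <- length(unique(ord$object_id))
  # objects x 2 (value + derivative) + junk x 2 + intercept
  expect_equal(ncol(des$X), n_obj * 2 + 2 + 1)
  expect_equal(length(des$object_cols), n_obj)
  expect_equal(nrow(des$col_map), ncol(des$X))
  # an object's regressor has energy at each of its presentations
  ob <- names(des$object_cols)[1]
  col <- des$X[, des$object_cols[ob]]
  ons <- ord$onset[ord$object_id == ob & !ord$target_flag]
  for (on in ons) {
    win <- floor(on / TR) + seq_len(8)
    expect_gt(max(col[win[win <= n_vol]]), 0.1 * max(col))
  }
  # junk regressor models exactly the pound-sign trials
  expect_equal(sum(des$col_map$kind == "junk"), 1)
  # scan too short errors; target-free order drops junk with a warning
  expect_error(build_design_matrix(ord, 10, TR), "exceeds")
  ex0 <- generate_exposure_orders(sets, n_targets = 0, seed = 2)
  expect_warning(build_design_matrix(ex0$scan1, n_vol, TR), "junk")
})

test_that("noise-free GLM recovers generating betas exactly", {
  sets <- two_session_sets()
  ex <- generate_exposure_orders(sets, seed = 3)
  ord <- ex$scan1
  TR <- 2
  n_vol <- ceiling((max(ord$onset + ord$duration) + 20) / TR)
  des <- build_design_matrix(ord, n_vol, TR)
  set.seed(42)
  n_vox <- 15
  B_true <- matrix(0, ncol(des$X), n_vox)
  B_true[des$object_cols, ] <- rnorm(length(des$object_cols) * n_vox)
  B_true[nrow(B_true), ] <- 100
  Y <- t(des$X %*% B_true)
  fit <- fit_trial_glm(Y, des)
  expect_lt(max(abs(fit$beta - B_true[des$object_cols, ])), 1e-8)

  # duplicated column -> rank error naming the column
  des_bad <- des
  des_bad$X <- cbind(des$X, dup = des$X[, 1])
  expect_error(fit_trial_glm(Y, des_bad), "rank deficient")
})

test_that("similarity matrices are raw cross-scan Pearson correlations", {
  set.seed(1)
  p <- named_patterns(matrix(rnorm(6 * 50), 6), "C1_")
  s_self <- similarity_matrix(p, p)
  expect_equal(unname(diag(unclass(s_self))), rep(1, 6))

  # toy perfect linear relation
  u <- named_patterns(rbind(c(1, 2, 3), c(3, 1, 2)), "u")
  v <- named_patterns(rbind(c(2, 4, 6), c(5, 0, 1)), "v")
  expect_equal(unclass(similarity_matrix(u, v))[1, 1], 1)

  # independent long vectors: near-zero entries
  a <- named_patterns(matrix(rnorm(6 * 1000), 6), "a")
  b <- named_patterns(matrix(rnorm(6 * 1000), 6), "b")
  expect_lt(abs(mean(similarity_matrix(a, b))), 0.05)

  # zero-variance pattern is rejected by name
  z <- a; z[2, ] <- 7
  expect_error(similarity_matrix(z, b), "a2")
  # mean-level invariance: adding constants changes nothing
  expect_equal(unclass(similarity_matrix(a + 5, b - 3)),
               unclass(similarity_matrix(a, b)), tolerance = 1e-12)
})

test_that("integration fits equal the two-group point-biserial closed form", {
  # closed form: r = (m1 - m0) sqrt(p q) / s_n, s_n the population-SD of cells
  pb_closed <- function(m, model) {
    v <- as.vector(m); g <- as.vector(model)
    m1 <- mean(v[g == 1]); m0 <- mean(v[g == 0])
    p <- mean(g == 1); q <- 1 - p
    s_n <- sqrt(mean((v - mean(v))^2))
    (m1 - m0) * sqrt(p * q) / s_n
  }
  set.seed(7)
  for (i in 1:1000) {
    m <- matrix(runif(36, -1, 1), 6)
    fit <- integration_fit(m)
    expect_equal(fit$r, pb_closed(m, integration_model(6)), tolerance = 1e-12)
  }
  # the stated two-level example, plus exact extremes
  m <- matrix(0.2, 6, 6); diag(m) <- 0.8
  fit <- integration_fit(m)
  expect_equal(fit$r, pb_closed(m, integration_model(6)), tolerance = 1e-12)
  expect_equal(integration_fit(integration_model(6))$r, 1)
  expect_true(integration_fit(matrix(0.3, 6, 6))$degenerate)
  # relabeling invariance: permuting rows/columns with the model unchanged
  set.seed(8)
  sim <- matrix(rnorm(36), 6)
  perm <- sample(6)
  expect_equal(integration_fit(sim[perm, perm])$r,
               integration_fit(sim, diag(6)[perm, perm] * 0 + diag(6))$r,
               tolerance = 1e-12)
  expect_equal(integration_fit(sim[perm, perm], diag(6))$r,
               integration_fit(sim, diag(6)[order(perm), order(perm)])$r,
               tolerance = 1e-12)
})

test_that("change scores difference Fisher z with the documented sign convention", {
  f <- function(z) list(z = z)
  expect_equal(change_score(f(0.4), f(0.4)), 0)
  expect_equal(change_score(f(0.1), f(-0.2)), -0.3) # differentiation
  expect_equal(change_score(f(0.3), f(0.9)), -change_score(f(0.9), f(0.3)))
  # monotone: subject ordering preserved through atanh
  rs <- c(-0.5, 0, 0.3, 0.8)
  expect_true(all(diff(fisher_z(rs)) > 0))
})

test_that("overlap means partition the similarity matrix exactly", {
  m_const <- matrix(0.42, 6, 6)
  expect_equal(unname(overlap_means(m_const)), c(0.42, 0.42))
  expect_equal(unname(overlap_means(diag(6))), c(1, 0))
  set.seed(3)
  m <- matrix(rnorm(36), 6)
  om <- overlap_means(m)
  expect_equal(mean(m), unname((6 * om[1] + 30 * om[2]) / 36), tolerance = 1e-12)
})

test_that("the BOLD-difference control equals the residual-correlation oracle", {
  set.seed(11)
  p1 <- named_patterns(matrix(rnorm(6 * 80), 6), "C1_")
  p2 <- named_patterns(matrix(rnorm(6 * 80), 6), "C2_")
  # inject a mean-level gradient so the control vector is informative
  p1 <- p1 + seq(0, 2, length.out = 6)
  sim <- similarity_matrix(p1, p2)
  fit <- bold_difference_control(p1, p2, sim)
  # oracle: correlate the two OLS residual vectors directly
  ctrl <- abs(outer(rowMeans(p1), rowMeans(p2), `-`))
  r1 <- resid(lm(as.vector(unclass(sim)) ~ as.vector(ctrl)))
  r2 <- resid(lm(as.vector(integration_model(6)) ~ as.vector(ctrl)))
  expect_equal(fit$r, cor(r1, r2), tolerance = 1e-10)
  # constant control falls back to the plain fit with a flag
  pc1 <- named_patterns(matrix(rnorm(6 * 80), 6), "C1_")
  pc1 <- pc1 - rowMeans(pc1) # all row means 0 -> constant control
  pc2 <- named_patterns(matrix(rnorm(6 * 80), 6), "C2_")
  pc2 <- pc2 - rowMeans(pc2)
  simc <- similarity_matrix(pc1, pc2)
  fitc <- bold_difference_control(pc1, pc2, simc)
  expect_true(fitc$control_degenerate)
  expect_equal(fitc$r, integration_fit(simc)$r)
})

test_that("voxel z-scoring standardizes without changing shifted similarities", {
  set.seed(13)
  p <- named_patterns(matrix(rnorm(8 * 40), 8), "p")
  z <- voxel_zscore_control(p)
  expect_equal(unname(colMeans(z)), rep(0, 40), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 40), tolerance = 1e-12)
  expect_equal(unname(voxel_zscore_control(z)), unname(z), tolerance = 1e-12)
  # per-pattern mean shifts leave Pearson similarity untouched
  q <- named_patterns(matrix(rnorm(8 * 40), 8), "q")
  shifted <- p + rnorm(8) # one constant per pattern row
  expect_equal(unclass(similarity_matrix(shifted, q)),
               unclass(similarity_matrix(p, q)), tolerance = 1e-12)
  # zero-variance voxel dropped with a message
  pz <- p; pz[, 3] <- 5
  expect_message(zz <- voxel_zscore_control(pz), "dropped")
  expect_equal(ncol(zz), 39)
  expect_error(voxel_zscore_control(p[1, , drop = FALSE]), "at least 2")
})

test_that("AB integration fits mirror the C-pair contract", {
  set.seed(17)
  basis <- seqprime:::pair_basis(100)
  pats <- seqprime:::build_pair_patterns(0.5, 100, prefix = c("A", "B"),
                                         basis = basis)
  fit <- ab_integration_fit(pats$first, pats$second)
  expect_gt(fit$r, 0.2) # strong same-pair sharing shows up in the fit
  null <- seqprime:::build_pair_patterns(0, 100, prefix = c("A", "B"))
  fit0 <- ab_integration_fit(null$first, null$second)
  expect_lt(abs(fit0$r), 0.5)
})

test_that("end-to-end: ground-truth patterns and noise-free GLM give identical fits", {
  p <- cohort_params(n_subjects = 1)
  p$patterns$n_voxels <- 40 # small ROI keeps the scan pair cheap
  sets <- two_session_sets()
  ex_orders <- generate_exposure_orders(sets, seed = 19)
  lat <- sample_subject_latents(p, seed = 20)
  expo <- simulate_exposure_data(ex_orders, sets, lat[1, ], p, seed = 21,
                                 rois = "mPFC", mode = "timeseries",
                                 noise_scale = 0)
  est <- estimate_patterns_glm(expo$mPFC, ex_orders, sets, stat = "beta",
                               apply_highpass = FALSE)
  for (ses in names(est)) {
    for (ph in c("pre", "post")) {
      truth <- expo$mPFC$sessions[[ses]][[ph]]$truth
      fit_t <- integration_fit(similarity_matrix(truth$C1, truth$C2))
      fit_e <- integration_fit(similarity_matrix(est[[ses]][[ph]]$C1,
                                                 est[[ses]][[ph]]$C2))
      expect_equal(fit_e$z, fit_t$z, tolerance = 1e-6)
    }
  }
})

test_that("high-pass filtering removes drift while sparing task-band signal", {
  TR <- 2
  n <- 300
  t <- seq_len(n) * TR
  drift <- 3 * sin(2 * pi * 0.002 * t)
  sig <- sin(2 * pi * 0.04 * t)
  filtered <- highpass(rbind(drift + sig), TR)
  expect_lt(sd(filtered[1, ] - sig) / sd(drift), 0.25)
  expect_error(highpass(rbind(sig), TR, cutoff = 0.3), "Nyquist")
})
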