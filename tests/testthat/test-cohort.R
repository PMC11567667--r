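test_that("latent draws reproduce the requested correlation structure", {
  p <- cohort_params()
  p$latent_corr <- diag(3)
  dimnames(p$latent_corr) <- dimnames(cohort_params()$latent_corr)
  lat <- sample_subject_latents(p, seed = 1, n_subjects = 10000)
  cc <- cor(as.matrix(lat[, c("priming", "integration", "coupling")]))
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.03))

  p2 <- cohort_params()
  lat2 <- sample_subject_latents(p2, seed = 2, n_subjects = 10000)
  cc2 <- cor(as.matrix(lat2[, c("priming", "integration", "coupling")]))
  expect_lt(abs(cc2["priming", "integration"] - 0.6), 0.02)
  expect_lt(abs(cc2["priming", "coupling"] - 0.6), 0.02)
  expect_lt(abs(cc2["integration", "coupling"] - 0.4), 0.02)
  # conditioned draws hit the targets exactly
  lat3 <- sample_subject_latents(p2, seed = 3, n_subjects = 200, empirical = TRUE)
  cc3 <- cor(as.matrix(lat3[, c("priming", "integration", "coupling")]))
  expect_equal(unname(cc3), unname(p2$latent_corr), tolerance = 1e-10)

  bad <- cohort_params()
  expect_error({
    bad$latent_corr[1, 2] <- bad$latent_corr[2, 1] <- 1.5
    cohort_params(latent_corr = bad$latent_corr)
  }, "positive definite")
})

test_that("learning RTs follow the closed-form mean curve in the noiseless limit", {
  p <- cohort_params(n_subjects = 2)
  p$learning$rt_noise_sd <- 0
  sets <- two_session_sets()
  orders <- list(remote = generate_learning_order(sets[[1]], seed = 1),
                 recent = generate_learning_order(sets[[2]], seed = 2))
  lat <- sample_subject_latents(p, seed = 3)
  rec <- simulate_learning_rts(orders, lat, p, seed = 4, sets)
  lp <- p$learning
  expected <- exp(log(lp$base_rt_ms) +
                    lp$session_slowdown * (rec$session == "remote") -
                    lp$rep_decay * (rec$repetition - 1) / 15 -
                    lp$pred_extra_decay * (rec$repetition - 1) / 15 *
                      (rec$predictability == "predictable"))
  expect_equal(rec$rt_ms, expected, tolerance = 1e-12)
  # remote slower; predictable faster late in learning
  expect_gt(median(rec$rt_ms[rec$session == "remote"]),
            median(rec$rt_ms[rec$session == "recent"]))
})

test_that("zero facilitation makes predictable and unpredictable RTs identical", {
  p <- cohort_params(n_subjects = 2)
  p$learning$pred_extra_decay <- 0
  p$learning$rt_noise_sd <- 0
  sets <- two_session_sets()
  orders <- list(remote = generate_learning_order(sets[[1]], seed = 1),
                 recent = generate_learning_order(sets[[2]], seed = 2))
  lat <- sample_subject_latents(p, seed = 3)
  rec <- simulate_learning_rts(orders, lat, p, seed = 4, sets)
  agg <- aggregate_learning_rts(rec)
  wide <- reshape(as.data.frame(agg), idvar = c("subject", "session", "repetition"),
                  timevar = "predictability", direction = "wide")
  expect_equal(wide$median_rt.predictable, wide$median_rt.unpredictable,
               tolerance = 1e-12)
})

test_that("recognition simulation ties priming to the latent and hit/FA rates", {
  sets <- two_session_sets()
  ro <- generate_recognition_order(sets, seed = 5)
  p <- cohort_params(n_subjects = 40)
  p$latent_means[] <- c(0, 0, 0)
  p$recognition$hit_rate <- 1; p$recognition$fa_rate <- 0
  lat <- sample_subject_latents(p, seed = 6)
  lat$priming[] <- 0
  rec <- simulate_recognition(ro, lat, p, seed = 7)
  expect_true(all(rec$response[rec$is_old] == "old"))
  expect_true(all(rec$response[!rec$is_old] == "new"))
  sc <- score_priming(rec, ro)
  # all 6 triples eligible per session; expected score 0
  expect_true(all(sc$scores$n_included == 6))
  expect_lt(abs(mean(sc$scores$median_diff_ms)), 5)

  # a nonzero latent shifts remote C2 responses by that amount in expectation
  lat$priming[] <- 80
  rec2 <- simulate_recognition(ro, lat, p, seed = 7)
  sc2 <- score_priming(rec2, ro)
  m <- tapply(sc2$scores$median_diff_ms, sc2$scores$session, mean)
  expect_lt(abs(m[["remote"]] - 80), 10)
  expect_lt(abs(m[["recent"]]), 10)
})

test_that("exposure patterns: equal weights pre/post give exactly zero change", {
  p <- cohort_params(n_subjects = 1)
  p$patterns$est_noise_sd <- 0
  p$patterns$roi_session_effects$delta_mean[] <- 0
  p$patterns$roi_session_effects$delta_sd[] <- 0
  sets <- two_session_sets()
  ex_orders <- generate_exposure_orders(sets, seed = 1)
  lat <- sample_subject_latents(p, seed = 2)
  lat$integration <- 0
  expo <- simulate_exposure_data(ex_orders, sets, lat[1, ], p, seed = 3,
                                 rois = c("mPFC", "LOC"))
  for (roi in names(expo)) {
    for (ses in names(expo[[roi]]$sessions)) {
      dat <- expo[[roi]]$sessions[[ses]]
      fit_pre <- integration_fit(similarity_matrix(dat$pre$est$C1, dat$pre$est$C2))
      fit_post <- integration_fit(similarity_matrix(dat$post$est$C1, dat$post$est$C2))
      expect_equal(change_score(fit_pre, fit_post), 0, tolerance = 1e-12)
    }
  }
})

test_that("a positive weight change raises the integration fit pre to post", {
  p <- cohort_params(n_subjects = 1)
  p$patterns$est_noise_sd <- 0
  sets <- two_session_sets()
  ex_orders <- generate_exposure_orders(sets, seed = 1)
  lat <- sample_subject_latents(p, seed = 2)
  lat$integration <- 0.4 # overlapping pairs gain shared signal after learning
  expo <- simulate_exposure_data(ex_orders, sets, lat[1, ], p, seed = 3,
                                 rois = "mPFC")
  dat <- expo$mPFC$sessions$remote
  fit_pre <- integration_fit(similarity_matrix(dat$pre$est$C1, dat$pre$est$C2))
  fit_post <- integration_fit(similarity_matrix(dat$post$est$C1, dat$post$est$C2))
  expect_gt(change_score(fit_pre, fit_post), 0)
})

test_that("rest simulation recovers injected coupling and band-limits its sources", {
  p <- cohort_params(n_subjects = 1)
  lat <- sample_subject_latents(p, seed = 1)
  lat$coupling <- 0

  # uncoupled, uncontaminated: near-zero correlations
  p0 <- p; p0$rest$baseline_r <- 0
  rest0 <- simulate_rest(lat[1, ], p0, seed = 2, contaminate = FALSE)
  r0 <- cor(roi_mean(rest0$pre$ts$mPFC), roi_mean(rest0$pre$ts$LOC))
  expect_lt(abs(r0), 0.25) # ~180 band-limited volumes: wide null spread

  # injected coupling, long scan: recovered within Monte-Carlo tolerance
  p5 <- p; p5$rest$baseline_r <- 0.5; p5$rest$n_volumes <- 3600
  rest5 <- simulate_rest(lat[1, ], p5, seed = 3, contaminate = FALSE)
  r5 <- cor(roi_mean(rest5$pre$ts$mPFC), roi_mean(rest5$pre$ts$LOC))
  expect_lt(abs(r5 - 0.5), 0.1)

  # shared source is band-limited: <5% of power outside 0.01-0.1 Hz
  set.seed(99)
  x <- seqprime:::band_limited_source(4096, 2)
  pw <- Mod(fft(x))^2
  freq <- seq(0, length(x) - 1) / (length(x) * 2)
  half <- freq <= 0.25
  inband <- half & freq >= 0.0099 & freq <= 0.101
  expect_lt(sum(pw[half & !inband]) / sum(pw[inband]), 0.05)
})

test_that("nuisance contamination biases coupling and regression removes the bias", {
  p <- cohort_params(n_subjects = 1)
  p$rest$baseline_r <- 0.3
  p$rest$n_volumes <- 900 # longer scan to separate bias from sampling noise
  # heavy shared contamination so the uncorrected bias dwarfs sampling noise
  p$rest$motion_amp <- 3; p$rest$tissue_amp <- 3; p$rest$spike_amp <- 8
  lat <- sample_subject_latents(p, seed = 1)
  lat$coupling <- 0
  biases <- sapply(1:6, function(seed) {
    rest <- simulate_rest(lat[1, ], p, seed = 1000 + seed, contaminate = TRUE)
    sc <- rest$pre
    raw <- cor(bandpass(roi_mean(sc$ts$mPFC), sc$TR),
               bandpass(roi_mean(sc$ts$LOC), sc$TR))
    clean <- cor(process_rest_scan(sc$ts$mPFC, sc$nuisance, sc$TR),
                 process_rest_scan(sc$ts$LOC, sc$nuisance, sc$TR))
    c(raw = raw - 0.3, clean = clean - 0.3)
  })
  expect_gt(mean(abs(biases["raw", ])), 2 * mean(abs(biases["clean", ])))
  expect_lt(mean(abs(biases["clean", ])), 0.08)
})

test_that("cohort simulation is deterministic from the master seed", {
  p <- cohort_params(n_subjects = 3)
  a <- simulate_cohort(p, seed = 77, rois = "mPFC")
  b <- simulate_cohort(p, seed = 77, rois = "mPFC")
  expect_identical(a$latents, b$latents)
  expect_identical(a$behavior$recognition, b$behavior$recognition)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$rest$sub001$pre$ts$mPFC, b$rest$sub001$pre$ts$mPFC)
  c2 <- simulate_cohort(p, seed = 78, rois = "mPFC")
  expect_false(identical(a$latents, c2$latents))
})
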