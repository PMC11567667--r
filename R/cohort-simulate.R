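# Synthetic-cohort simulators. Every function is deterministic given
# (params, seed); per-subject substreams come from seed_stream() so single
# subjects can be regenerated in isolation.

#' Simulate trial-level size-judgment RTs during learning
#'
#' Log-normal RTs with multiplicative structure: a global repetition decay,
#' extra decay for predictable roles (B, C1, C2), a remote-session slowdown,
#' and trial noise. Responses slower than the response window are flagged as
#' no-response. Accuracy is generated only for trials whose predecessor
#' occupies the other size bin (the only comparisons with a defined answer).
#'
#' @param orders named list of learning trial orders (`remote`, `recent`).
#' @param latents tibble from [sample_subject_latents()].
#' @param params [cohort_params()].
#' @param seed integer seed.
#' @param seq_sets list of the session sequence sets (for size bins).
#' @return tibble of trial records: subject, session, position, block,
#'   object_id, role, repetition, predictability, rt_ms, no_response,
#'   accuracy (NA when ineligible).
#' @export
simulate_learning_rts <- function(orders, latents, params, seed, seq_sets) {
  lp <- params$learning
  bins <- role_table(seq_sets)
  per_order <- lapply(names(orders), function(ses) {
    o <- as.data.frame(orders[[ses]])
    o$repetition <- learning_repetition(o)
    o$predictability <- label_predictability(o)
    o$size_bin <- bins$size_bin[match(o$object_id, bins$object_id)]
    o$prev_bin <- c(NA, o$size_bin[-nrow(o)])
    o$prev_bin[!duplicated(o$block)] <- NA # block-initial trials have no referent
    o$eligible <- !is.na(o$prev_bin) & o$prev_bin != o$size_bin
    o
  })
  names(per_order) <- names(orders)

  rows <- lapply(seq_len(nrow(latents)), function(i) {
    sub <- latents$subject[i]
    with_seed(seed_stream(seed, paste0("learning_", sub)), {
      do.call(rbind, lapply(names(per_order), function(ses) {
        o <- per_order[[ses]]
        prog <- (o$repetition - 1) / 15
        mu <- log(lp$base_rt_ms) +
          lp$session_slowdown * (ses == "remote") -
          lp$rep_decay * prog -
          lp$pred_extra_decay * prog * (o$predictability == "predictable")
        rt <- exp(mu + stats::rnorm(nrow(o), 0, lp$rt_noise_sd))
        no_resp <- rt > lp$response_window_ms
        p_acc <- pmin(1, lp$accuracy_base +
                        lp$accuracy_pred_gain * prog * (o$predictability == "predictable"))
        acc <- ifelse(o$eligible & !no_resp,
                      stats::rbinom(nrow(o), 1, p_acc), NA_integer_)
        tibble::tibble(subject = sub, session = ses, position = o$position,
                       block = o$block, object_id = o$object_id, role = o$role,
                       repetition = o$repetition,
                       predictability = o$predictability,
                       rt_ms = ifelse(no_resp, NA_real_, rt),
                       no_response = no_resp, accuracy = acc)
      }))
    })
  })
  do.call(rbind, rows)
}

#' Simulate recognition-priming responses
#'
#' Near-ceiling old/new endorsements (configurable hit and false-alarm rates)
#' and log-normal RTs. The subject's priming latent (ms) is subtracted from
#' remote-session C2 trials — the trials primed by their overlapping C1 —
#' and `priming_recent_ms` (default 0) from recent-session C2 trials.
#'
#' @param trial_order recognition trial order.
#' @param latents tibble from [sample_subject_latents()].
#' @param params [cohort_params()].
#' @param seed integer seed.
#' @return tibble: subject, position, object_id, role, session, rt_ms,
#'   response, is_old.
#' @export
simulate_recognition <- function(trial_order, latents, params, seed) {
  rp <- params$recognition
  o <- as.data.frame(trial_order)
  is_old <- o$role != "foil"
  rows <- lapply(seq_len(nrow(latents)), function(i) {
    sub <- latents$subject[i]
    with_seed(seed_stream(seed, paste0("recognition_", sub)), {
      p_old <- ifelse(is_old, rp$hit_rate, rp$fa_rate)
      resp <- ifelse(stats::runif(nrow(o)) < p_old, "old", "new")
      facil <- ifelse(o$role == "C2" & o$session == "remote",
                      latents$priming[i],
                      ifelse(o$role == "C2" & o$session == "recent",
                             rp$priming_recent_ms, 0))
      facil[is.na(facil)] <- 0
      rt <- rp$base_rt_ms * exp(stats::rnorm(nrow(o), 0, rp$rt_noise_sd)) - facil
      tibble::tibble(subject = sub, position = o$position,
                     object_id = o$object_id, role = o$role,
                     session = o$session, rt_ms = pmax(rt, 150),
                     response = resp, is_old = is_old)
    })
  })
  do.call(rbind, rows)
}

#' Simulate explicit-integration responses
#'
#' Experiment 2 (2AFC): per-subject correct-choice probability drawn around
#' `p_correct` on the logit scale. Experiment 1 (ratings): intact pairs gain
#' `rating_effect_C` / `rating_effect_AB` over re-arranged ones, with
#' truncation to the 0-1 rating scale; baseline pairs sit at the scale floor
#' region.
#'
#' @param trials [generate_explicit_trials()] output.
#' @param latents subject table.
#' @param params [cohort_params()].
#' @param seed integer seed.
#' @param experiment 1 or 2 (must match how `trials` was generated).
#' @return tibble of records suitable for [score_explicit()].
#' @export
simulate_explicit <- function(trials, latents, params, seed, experiment = 2) {
  ep <- params$explicit
  tr <- as.data.frame(trials)
  rows <- lapply(seq_len(nrow(latents)), function(i) {
    sub <- latents$subject[i]
    with_seed(seed_stream(seed, paste0("explicit_", sub)), {
      if (experiment == 2) {
        p_sub <- stats::plogis(stats::qlogis(ep$p_correct) +
                                 stats::rnorm(1, 0, ep$subject_logit_sd))
        tibble::tibble(subject = sub, session = tr$session,
                       test_block = tr$test_block,
                       sequence_id = tr$sequence_id,
                       correct = stats::runif(nrow(tr)) < p_sub)
      } else {
        eff <- ifelse(grepl("^AB", tr$pair_type), ep$rating_effect_AB,
                      ifelse(grepl("^C", tr$pair_type), ep$rating_effect_C, 0))
        intact <- grepl("intact$", tr$pair_type)
        mu <- 0.35 + eff * intact
        tibble::tibble(subject = sub, session = tr$session,
                       pair_type = tr$pair_type,
                       rating = pmin(1, pmax(0, mu + stats::rnorm(nrow(tr), 0,
                                                                  ep$rating_noise_sd))))
      }
    })
  })
  do.call(rbind, rows)
}

# same-pair pattern correlation targets for one subject x roi x session:
# z_post = z_pre + delta, where delta is the integration latent for
# mPFC/remote C pairs and a subject draw from roi_session_effects otherwise.
pair_correlation_targets <- function(latents_row, params, roi, session,
                                     pair_class, rng_delta) {
  rho_pre <- params$patterns$rho_same_pre
  z_pre <- atanh(rho_pre)
  if (roi == "mPFC" && session == "remote" && pair_class == "C") {
    delta <- latents_row$integration
  } else {
    eff <- params$patterns$roi_session_effects
    hit <- eff[eff$roi == roi & eff$session == session &
                 eff$pair_class == pair_class, ]
    delta <- if (nrow(hit) == 1) rng_delta(hit$delta_mean, hit$delta_sd) else 0
  }
  c(pre = rho_pre, post = tanh(z_pre + delta))
}

# random basis for a set of object pairs: idiosyncratic components u1/u2 and
# the pair-shared component g. The basis is drawn once per ROI x session so
# object representations persist across the pre/post phases; only the shared
# -component weight changes between phases.
pair_basis <- function(n_voxels, n_pairs = 6) {
  list(u1 = matrix(stats::rnorm(n_pairs * n_voxels), n_pairs),
       u2 = matrix(stats::rnorm(n_pairs * n_voxels), n_pairs),
       g = matrix(stats::rnorm(n_pairs * n_voxels), n_pairs))
}

# build 6 first-member + 6 second-member patterns with the requested
# same-pair correlation rho (signed shared component); a fresh basis is drawn
# unless one is supplied
build_pair_patterns <- function(rho, n_voxels, n_pairs = 6,
                                prefix = c("C1", "C2"), basis = NULL) {
  if (is.null(basis)) basis <- pair_basis(n_voxels, n_pairs)
  a <- sqrt(abs(rho) / (1 - abs(rho)))
  p1 <- basis$u1 + a * basis$g
  p2 <- basis$u2 + sign(rho) * a * basis$g
  rownames(p1) <- paste0(prefix[1], "_", seq_len(n_pairs))
  rownames(p2) <- paste0(prefix[2], "_", seq_len(n_pairs))
  list(first = p1, second = p2)
}

#' Simulate exposure-scan data for one subject
#'
#' Generates, for each requested ROI and session, the ground-truth object
#' patterns for both exposure phases — overlapping pairs share a common
#' component whose pre-to-post change is set by the subject's integration
#' latent (mPFC, remote, C pairs) or by the configured ROI/session effects —
#' and either (a) `mode = "patterns"`: estimated patterns (truth plus
#' independent estimation noise, emulating GLM output) or (b)
#' `mode = "timeseries"`: full voxel-by-volume scans built by convolving each
#' object's event train with the double-gamma HRF weighted by its pattern,
#' plus Gaussian noise and slow drift, for the single-trial GLM to estimate.
#'
#' @param orders list with `scan1`, `scan2` exposure trial orders (reused
#'   verbatim for both phases).
#' @param seq_sets list of session sequence sets.
#' @param latents_row one row of the latents tibble.
#' @param params [cohort_params()].
#' @param seed integer seed (already subject-specific).
#' @param rois ROIs to simulate.
#' @param mode `"patterns"` or `"timeseries"`.
#' @param noise_scale multiplier on estimation/scan noise (0 = noise-free).
#' @return nested list per ROI: `sessions[[session]][[phase]]` holds `truth`
#'   and (patterns mode) `est` — each a list of C1/C2/A/B pattern matrices
#'   (rows in sequence order); timeseries mode adds `scans[[phase]][[scan]]`
#'   (voxels x volumes, shared across sessions), `n_volumes`, `TR`.
#' @export
simulate_exposure_data <- function(orders, seq_sets, latents_row, params, seed,
                                   rois = params$rois,
                                   mode = c("patterns", "timeseries"),
                                   noise_scale = 1) {
  mode <- match.arg(mode)
  pp <- params$patterns
  TR <- 2
  sessions <- vapply(seq_sets, function(s) s$session, character(1))
  out <- list()
  for (roi in rois) {
    out[[roi]] <- list(sessions = list())
    for (si in seq_along(sessions)) {
      ses <- sessions[si]
      sd_seed <- seed_stream(seed, paste("expo", roi, ses, sep = "_"))
      out[[roi]]$sessions[[ses]] <- with_seed(sd_seed, {
        rng_delta <- function(m, s) stats::rnorm(1, m, s)
        rho_C <- pair_correlation_targets(latents_row, params, roi, ses, "C", rng_delta)
        rho_AB <- pair_correlation_targets(latents_row, params, roi, ses, "AB", rng_delta)
        basis_C <- pair_basis(pp$n_voxels)
        basis_AB <- pair_basis(pp$n_voxels)
        phases <- list()
        for (ph in c("pre", "post")) {
          cpat <- build_pair_patterns(rho_C[[ph]], pp$n_voxels, prefix = c("C1", "C2"),
                                      basis = basis_C)
          abpat <- build_pair_patterns(rho_AB[[ph]], pp$n_voxels, prefix = c("A", "B"),
                                       basis = basis_AB)
          truth <- list(C1 = cpat$first, C2 = cpat$second,
                        A = abpat$first, B = abpat$second)
          if (mode == "patterns") {
            est <- lapply(truth, function(m)
              m + matrix(stats::rnorm(length(m), 0,
                                      pp$est_noise_sd * noise_scale), nrow(m)))
            phases[[ph]] <- list(truth = truth, est = est)
          } else {
            phases[[ph]] <- list(truth = truth)
          }
        }
        phases
      })
    }
  }
  if (mode == "timeseries") {
    # voxel time series mix both sessions' objects within a scan; build per
    # roi x phase x scan from the union of this subject's true patterns
    spec <- hrf_spec()
    for (roi in rois) {
      out[[roi]]$scans <- list(pre = list(), post = list())
      for (ph in c("pre", "post")) {
        for (sc in c("scan1", "scan2")) {
          ord <- orders[[sc]]
          n_volumes <- ceiling((max(ord$onset + ord$duration) + 20) / TR)
          des <- build_design_matrix(ord, n_volumes, TR, spec)
          B <- matrix(0, ncol(des$X), pp$n_voxels)
          for (si in seq_along(sessions)) {
            ses <- sessions[si]
            truth <- out[[roi]]$sessions[[ses]][[ph]]$truth
            sq <- seq_sets[[si]]$sequences
            obj_of <- list(C1 = sq$C1, C2 = sq$C2, A = sq$A, B = sq$B)
            for (role in names(truth)) {
              ids <- obj_of[[role]]
              for (j in seq_along(ids)) {
                col <- which(names(des$object_cols) == ids[j])
                if (length(col) == 1) {
                  B[des$object_cols[col], ] <- truth[[role]][j, ]
                }
              }
            }
          }
          B[nrow(B), ] <- pp$baseline_signal # intercept row
          ts_seed <- seed_stream(seed, paste("expots", roi, ph, sc, sep = "_"))
          Y <- with_seed(ts_seed, {
            sig <- des$X %*% B
            if (noise_scale > 0) {
              drift <- outer(cos(pi * seq_len(n_volumes) / n_volumes),
                             stats::rnorm(pp$n_voxels, 0, pp$drift_amp * noise_scale))
              sig <- sig + drift +
                matrix(stats::rnorm(length(sig), 0, pp$glm_noise_sd * noise_scale),
                       nrow(sig))
            }
            t(sig) # voxels x volumes
          })
          out[[roi]]$scans[[ph]][[sc]] <- Y
          out[[roi]]$n_volumes[[sc]] <- n_volumes
        }
      }
      out[[roi]]$TR <- TR
    }
  }
  out
}

# smoothed random-walk motion parameters, spike indicators, tissue signals
make_nuisance_table <- function(n_volumes, spike_rate) {
  mot <- vapply(1:6, function(j) {
    v <- cumsum(stats::rnorm(n_volumes, 0, 0.05))
    stats::filter(v, rep(1 / 5, 5), sides = 2, circular = TRUE)
  }, numeric(n_volumes))
  colnames(mot) <- paste0("mot", 1:6)
  tibble::tibble(as.data.frame(mot),
                 spike = as.integer(stats::runif(n_volumes) < spike_rate),
                 wm = as.numeric(stats::filter(stats::rnorm(n_volumes), rep(1 / 8, 8),
                                               sides = 2, circular = TRUE)),
                 csf = as.numeric(stats::filter(stats::rnorm(n_volumes), rep(1 / 8, 8),
                                                sides = 2, circular = TRUE)))
}

# band-limited unit-variance source: white noise through the zero-phase
# band-pass twice (a single second-order pass leaves ~5% out-of-band power;
# the repeated pass steepens the rolloff), edges trimmed, restandardized
band_limited_source <- function(n_volumes, TR, low = 0.01, high = 0.1) {
  x <- bandpass(bandpass(stats::rnorm(n_volumes * 3), TR, low, high),
                TR, low, high)
  x <- x[n_volumes + seq_len(n_volumes)] # drop filter edges
  (x - mean(x)) / stats::sd(x)
}

#' Simulate the three resting-state scans for one subject
#'
#' Each ROI's signal is a mixture of band-limited (0.01-0.1 Hz) sources whose
#' mixing reproduces a target inter-ROI correlation matrix: `baseline_r`
#' everywhere, with the posterior-hippocampus/LOC coupling in the post-remote
#' scan raised (on the Fisher-z scale) by the subject's coupling latent, and
#' any configured non-latent scan/pair effects applied the same way. Voxel
#' data add white voxel noise plus shared nuisance contamination (motion,
#' spikes, tissue signals, linear drift) built from the returned nuisance
#' table, so nuisance regression can remove it exactly.
#'
#' @param latents_row one row of the latents tibble.
#' @param params [cohort_params()].
#' @param seed integer seed (already subject-specific).
#' @param contaminate add nuisance contamination (default TRUE).
#' @return list per scan (`pre`, `post_remote`, `post_recent`): `ts` (list of
#'   voxels x volumes matrices per ROI), `nuisance` (tibble), `target`
#'   (the generating correlation matrix), `TR`.
#' @export
simulate_rest <- function(latents_row, params, seed, contaminate = TRUE) {
  rp <- params$rest
  rois <- params$rois
  k <- length(rois)
  scans <- c("pre", "post_remote", "post_recent")
  z_base <- atanh(rp$baseline_r)

  target_matrix <- function(scan) {
    Z <- matrix(z_base, k, k, dimnames = list(rois, rois))
    eff <- rp$effects[rp$effects$scan == scan, ]
    apply_delta <- function(Z, pair, delta) {
      ab <- strsplit(pair, "-")[[1]]
      Z[ab[1], ab[2]] <- Z[ab[2], ab[1]] <- Z[ab[1], ab[2]] + delta
      Z
    }
    if (scan == "post_remote") {
      Z <- apply_delta(Z, "postHPC-LOC", latents_row$coupling)
    }
    if (nrow(eff) > 0) {
      for (i in seq_len(nrow(eff))) {
        d_seed <- seed_stream(seed, paste("resteff", scan, eff$pair[i], sep = "_"))
        delta <- with_seed(d_seed, stats::rnorm(1, eff$delta_mean[i], eff$delta_sd[i]))
        Z <- apply_delta(Z, eff$pair[i], delta)
      }
    }
    R <- tanh(Z); diag(R) <- 1
    # guard positive definiteness (large latent draws can break it)
    ev <- eigen(R, symmetric = TRUE)
    if (any(ev$values < 1e-6)) {
      v <- pmax(ev$values, 1e-6)
      R <- ev$vectors %*% diag(v) %*% t(ev$vectors)
      R <- stats::cov2cor(R)
      dimnames(R) <- list(rois, rois)
    }
    R
  }

  out <- list()
  for (scan in scans) {
    sc_seed <- seed_stream(seed, paste0("rest_", scan))
    out[[scan]] <- with_seed(sc_seed, {
      R <- target_matrix(scan)
      S <- t(vapply(seq_len(k), function(i)
        band_limited_source(rp$n_volumes, rp$TR), numeric(rp$n_volumes)))
      courses <- t(chol(R)) %*% S # k x volumes with cor ~ R
      nuis <- make_nuisance_table(rp$n_volumes, rp$spike_rate)
      ts <- list()
      for (i in seq_len(k)) {
        vox <- matrix(rep(courses[i, ], each = rp$n_voxels), rp$n_voxels) +
          matrix(stats::rnorm(rp$n_voxels * rp$n_volumes, 0, rp$voxel_noise_sd),
                 rp$n_voxels)
        if (contaminate) {
          art <- rp$motion_amp * as.matrix(nuis[, paste0("mot", 1:6)]) %*%
            stats::rnorm(6) +
            rp$spike_amp * nuis$spike * stats::rnorm(1) +
            rp$tissue_amp * (nuis$wm + nuis$csf) / 2 +
            rp$drift_amp * seq(-1, 1, length.out = rp$n_volumes)
          vox <- vox + matrix(rep(as.numeric(art), each = rp$n_voxels), rp$n_voxels)
        }
        ts[[rois[i]]] <- vox
      }
      list(ts = ts, nuisance = nuis, target = R, TR = rp$TR)
    })
  }
  out
}
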