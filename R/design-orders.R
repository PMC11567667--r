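# Trial orders are tibbles with one row per stimulus event:
#   phase, block, position, onset, duration, iti, object_id, role,
#   sequence_id, session, target_flag
# Onsets increase strictly; onset[i+1] = onset[i] + duration[i] + iti[i].

new_trial_order <- function(df, phase) {
  df$phase <- phase
  df$position <- seq_len(nrow(df))
  need <- c("phase", "block", "position", "onset", "duration", "iti",
            "object_id", "role", "sequence_id", "session", "target_flag")
  tibble::as_tibble(df[, need])
}

# lay out onsets from durations and ITIs
layout_onsets <- function(df) {
  n <- nrow(df)
  df$onset <- c(0, cumsum(df$duration[-n] + df$iti[-n]))
  df
}

# Sequentially build an order over token types with a no-adjacency predicate.
# Restarting construction is the rejection-sampling engine: a dead end or an
# unsatisfiable draw discards the attempt and costs one of `max_attempts`.
sample_no_adjacent <- function(types, counts, conflict, max_attempts = 10000,
                               first_forbidden = NULL) {
  total <- sum(counts)
  for (attempt in seq_len(max_attempts)) {
    rem <- counts
    out <- integer(total)
    prev <- 0L
    ok <- TRUE
    for (i in seq_len(total)) {
      cand <- which(rem > 0L)
      if (i == 1L && !is.null(first_forbidden)) {
        cand <- cand[!conflict(first_forbidden, cand)]
      } else if (i > 1L) {
        cand <- cand[!conflict(prev, cand)]
      }
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L, prob = rem[cand])]
      out[i] <- pick
      rem[pick] <- rem[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("pseudo-randomization failed: no-adjacency constraint unsatisfiable after ",
       max_attempts, " attempts")
}

#' Generate a pseudo-randomized learning order
#'
#' Emits one session's sequence-learning order: each of the 12 triplet variants
#' (6 sequences x C1/C2) appears `n_reps` times, split evenly over `n_blocks`
#' blocks, with baseline objects occupying inter-triplet gaps. Constraints:
#' no two consecutive triplets share an A/B stem (including across block
#' boundaries); baselines are never adjacent to one another and are always
#' immediately followed by an A; within each block every variant and every
#' baseline object appears `n_reps / n_blocks` times.
#'
#' @param seq_set a [build_sequence_set()] result.
#' @param n_reps presentations per triplet variant (default 16, so A/B are seen
#'   32 times and each C 16 times).
#' @param n_blocks number of blocks; must divide `n_reps`.
#' @param seed integer seed.
#' @param baseline_reps presentations per baseline object (default `n_reps`);
#'   0 drops baselines entirely.
#' @param iti_pool ITIs sampled uniformly per trial, seconds.
#' @param max_attempts rejection-sampling budget per block.
#' @return trial-order tibble (stimulus duration 2 s).
#' @export
generate_learning_order <- function(seq_set, n_reps = 16, n_blocks = 4, seed,
                                    baseline_reps = n_reps,
                                    iti_pool = 0:4, max_attempts = 10000) {
  stopifnot(inherits(seq_set, "sequence_set"))
  if (n_reps %% n_blocks != 0) stop("n_reps must be divisible by n_blocks")
  if (baseline_reps %% n_blocks != 0) stop("baseline_reps must be divisible by n_blocks")
  per_block <- n_reps / n_blocks
  sq <- seq_set$sequences
  n_seq <- nrow(sq)
  variants <- expand.grid(sequence_id = seq_len(n_seq), c_role = c("C1", "C2"),
                          stringsAsFactors = FALSE)
  base_ids <- seq_set$objects$object_id[seq_set$objects$role == "baseline"]
  base_per_block <- baseline_reps / n_blocks
  n_trip_block <- nrow(variants) * per_block
  n_base_block <- length(base_ids) * base_per_block
  if (n_base_block > n_trip_block) {
    stop("more baseline presentations than inter-triplet gaps per block")
  }
  conflict <- function(prev, cand) variants$sequence_id[cand] == variants$sequence_id[prev]

  with_seed(seed, {
    rows <- list()
    prev_last <- NULL
    for (blk in seq_len(n_blocks)) {
      idx <- sample_no_adjacent(seq_len(nrow(variants)),
                                rep(per_block, nrow(variants)),
                                conflict, max_attempts,
                                first_forbidden = prev_last)
      prev_last <- idx[length(idx)]
      gaps <- if (n_base_block > 0) sort(sample.int(n_trip_block, n_base_block)) else integer(0)
      base_tokens <- if (n_base_block > 0) sample(rep(base_ids, base_per_block)) else character(0)
      gb <- 0L
      for (t in seq_along(idx)) {
        if (t %in% gaps) {
          gb <- gb + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            block = blk, object_id = base_tokens[gb], role = "baseline",
            sequence_id = NA_integer_)
        }
        v <- variants[idx[t], ]
        s <- sq[sq$sequence_id == v$sequence_id, ]
        c_obj <- if (v$c_role == "C1") s$C1 else s$C2
        rows[[length(rows) + 1L]] <- data.frame(
          block = blk,
          object_id = c(s$A, s$B, c_obj),
          role = c("A", "B", v$c_role),
          sequence_id = v$sequence_id)
      }
    }
    df <- do.call(rbind, rows)
    df$session <- seq_set$session
    df$duration <- 2
    df$iti <- sample(iti_pool, nrow(df), replace = TRUE)
    df$target_flag <- FALSE
    df <- layout_onsets(df)
    new_trial_order(df, "learning")
  })
}

#' Generate the recognition-priming test order
#'
#' All old objects from both sessions plus novel foils, each shown once
#' (duration 2 s, fixed 1 s ITI). Structural constraints: for every sequence a
#' contiguous (same-session baseline, C1, C2) triple; every B immediately
#' follows its own A; and no triple directly follows another triple (so a C2 is
#' never immediately followed by a baseline object, matching the design's
#' transition table). Remaining placement is pseudo-random.
#'
#' @param seq_sets list of the two session [build_sequence_set()] results (one
#'   is also accepted).
#' @param n_foils number of novel foils interleaved.
#' @param seed integer seed.
#' @param foil_pool tibble with `object_id` for foils; defaults to generated
#'   identifiers.
#' @param max_attempts rejection-sampling budget.
#' @return trial-order tibble.
#' @export
generate_recognition_order <- function(seq_sets, n_foils = 40, seed,
                                       foil_pool = NULL, max_attempts = 10000) {
  if (inherits(seq_sets, "sequence_set")) seq_sets <- list(seq_sets)
  if (is.null(foil_pool)) {
    foil_pool <- tibble::tibble(object_id = sprintf("foil%03d", seq_len(n_foils)))
  }
  if (nrow(foil_pool) < n_foils) stop("foil pool smaller than n_foils")

  with_seed(seed, {
    units <- list()
    for (s in seq_sets) {
      sq <- s$sequences
      base_ids <- sample(s$objects$object_id[s$objects$role == "baseline"])
      if (length(base_ids) < nrow(sq)) {
        stop("need one same-session baseline object per sequence for the triples")
      }
      for (j in seq_len(nrow(sq))) {
        r <- sq[j, ]
        units[[length(units) + 1L]] <- data.frame(
          object_id = c(base_ids[j], r$C1, r$C2),
          role = c("baseline", "C1", "C2"),
          sequence_id = c(NA_integer_, r$sequence_id, r$sequence_id),
          session = s$session, kind = "triple")
        units[[length(units) + 1L]] <- data.frame(
          object_id = c(r$A, r$B), role = c("A", "B"),
          sequence_id = r$sequence_id, session = s$session, kind = "pair")
      }
    }
    foils <- foil_pool$object_id[seq_len(n_foils)]
    for (f in foils) {
      units[[length(units) + 1L]] <- data.frame(
        object_id = f, role = "foil", sequence_id = NA_integer_,
        session = NA_character_, kind = "foil")
    }
    is_triple <- vapply(units, function(u) u$kind[1] == "triple", logical(1))
    ord <- NULL
    for (attempt in seq_len(max_attempts)) {
      perm <- sample.int(length(units))
      adj <- is_triple[perm][-1] & is_triple[perm][-length(perm)]
      if (!any(adj)) { ord <- perm; break }
    }
    if (is.null(ord)) {
      stop("recognition order: triple-adjacency constraint unsatisfiable after ",
           max_attempts, " attempts")
    }
    df <- do.call(rbind, units[ord])
    df$kind <- NULL
    df$block <- 1L
    df$duration <- 2
    df$iti <- 1
    df$target_flag <- FALSE
    df <- layout_onsets(df)
    new_trial_order(df, "recognition")
  })
}

#' Generate the pre/post exposure-scan orders
#'
#' Splits the 60 session objects over two scans — scan 1: all A, all C1, half
#' the baseline objects; scan 2: all B, all C2, the other half — so an
#' overlapping C1/C2 (or A/B) pair never shares a scan. Each object appears
#' `n_presentations` times with no back-to-back repeats; `n_targets` objects
#' (sampled across both scans) get one extra presentation, and exactly one of
#' their presentations carries `target_flag = TRUE` (the pound-sign trial,
#' which downstream pattern analyses drop). The same orders serve the pre- and
#' post-learning phases verbatim.
#'
#' @param seq_sets list of the two session sequence sets.
#' @param n_presentations baseline presentation count per object.
#' @param n_targets number of pound-sign objects across both scans.
#' @param seed integer seed.
#' @param iti_pool ITIs sampled uniformly per trial, seconds.
#' @param max_attempts rejection-sampling budget per scan.
#' @return list with trial-order tibbles `scan1` and `scan2`.
#' @export
generate_exposure_orders <- function(seq_sets, n_presentations = 4,
                                     n_targets = 20, seed,
                                     iti_pool = 2:5, max_attempts = 10000) {
  if (inherits(seq_sets, "sequence_set")) seq_sets <- list(seq_sets)
  roles <- role_table(seq_sets)

  with_seed(seed, {
    scan_members <- list(`1` = NULL, `2` = NULL)
    for (s in seq_sets) {
      obj <- s$objects
      base_ids <- sample(obj$object_id[obj$role == "baseline"])
      half <- length(base_ids) %/% 2
      scan_members[["1"]] <- rbind(
        scan_members[["1"]],
        obj[obj$role %in% c("A", "C1"), ],
        obj[obj$object_id %in% base_ids[seq_len(half)], ])
      scan_members[["2"]] <- rbind(
        scan_members[["2"]],
        obj[obj$role %in% c("B", "C2"), ],
        obj[obj$object_id %in% base_ids[-seq_len(half)], ])
    }
    all_ids <- c(scan_members[["1"]]$object_id, scan_members[["2"]]$object_id)
    targets <- if (n_targets > 0) sample(all_ids, n_targets) else character(0)

    build_scan <- function(members, scan_idx) {
      counts <- rep(n_presentations, nrow(members))
      counts[members$object_id %in% targets] <- n_presentations + 1L
      idx <- sample_no_adjacent(seq_len(nrow(members)), counts,
                                conflict = function(prev, cand) cand == prev,
                                max_attempts = max_attempts)
      df <- members[idx, c("object_id", "role", "sequence_id", "session")]
      df$block <- scan_idx
      df$duration <- 2
      df$iti <- sample(iti_pool, nrow(df), replace = TRUE)
      df$target_flag <- FALSE
      # one pound-sign presentation per target object
      for (tid in intersect(targets, members$object_id)) {
        pres <- which(df$object_id == tid)
        df$target_flag[pres[sample.int(length(pres), 1)]] <- TRUE
      }
      df <- layout_onsets(df)
      new_trial_order(df, paste0("exposure_scan", scan_idx))
    }
    list(scan1 = build_scan(scan_members[["1"]], 1L),
         scan2 = build_scan(scan_members[["2"]], 2L))
  })
}

#' Generate the explicit-integration test trials
#'
#' Experiment 1 is a familiarity-rating task over 60 pairs: 12 intact AB, 12
#' re-arranged AB, 12 intact C (C1 with its overlapping C2), 12 re-arranged C,
#' and 12 random baseline pairings; every sequence object appears once intact
#' and once re-arranged (re-arrangement is a within-session derangement).
#' Experiment 2 is a two-alternative forced choice: a cue object with the true
#' associate and a foil drawn from a different same-session sequence, in
#' separate AB and C blocks, cueing each pair from both sides.
#'
#' @param seq_sets list of the two session sequence sets.
#' @param experiment 1 (rating pairs) or 2 (2AFC).
#' @param seed integer seed.
#' @return tibble of trials; Experiment 1 rows have `pair_type`, `left_object`,
#'   `right_object`; Experiment 2 rows have `test_block`, `cue_object`,
#'   `target_object`, `foil_object` (4 s trials).
#' @export
generate_explicit_trials <- function(seq_sets, experiment = 1, seed) {
  if (inherits(seq_sets, "sequence_set")) seq_sets <- list(seq_sets)
  stopifnot(experiment %in% c(1, 2))

  derange <- function(n) {
    if (n < 2) stop("re-arranged/foil pairs need at least 2 sequences per session")
    repeat {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) return(p)
    }
  }

  with_seed(seed, {
    if (experiment == 1) {
      rows <- list()
      for (s in seq_sets) {
        sq <- s$sequences
        n <- nrow(sq)
        pb <- derange(n) # B re-pairing
        pc <- derange(n) # C2 re-pairing
        rows[[length(rows) + 1L]] <- data.frame(
          pair_type = rep(c("AB_intact", "AB_rearranged", "C_intact", "C_rearranged"),
                          each = n),
          left_object = c(sq$A, sq$A, sq$C1, sq$C1),
          right_object = c(sq$B, sq$B[pb], sq$C2, sq$C2[pc]),
          sequence_id = rep(sq$sequence_id, 4),
          session = s$session)
        base_ids <- s$objects$object_id[s$objects$role == "baseline"]
        pair_up <- function() {
          ids <- sample(base_ids)
          data.frame(pair_type = "baseline",
                     left_object = ids[seq(1, length(ids), by = 2)],
                     right_object = ids[seq(2, length(ids), by = 2)],
                     sequence_id = NA_integer_, session = s$session)
        }
        rows[[length(rows) + 1L]] <- rbind(pair_up(), pair_up())
      }
      df <- do.call(rbind, rows)
      df <- df[sample.int(nrow(df)), ]
      df$trial <- seq_len(nrow(df))
      df$duration <- 6
      df$iti <- stats::runif(nrow(df), 0.5, 1.5)
      tibble::as_tibble(df[, c("trial", "pair_type", "left_object", "right_object",
                               "sequence_id", "session", "duration", "iti")])
    } else {
      rows <- list()
      for (s in seq_sets) {
        sq <- s$sequences
        n <- nrow(sq)
        for (blk in c("AB", "C")) {
          first <- if (blk == "AB") sq$A else sq$C1
          second <- if (blk == "AB") sq$B else sq$C2
          pf <- derange(n)
          # cue the first member, choose among second members
          rows[[length(rows) + 1L]] <- data.frame(
            test_block = blk, cue_object = first, cue_role = if (blk == "AB") "A" else "C1",
            target_object = second, foil_object = second[pf],
            sequence_id = sq$sequence_id, session = s$session)
          pf2 <- derange(n)
          rows[[length(rows) + 1L]] <- data.frame(
            test_block = blk, cue_object = second, cue_role = if (blk == "AB") "B" else "C2",
            target_object = first, foil_object = first[pf2],
            sequence_id = sq$sequence_id, session = s$session)
        }
      }
      df <- do.call(rbind, rows)
      # shuffle within test block (AB scan precedes C scan)
      df <- do.call(rbind, lapply(split(df, factor(df$test_block, c("AB", "C"))),
                                  function(d) d[sample.int(nrow(d)), ]))
      df$trial <- seq_len(nrow(df))
      df$duration <- 4
      df$iti <- sample(3:8, nrow(df), replace = TRUE)
      tibble::as_tibble(df[, c("trial", "test_block", "cue_object", "cue_role",
                               "target_object", "foil_object", "sequence_id",
                               "session", "duration", "iti")])
    }
  })
}

#' Write a trial order as a BIDS-style events table
#' @param order trial-order tibble.
#' @param path output TSV path.
#' @export
write_events_tsv <- function(order, path) {
  out <- order
  out$trial_type <- out$role
  cols <- c("onset", "duration", "trial_type", "object_id", "role",
            "sequence_id", "session", "block", "target_flag", "iti", "phase")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events table written by [write_events_tsv()]
#' @param path TSV path.
#' @return trial-order tibble.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  df$target_flag <- as.logical(df$target_flag)
  new_trial_order(df, df$phase[1])
}
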