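test_that("sequence sets satisfy role counts, bin constraints and determinism", {
  pool <- default_pool()
  ss <- build_sequence_set("remote", pool[1:30, ], seed = 3)
  obj <- ss$objects
  expect_equal(nrow(obj), 30)
  expect_equal(as.vector(table(obj$role)[c("A", "B", "C1", "C2", "baseline")]),
               rep(6L, 5))
  expect_equal(length(unique(obj$object_id)), 30)
  # C1/C2 share a bin that differs from B's; half the sequences have big Cs
  sq <- ss$sequences
  bin <- function(id) obj$size_bin[match(id, obj$object_id)]
  for (j in seq_len(nrow(sq))) {
    expect_equal(bin(sq$C1[j]), bin(sq$C2[j]))
    expect_false(bin(sq$C1[j]) == bin(sq$B[j]))
  }
  expect_equal(sum(sq$c_bin == "big"), 3)

  ss2 <- build_sequence_set("remote", pool[1:30, ], seed = 3)
  expect_identical(ss, ss2)
  ss3 <- build_sequence_set("remote", pool[1:30, ], seed = 4)
  expect_false(identical(ss$sequences, ss3$sequences))
})

test_that("deficient object pools are rejected with an informative error", {
  pool <- default_pool()
  expect_error(build_sequence_set("remote", pool[1:29, ], seed = 1),
               "too small")
  skew <- pool[1:30, ]
  skew$size_bin <- c(rep("big", 26), rep("small", 4))
  expect_error(build_sequence_set("remote", skew, seed = 1), "small")
})

test_that("learning orders satisfy all structural constraints", {
  ss <- two_session_sets()[[1]]
  lo <- generate_learning_order(ss, seed = 5)
  expect_equal(nrow(lo), 672) # 192 triplets x 3 + 96 baselines
  counts <- table(lo$role)
  expect_equal(as.vector(counts[c("A", "B")]), c(192L, 192L))
  expect_equal(as.vector(counts[c("C1", "C2", "baseline")]), c(96L, 96L, 96L))
  per_obj <- table(lo$object_id, lo$role)
  expect_true(all(rowSums(per_obj)[colnames(per_obj) != ""] %in% c(16, 32)))
  a_ids <- ss$sequences$A
  expect_true(all(table(lo$object_id[lo$role == "A"]) == 32))
  expect_true(all(table(lo$object_id[lo$role == "C1"]) == 16))
  expect_true(all(table(lo$object_id[lo$role == "baseline"]) == 16))

  # per block: each of the 12 variants 4 times, each baseline object 4 times
  for (blk in unique(lo$block)) {
    b <- lo[lo$block == blk, ]
    cvar <- paste(b$sequence_id[b$role %in% c("C1", "C2")],
                  b$role[b$role %in% c("C1", "C2")])
    expect_true(all(table(cvar) == 4))
    expect_true(all(table(b$object_id[b$role == "baseline"]) == 4))
  }

  # exhaustive adjacency scan: A always followed by its own B; B by its own
  # C (half C1, half C2); baselines always followed by an A, never adjacent
  n <- nrow(lo)
  for (i in which(lo$role == "A")) {
    expect_identical(lo$role[i + 1], "B")
    expect_equal(lo$sequence_id[i + 1], lo$sequence_id[i])
  }
  b_next <- lo$role[which(lo$role == "B") + 1]
  expect_true(all(b_next %in% c("C1", "C2")))
  base_next <- lo$role[which(lo$role == "baseline") + 1]
  expect_true(all(base_next == "A"))
  # no two consecutive triplets share an A/B stem
  trip_seq <- lo$sequence_id[lo$role == "A"]
  expect_true(all(trip_seq[-1] != trip_seq[-length(trip_seq)]))
  # per-sequence C1/C2 balance: each C follows its B in half the presentations
  for (j in ss$sequences$sequence_id) {
    expect_equal(sum(lo$role == "C1" & lo$sequence_id == j), 16)
    expect_equal(sum(lo$role == "C2" & lo$sequence_id == j), 16)
  }
  # onsets follow the stated recursion
  expect_true(all(diff(lo$onset) > 0))
  expect_equal(lo$onset[-1], (lo$onset + lo$duration + lo$iti)[-n])
})

test_that("small learning orders honour custom repetition counts", {
  ss <- two_session_sets()[[1]]
  lo <- generate_learning_order(ss, n_reps = 4, n_blocks = 1, seed = 2,
                                baseline_reps = 0)
  expect_equal(nrow(lo), 144) # 12 variants x 4 repetitions x 3 trials
  expect_equal(sum(lo$role == "A"), 48)
  trip_seq <- lo$sequence_id[lo$role == "A"]
  expect_true(all(trip_seq[-1] != trip_seq[-length(trip_seq)]))
  expect_error(generate_learning_order(ss, n_reps = 5, n_blocks = 4, seed = 1),
               "divisible")
})

test_that("learning orders reproduce the design transition table exactly", {
  ss <- two_session_sets()[[1]]
  lo <- generate_learning_order(ss, seed = 8)
  tm <- compute_transition_matrix(lo, same_sequence = TRUE)
  expect_equal(tm$mean["A", "B"], 1)
  expect_equal(tm$mean["B", "C1"], 0.5)
  expect_equal(tm$mean["B", "C2"], 0.5)
  expect_equal(tm$mean["baseline", "A"], 1)
  expect_equal(tm$mean["A", "C1"] + tm$mean["A", "C2"], 0)
  expect_equal(sum(tm$mean[c("C1", "C2"), c("C1", "C2")]), 0)
  # sequence-specific (italicised) cells: same B follows same A every time
  expect_equal(tm$same_sequence["A", "B"], 1)
  expect_equal(tm$same_sequence["B", "C1"], 1)
})

test_that("recognition orders place triples, AB adjacencies and foils correctly", {
  sets <- two_session_sets()
  ro <- generate_recognition_order(sets, seed = 7)
  expect_equal(nrow(ro), 100)
  expect_equal(sum(ro$role == "foil"), 40)
  expect_equal(anyDuplicated(ro$object_id), 0)
  expect_true(all(ro$iti == 1) && all(ro$duration == 2))

  # every C1 is preceded by a same-session baseline and followed by its C2
  c1 <- which(ro$role == "C1")
  expect_length(c1, 12)
  expect_true(all(ro$role[c1 - 1] == "baseline"))
  expect_true(all(ro$session[c1 - 1] == ro$session[c1]))
  expect_true(all(ro$role[c1 + 1] == "C2"))
  expect_true(all(ro$sequence_id[c1 + 1] == ro$sequence_id[c1]))
  expect_true(all(ro$session[c1 + 1] == ro$session[c1]))
  # every B directly follows its own A
  b <- which(ro$role == "B")
  expect_length(b, 12)
  expect_true(all(ro$role[b - 1] == "A"))
  expect_true(all(ro$sequence_id[b - 1] == ro$sequence_id[b]))
  # a triple never directly follows a triple (no C2 -> baseline transitions)
  tm <- compute_transition_matrix(ro)
  expect_equal(tm$mean["C2", "baseline"], 0)
})

test_that("recognition toy case with one sequence per session and no foils", {
  sets <- list(toy_sequence_set("remote", "rem"), toy_sequence_set("recent", "rec"))
  ro <- generate_recognition_order(sets, n_foils = 0, seed = 3)
  expect_equal(nrow(ro), 10)
  c1 <- which(ro$role == "C1")
  expect_true(all(ro$role[c1 - 1] == "baseline"))
  expect_true(all(ro$role[c1 + 1] == "C2"))
  b <- which(ro$role == "B")
  expect_true(all(ro$role[b - 1] == "A"))
})

test_that("exposure orders split roles across scans with targets and no repeats", {
  sets <- two_session_sets()
  ex <- generate_exposure_orders(sets, seed = 9)
  expect_equal(nrow(ex$scan1) + nrow(ex$scan2), 260)
  expect_equal(length(unique(c(ex$scan1$object_id, ex$scan2$object_id))), 60)
  expect_true(all(ex$scan1$role %in% c("A", "C1", "baseline")))
  expect_true(all(ex$scan2$role %in% c("B", "C2", "baseline")))
  # C1 and its overlapping C2 never share a scan (role split guarantees it)
  expect_length(intersect(ex$scan1$object_id, ex$scan2$object_id), 0)
  for (sc in ex) {
    expect_false(any(sc$object_id[-1] == sc$object_id[-nrow(sc)]))
    expect_true(all(sc$iti %in% 2:5))
  }
  # 20 pound-sign trials; flagged objects shown five times, others four
  flags <- rbind(ex$scan1, ex$scan2)
  expect_equal(sum(flags$target_flag), 20)
  pres <- table(flags$object_id)
  tgt <- unique(flags$object_id[flags$target_flag])
  expect_true(all(pres[tgt] == 5))
  expect_true(all(pres[setdiff(names(pres), tgt)] == 4))

  ex0 <- generate_exposure_orders(sets, n_targets = 0, seed = 9)
  expect_equal(nrow(ex0$scan1) + nrow(ex0$scan2), 240)
  expect_false(any(ex0$scan1$target_flag))
})

test_that("explicit-test generation matches both experiments' composition", {
  sets <- two_session_sets()
  e1 <- generate_explicit_trials(sets, experiment = 1, seed = 4)
  expect_equal(nrow(e1), 60)
  expect_equal(as.vector(table(e1$pair_type)[c("AB_intact", "AB_rearranged",
                                               "C_intact", "C_rearranged",
                                               "baseline")]),
               rep(12L, 5))
  # every C object appears exactly twice (once intact, once re-arranged)
  c_ids <- unlist(lapply(sets, function(s) c(s$sequences$C1, s$sequences$C2)))
  c_rows <- e1[grepl("^C", e1$pair_type), ]
  appearances <- table(c(c_rows$left_object, c_rows$right_object))
  expect_true(all(appearances[c_ids] == 2))
  # re-arranged pairs never match the intact pairing
  rearr <- e1[e1$pair_type == "C_rearranged", ]
  for (s in sets) {
    sq <- s$sequences
    for (j in seq_len(nrow(sq))) {
      hit <- rearr$left_object == sq$C1[j]
      expect_false(any(rearr$right_object[hit] == sq$C2[j]))
    }
  }

  e2 <- generate_explicit_trials(sets, experiment = 2, seed = 4)
  expect_equal(nrow(e2), 48) # 12 sequences x 2 blocks x 2 cue directions
  expect_true(all(e2$foil_object != e2$target_object))
  expect_true(all(e2$duration == 4))
  # foils come from a different sequence in the same session
  for (i in seq_len(nrow(e2))) {
    s <- sets[[which(vapply(sets, function(x) x$session, "") == e2$session[i])]]
    foil_row <- s$objects[s$objects$object_id == e2$foil_object[i], ]
    expect_equal(foil_row$session, e2$session[i])
    expect_false(foil_row$sequence_id == e2$sequence_id[i])
  }
  # a single sequence per session leaves no valid foil
  toy <- list(toy_sequence_set("remote", "rem"), toy_sequence_set("recent", "rec"))
  expect_error(generate_explicit_trials(toy, experiment = 2, seed = 1),
               "at least 2 sequences")
})

test_that("transition matrices handle toy orders, aggregation and errors", {
  toy <- tibble::tibble(
    phase = "learning", block = 1L, position = 1:3, onset = c(0, 3, 6),
    duration = 2, iti = 1, object_id = c("a1", "b1", "c1"),
    role = c("A", "B", "C1"), sequence_id = 1L, session = "remote",
    target_flag = FALSE)
  tm <- compute_transition_matrix(toy)
  expect_equal(tm$mean["A", "B"], 1)
  expect_true(all(is.nan(tm$mean["C1", ])))
  expect_error(compute_transition_matrix(toy[1, , drop = FALSE]), "at least 2")
  expect_error(compute_transition_matrix(list()), "no orders")

  ss <- two_session_sets()[[1]]
  orders <- lapply(1:5, function(s) generate_learning_order(ss, seed = s))
  agg <- compute_transition_matrix(orders)
  expect_equal(agg$n_orders, 5)
  expect_equal(agg$sd["A", "B"], 0) # structural cell: no variance
  expect_gt(agg$sd["C1", "A"], 0)  # stochastic cell varies across orders
})

test_that("trial orders are byte-identical under the same seed and round-trip TSV", {
  ss <- two_session_sets()[[1]]
  a <- generate_learning_order(ss, seed = 21)
  b <- generate_learning_order(ss, seed = 21)
  expect_identical(a, b)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(a, f)
  rt <- read_events_tsv(f)
  expect_equal(rt$object_id, a$object_id)
  expect_equal(rt$onset, a$onset)
  expect_equal(rt$target_flag, a$target_flag)
  # serialized representation itself is reproducible
  f2 <- tempfile(fileext = ".tsv")
  write_events_tsv(b, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})

test_that("design validation flags corrupted orders", {
  ss <- two_session_sets()[[1]]
  lo <- generate_learning_order(ss, seed = 31)
  good <- validate_design_orders(lo)
  expect_true(all(good$pass))
  corrupted <- lo[lo$role != "B", ]
  bad <- validate_design_orders(corrupted)
  expect_false(bad$pass[bad$check == "learning: P(B follows A)"])
})
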