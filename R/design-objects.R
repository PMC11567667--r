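#' Synthetic object pool
#'
#' Builds a pool of object identifiers with big/small size-bin labels, the
#' manifest the design generator consumes. Real experiments would read a CSV
#' manifest instead (see [read_object_pool()]); bins here are split 50/50.
#'
#' @param n number of objects (default 100: two learning sessions of 30 plus
#'   40 recognition foils).
#' @param prefix identifier prefix.
#' @return tibble with `object_id`, `size_bin`.
#' @export
synthetic_object_pool <- function(n = 100, prefix = "obj") {
  stopifnot(n >= 2)
  tibble::tibble(
    object_id = sprintf("%s%03d", prefix, seq_len(n)),
    size_bin = rep(c("big", "small"), length.out = n)
  )
}

#' Read an object-pool manifest
#'
#' @param path CSV file with columns `object_id`, `size_bin` (`big`/`small`).
#' @return tibble with those columns.
#' @export
read_object_pool <- function(path) {
  pool <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("object_id", "size_bin") %in% names(pool))) {
    stop("object pool manifest must have columns 'object_id' and 'size_bin'")
  }
  if (!all(pool$size_bin %in% c("big", "small"))) {
    stop("size_bin must be 'big' or 'small'")
  }
  tibble::as_tibble(pool[, c("object_id", "size_bin")])
}

#' Assign a session's objects to sequence roles
#'
#' Arranges 30 pool objects into the session's 6 overlapping triplet structures
#' (A, B, C1, C2) plus 6 baseline objects. The motor-matching constraint is
#' enforced: within a sequence C1 and C2 share a size bin and that bin differs
#' from B's, and in exactly 3 of the 6 sequences the C bin is "big". Assignment
#' is uniform-random given those constraints and reproducible from `seed`.
#'
#' @param session `"recent"` or `"remote"`.
#' @param object_pool tibble with `object_id`, `size_bin`; needs at least 30
#'   objects with at least 15 per bin.
#' @param seed integer seed.
#' @param n_sequences,n_baseline structure counts (defaults 6 and 6).
#' @return a `sequence_set`: list with `session`, `sequences` (tibble: one row
#'   per sequence with A/B/C1/C2 ids and the C size bin) and `objects` (tibble
#'   of all 30 objects with `role`, `sequence_id`, `size_bin`, `session`).
#' @export
build_sequence_set <- function(session, object_pool, seed,
                               n_sequences = 6, n_baseline = 6) {
  session <- match.arg(session, c("recent", "remote"))
  stopifnot(n_sequences %% 2 == 0)
  need <- 4 * n_sequences + n_baseline
  if (nrow(object_pool) < need) {
    stop(sprintf("object pool too small: %d objects supplied, %d required",
                 nrow(object_pool), need))
  }
  # big-C sequences need 2 big C + 1 small B; small-C sequences the reverse;
  # A and baseline objects are unconstrained.
  half <- n_sequences / 2
  need_per_bin <- 2 * half + half # C pair + opposite-bin B per half
  for (bin in c("big", "small")) {
    n_bin <- sum(object_pool$size_bin == bin)
    if (n_bin < need_per_bin) {
      stop(sprintf("object pool bin-imbalanced: %d '%s' objects, %d required",
                   n_bin, bin, need_per_bin))
    }
  }

  with_seed(seed, {
    pool <- object_pool[sample.int(nrow(object_pool)), ]
    big <- pool$object_id[pool$size_bin == "big"]
    small <- pool$object_id[pool$size_bin == "small"]
    take <- function(ids, k) {
      out <- ids[seq_len(k)]
      list(taken = out, rest = ids[-seq_len(k)])
    }
    # C bins: half big, half small, in random sequence positions
    c_bins <- sample(rep(c("big", "small"), each = half))
    c1 <- c2 <- b <- character(n_sequences)
    for (j in seq_len(n_sequences)) {
      if (c_bins[j] == "big") {
        t1 <- take(big, 2); big <- t1$rest
        c1[j] <- t1$taken[1]; c2[j] <- t1$taken[2]
        t2 <- take(small, 1); small <- t2$rest
        b[j] <- t2$taken
      } else {
        t1 <- take(small, 2); small <- t1$rest
        c1[j] <- t1$taken[1]; c2[j] <- t1$taken[2]
        t2 <- take(big, 1); big <- t2$rest
        b[j] <- t2$taken
      }
    }
    rest <- sample(c(big, small))
    a <- rest[seq_len(n_sequences)]
    baselines <- rest[n_sequences + seq_len(n_baseline)]

    sequences <- tibble::tibble(
      sequence_id = seq_len(n_sequences),
      A = a, B = b, C1 = c1, C2 = c2, c_bin = c_bins
    )
    objects <- rbind(
      data.frame(object_id = a, role = "A", sequence_id = seq_len(n_sequences)),
      data.frame(object_id = b, role = "B", sequence_id = seq_len(n_sequences)),
      data.frame(object_id = c1, role = "C1", sequence_id = seq_len(n_sequences)),
      data.frame(object_id = c2, role = "C2", sequence_id = seq_len(n_sequences)),
      data.frame(object_id = baselines, role = "baseline", sequence_id = NA_integer_)
    )
    objects$session <- session
    objects$size_bin <- object_pool$size_bin[match(objects$object_id, object_pool$object_id)]
    out <- list(session = session, sequences = sequences,
                objects = tibble::as_tibble(objects))
    class(out) <- "sequence_set"
    out
  })
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set: %s session, %d sequences, %d baseline objects>\n",
              x$session, nrow(x$sequences), sum(x$objects$role == "baseline")))
  invisible(x)
}

# role lookup table for an order built from one or two sequence sets
role_table <- function(seq_sets) {
  if (inherits(seq_sets, "sequence_set")) seq_sets <- list(seq_sets)
  do.call(rbind, lapply(seq_sets, function(s) s$objects))
}
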