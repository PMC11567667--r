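#' Empirical role-transition probabilities for trial orders
#'
#' Computes, for each ordered pair of roles, the empirical probability that a
#' column-role item immediately follows a row-role item. Transitions are
#' counted within blocks/scans only. Across several orders the per-cell mean
#' and SD are returned (the design's descriptive transition table aggregates
#' per participant this way). Rows with zero occurrences are `NaN` and flagged
#' in `undefined_rows`.
#'
#' @param orders a trial-order tibble or a list of them.
#' @param roles role levels in display order; defaults to those present.
#' @param same_sequence if `TRUE`, also return the fraction of transitions
#'   whose successor comes from the same sequence (the sequence-specific,
#'   italicised reading of deterministic cells).
#' @return object of class `transition_matrix`: list with `mean`, `sd`,
#'   `n_orders`, `undefined_rows`, and optionally `same_sequence`.
#' @export
compute_transition_matrix <- function(orders, roles = NULL, same_sequence = FALSE) {
  if (is.data.frame(orders)) orders <- list(orders)
  if (length(orders) == 0) stop("no orders supplied")
  for (o in orders) if (nrow(o) < 2) stop("orders need at least 2 trials")
  if (is.null(roles)) {
    roles <- unique(unlist(lapply(orders, function(o) o$role)))
    pref <- c("A", "B", "C1", "C2", "baseline", "foil")
    roles <- c(intersect(pref, roles), setdiff(roles, pref))
  }
  k <- length(roles)
  per_order <- lapply(orders, function(o) {
    counts <- matrix(0, k, k, dimnames = list(precedes = roles, follows = roles))
    same <- matrix(0, k, k, dimnames = dimnames(counts))
    same_n <- matrix(0, k, k, dimnames = dimnames(counts))
    for (blk in split(o, o$block)) {
      n <- nrow(blk)
      if (n < 2) next
      from <- match(blk$role[-n], roles)
      to <- match(blk$role[-1], roles)
      for (i in seq_len(n - 1)) {
        counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
        sf <- blk$sequence_id[i]; st <- blk$sequence_id[i + 1]
        if (!is.na(sf) && !is.na(st)) {
          same_n[from[i], to[i]] <- same_n[from[i], to[i]] + 1
          if (sf == st) same[from[i], to[i]] <- same[from[i], to[i]] + 1
        }
      }
    }
    p <- counts / rowSums(counts)
    list(p = p, same = same / pmax(same_n, 1), counts = counts)
  })
  ps <- simplify2array(lapply(per_order, `[[`, "p"))
  mean_p <- apply(ps, c(1, 2), mean)
  sd_p <- if (length(orders) > 1) apply(ps, c(1, 2), stats::sd) else
    matrix(0, k, k, dimnames = dimnames(mean_p))
  out <- list(mean = mean_p, sd = sd_p, n_orders = length(orders),
              undefined_rows = roles[apply(is.nan(mean_p), 1, all)])
  if (same_sequence) {
    ss <- simplify2array(lapply(per_order, `[[`, "same"))
    out$same_sequence <- apply(ss, c(1, 2), mean)
  }
  class(out) <- "transition_matrix"
  out
}

#' @export
print.transition_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<transition_matrix over %d order(s)>\nmean:\n", x$n_orders))
  print(round(x$mean, digits))
  if (x$n_orders > 1) { cat("sd:\n"); print(round(x$sd, digits)) }
  invisible(x)
}

# one structural check row
.check <- function(name, value, target, tol = 0) {
  tibble::tibble(check = name, value = value, target = target,
                 pass = is.finite(value) & abs(value - target) <= tol)
}

#' Validate generated orders against the design's transition structure
#'
#' Checks the structural (exact 0 / 1 / 0.5) transition-probability cells that
#' any valid order must reproduce: during learning, B always follows A, C1 and
#' C2 each follow B half the time, baselines are always followed by A, and C
#' objects never follow A or another C; during recognition, B follows its A,
#' C2 follows C1, and baselines precede C1 deterministically. Stochastic cells
#' (e.g. what follows a C during learning) are reported but only bounded.
#'
#' @param learning trial-order tibble or list of them (one per session).
#' @param recognition optional recognition trial order.
#' @param exposure optional list with `scan1`/`scan2` exposure orders.
#' @return tibble of checks with `value`, `target`, `pass`.
#' @export
validate_design_orders <- function(learning, recognition = NULL, exposure = NULL) {
  out <- list()
  if (!is.null(learning)) {
    tm <- compute_transition_matrix(
      learning, roles = c("A", "B", "C1", "C2", "baseline"))$mean
    out[[length(out) + 1L]] <- rbind(
      .check("learning: P(B follows A)", tm["A", "B"], 1),
      .check("learning: P(C1 follows B)", tm["B", "C1"], 0.5),
      .check("learning: P(C2 follows B)", tm["B", "C2"], 0.5),
      .check("learning: P(A follows baseline)", tm["baseline", "A"], 1),
      .check("learning: P(C follows A)", tm["A", "C1"] + tm["A", "C2"], 0),
      .check("learning: P(C follows C)",
             sum(tm[c("C1", "C2"), c("C1", "C2")]), 0),
      .check("learning: P(A or base follows C1)",
             tm["C1", "A"] + tm["C1", "baseline"], 1),
      .check("learning: P(A or base follows C2)",
             tm["C2", "A"] + tm["C2", "baseline"], 1))
  }
  if (!is.null(recognition)) {
    tm <- compute_transition_matrix(
      recognition, roles = c("A", "B", "C1", "C2", "baseline", "foil"))$mean
    out[[length(out) + 1L]] <- rbind(
      .check("recognition: P(B follows A)", tm["A", "B"], 1),
      .check("recognition: P(C2 follows C1)", tm["C1", "C2"], 1),
      .check("recognition: P(C1 follows baseline)", tm["baseline", "C1"], 1),
      .check("recognition: P(base follows C2)", tm["C2", "baseline"], 0))
  }
  if (!is.null(exposure)) {
    for (sc in names(exposure)) {
      o <- exposure[[sc]]
      n <- nrow(o)
      out[[length(out) + 1L]] <- .check(
        sprintf("exposure %s: back-to-back repeats", sc),
        sum(o$object_id[-1] == o$object_id[-n]), 0)
    }
  }
  do.call(rbind, out)
}
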