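# Behavioral statistics: predictability labelling, learning-curve mixed
# models, the recognition-priming score and its trial-level models,
# nonparametric sensitivity A, and explicit-integration scores.

#' Predictability labels for learning trials
#'
#' B, C1 and C2 responses are predictable from the preceding object; A and
#' baseline objects are not.
#'
#' @param trial_order learning trial-order tibble (or any vector of roles).
#' @return character vector `"predictable"` / `"unpredictable"`.
#' @export
label_predictability <- function(trial_order) {
  roles <- if (is.data.frame(trial_order)) trial_order$role else trial_order
  bad <- setdiff(unique(roles), c("A", "B", "C1", "C2", "baseline"))
  if (length(bad) > 0) {
    stop("unknown role(s) in learning order: ", paste(bad, collapse = ", "))
  }
  ifelse(roles %in% c("B", "C1", "C2"), "predictable", "unpredictable")
}

#' Repetition index of each learning trial
#'
#' Presentation count per object mapped onto the 1..n_reps repetition scale:
#' C and baseline objects appear once per repetition, A and B twice (once in
#' each triplet variant), so their presentation indices are halved.
#'
#' @param trial_order learning trial-order tibble (one session).
#' @param n_reps repetitions per triplet variant.
#' @return integer vector of repetition indices, one per trial.
#' @export
learning_repetition <- function(trial_order, n_reps = 16) {
  idx <- stats::ave(seq_len(nrow(trial_order)), trial_order$object_id,
                    FUN = seq_along)
  total <- stats::ave(seq_len(nrow(trial_order)), trial_order$object_id,
                      FUN = length)
  as.integer(ceiling(idx * n_reps / total))
}

#' Aggregate learning RTs to per-repetition medians
#'
#' The modelling unit for the learning curve: per subject, session,
#' repetition (1..16) and predictability class, the median RT over all trials
#' of that class (all trials included regardless of accuracy).
#'
#' @param records trial-level learning records with columns `subject`,
#'   `session`, `repetition`, `predictability` (or `role`), `rt_ms`.
#' @return tibble `subject, session, repetition, predictability, median_rt`.
#' @export
aggregate_learning_rts <- function(records) {
  df <- as.data.frame(records)
  if (!"predictability" %in% names(df)) {
    df$predictability <- label_predictability(df$role)
  }
  df <- df[is.finite(df$rt_ms), ]
  agg <- stats::aggregate(rt_ms ~ subject + session + repetition + predictability,
                          data = df, FUN = stats::median)
  names(agg)[names(agg) == "rt_ms"] <- "median_rt"
  tibble::as_tibble(agg[order(agg$subject, agg$session, agg$repetition), ])
}

# try a ladder of random-effect structures, reducing on singular fits
fit_lmm_reduced <- function(data, fixed, ladders, reml = TRUE) {
  log_ <- character(0)
  for (re in ladders) {
    f <- stats::as.formula(paste(fixed, "+", re))
    fit <- suppressMessages(suppressWarnings(
      try(lmerTest::lmer(f, data = data, REML = reml), silent = TRUE)))
    if (inherits(fit, "try-error")) {
      log_ <- c(log_, paste(re, "-> fit error"))
      next
    }
    if (lme4::isSingular(fit, tol = 1e-4)) {
      log_ <- c(log_, paste(re, "-> singular"))
      next
    }
    return(list(fit = fit, random = re, reduction_log = log_, converged = TRUE))
  }
  # nothing non-singular: keep the simplest fit, flagged
  f <- stats::as.formula(paste(fixed, "+", ladders[[length(ladders)]]))
  fit <- suppressMessages(suppressWarnings(lmerTest::lmer(f, data = data, REML = reml)))
  list(fit = fit, random = ladders[[length(ladders)]],
       reduction_log = c(log_, "kept simplest structure (flagged)"),
       converged = !lme4::isSingular(fit, tol = 1e-4))
}

lmm_report <- function(fitted, model_desc) {
  an <- stats::anova(fitted$fit) # lmerTest: Satterthwaite F tests
  structure(list(
    model = model_desc,
    random = fitted$random,
    terms = tibble::tibble(term = rownames(an), F = an$`F value`,
                           df1 = an$NumDF, df2 = an$DenDF,
                           p = an$`Pr(>F)`),
    converged = fitted$converged,
    singular = lme4::isSingular(fitted$fit, tol = 1e-4),
    reduction_log = fitted$reduction_log,
    fit = fitted$fit), class = "lmm_report")
}

#' @export
print.lmm_report <- function(x, ...) {
  cat(sprintf("<lmm_report: %s | random: %s%s>\n", x$model, x$random,
              if (!x$converged) " | NOT CONVERGED" else ""))
  print(x$terms)
  invisible(x)
}

#' Mixed-effects learning-curve model
#'
#' Linear mixed model on per-repetition median RTs (or eligible-trial
#' accuracy) with repetition (continuous), learning session, predictability
#' and all interactions as fixed effects. Random effects start maximal
#' (per-subject intercepts and slopes for every predictor) and are reduced
#' until the fit is non-singular; the reduction path is logged. F statistics
#' use Satterthwaite approximate degrees of freedom.
#'
#' @param records trial-level learning records (see
#'   [aggregate_learning_rts()]); for `response = "accuracy"` they must carry
#'   an `accuracy` column with NA for ineligible trials.
#' @param response `"rt"` or `"accuracy"`.
#' @return `lmm_report` with per-term F, df, p and convergence flags.
#' @export
fit_learning_model <- function(records, response = c("rt", "accuracy")) {
  response <- match.arg(response)
  df <- as.data.frame(records)
  if (length(unique(df$subject)) < 2) stop("need records from at least 2 subjects")
  if (length(unique(df$session)) < 2) stop("need both learning sessions")
  if (response == "rt") {
    agg <- as.data.frame(aggregate_learning_rts(df))
    agg$y <- agg$median_rt
  } else {
    if (!"accuracy" %in% names(df)) stop("records lack an accuracy column")
    df <- df[!is.na(df$accuracy), ]
    if (!"predictability" %in% names(df)) {
      df$predictability <- label_predictability(df$role)
    }
    agg <- stats::aggregate(accuracy ~ subject + session + repetition + predictability,
                            data = df, FUN = mean)
    agg$y <- agg$accuracy
  }
  agg$repetition_c <- (agg$repetition - mean(agg$repetition)) / stats::sd(agg$repetition)
  agg$session <- factor(agg$session)
  agg$predictability <- factor(agg$predictability)
  fitted <- fit_lmm_reduced(
    agg, "y ~ repetition_c * session * predictability",
    list("(1 + repetition_c + session + predictability | subject)",
         "(1 + repetition_c | subject)",
         "(1 | subject)"))
  lmm_report(fitted, sprintf("%s ~ repetition * session * predictability", response))
}

#' Recognition-priming scores
#'
#' For every sequence the recognition order contains a contiguous
#' (same-session baseline, C1, C2) triple; the C1 response (preceded by an
#' unrelated old object) is the control and the C2 response (preceded by its
#' overlapping C1) is primed. A sequence enters the score only if the
#' baseline, C1 and C2 were all correctly endorsed 'old', which matches the
#' response history of the two conditions. The per-subject score is the
#' median of the within-sequence differences `RT(C1) - RT(C2)` (positive =
#' faster when primed); `difference_of_medians` gives the alternative
#' aggregation `median(RT C1) - median(RT C2)`.
#'
#' @param records recognition records: `subject`, `position`, `rt_ms`,
#'   `response` (`"old"`/`"new"`).
#' @param trial_order the recognition trial order the records were collected
#'   under.
#' @param aggregate `"median_of_differences"` (default) or
#'   `"difference_of_medians"`.
#' @return list with `scores` (tibble: subject, session, median_diff_ms,
#'   n_included) and `trials` (trial-level table for mixed models: subject,
#'   session, sequence_id, order_cond primed/control, rt_ms, position).
#' @export
score_priming <- function(records, trial_order,
                          aggregate = c("median_of_differences",
                                        "difference_of_medians")) {
  aggregate <- match.arg(aggregate)
  ord <- as.data.frame(trial_order)
  rec <- as.data.frame(records)
  need <- c("subject", "position", "rt_ms", "response")
  if (!all(need %in% names(rec))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  c1_pos <- which(ord$role == "C1")
  triples <- data.frame(
    session = ord$session[c1_pos],
    sequence_id = ord$sequence_id[c1_pos],
    pos_base = c1_pos - 1L, pos_c1 = c1_pos, pos_c2 = c1_pos + 1L)
  stopifnot(all(ord$role[triples$pos_base] == "baseline"),
            all(ord$role[triples$pos_c2] == "C2"))

  out_scores <- list(); out_trials <- list()
  for (sub in unique(rec$subject)) {
    rs <- rec[rec$subject == sub, ]
    look <- function(pos, col) rs[[col]][match(pos, rs$position)]
    incl <- look(triples$pos_base, "response") == "old" &
      look(triples$pos_c1, "response") == "old" &
      look(triples$pos_c2, "response") == "old"
    incl[is.na(incl)] <- FALSE
    for (ses in unique(triples$session)) {
      sel <- triples$session == ses & incl
      rt_c1 <- look(triples$pos_c1[sel], "rt_ms")
      rt_c2 <- look(triples$pos_c2[sel], "rt_ms")
      n_inc <- sum(sel)
      med <- if (n_inc == 0) NA_real_ else if (aggregate == "median_of_differences")
        stats::median(rt_c1 - rt_c2) else
        stats::median(rt_c1) - stats::median(rt_c2)
      out_scores[[length(out_scores) + 1L]] <- tibble::tibble(
        subject = sub, session = ses, median_diff_ms = med, n_included = n_inc)
      if (n_inc > 0) {
        out_trials[[length(out_trials) + 1L]] <- tibble::tibble(
          subject = sub, session = ses,
          sequence_id = rep(triples$sequence_id[sel], 2),
          order_cond = rep(c("control", "primed"), each = n_inc),
          rt_ms = c(rt_c1, rt_c2),
          position = c(triples$pos_c1[sel], triples$pos_c2[sel]))
      }
    }
  }
  list(scores = do.call(rbind, out_scores),
       trials = if (length(out_trials)) do.call(rbind, out_trials) else NULL)
}

#' Trial-level mixed model for recognition priming
#'
#' RT as outcome, priming condition (primed vs control) as predictor, random
#' intercepts/slopes per subject reduced on singularity; optionally restricted
#' to one session, with learning session as an additional factor otherwise,
#' and optionally with trial position as a continuous covariate (the practice
#' -effect control).
#'
#' @param trials the `trials` table from [score_priming()].
#' @param session optional session to subset to.
#' @param include_position add trial position as covariate.
#' @return `lmm_report`.
#' @export
fit_priming_model <- function(trials, session = NULL, include_position = FALSE) {
  df <- as.data.frame(trials)
  if (!is.null(session)) df <- df[df$session == session, ]
  df$order_cond <- factor(df$order_cond, c("control", "primed"))
  fixed <- "rt_ms ~ order_cond"
  if (is.null(session)) fixed <- paste(fixed, "* session")
  if (include_position) {
    df$position_c <- as.numeric(scale(df$position))
    fixed <- paste(fixed, "+ position_c")
  }
  fitted <- fit_lmm_reduced(df, fixed,
                            list("(1 + order_cond | subject)", "(1 | subject)"))
  lmm_report(fitted, fixed)
}

#' Nonparametric sensitivity A
#'
#' The closed-form piecewise A of Zhang & Mueller (2005): the average of the
#' areas under the minimal and maximal proper ROC curves through the observed
#' (false-alarm, hit) point. Defined for perfect performance where d-prime is
#' not; ties (h = f) give exactly 0.5 and points below the diagonal are
#' handled by symmetry (A(h, f) = 1 - A(f, h)).
#'
#' @param hits hit rate(s) in `[0, 1]`.
#' @param false_alarms false-alarm rate(s) in `[0, 1]`.
#' @return sensitivity values in `[0, 1]` (0.5 = chance, 1 = perfect).
#' @export
sensitivity_A <- function(hits, false_alarms) {
  if (any(hits < 0 | hits > 1 | false_alarms < 0 | false_alarms > 1)) {
    stop("hit and false-alarm rates must lie in [0, 1]")
  }
  a_upper <- function(h, f) {
    if (f <= 0.5 && h >= 0.5) {
      3 / 4 + (h - f) / 4 - f * (1 - h)
    } else if (f < h && h < 0.5) {
      3 / 4 + (h - f) / 4 - f / (4 * h)
    } else {
      3 / 4 + (h - f) / 4 - (1 - h) / (4 * (1 - f))
    }
  }
  mapply(function(h, f) {
    if (h == f) return(0.5)
    if (h > f) a_upper(h, f) else 1 - a_upper(f, h)
  }, hits, false_alarms)
}

#' Wilcoxon signed-rank comparison of sensitivity across sessions
#'
#' @param a_recent,a_remote paired per-subject A values.
#' @return `stats::wilcox.test` result (paired; exact for n <= 25 without ties).
#' @export
sensitivity_session_test <- function(a_recent, a_remote) {
  d <- a_recent - a_remote
  use_exact <- length(d) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  stats::wilcox.test(a_recent, a_remote, paired = TRUE, exact = use_exact)
}

#' Explicit-integration scores with group tests
#'
#' Experiment 1 (rating pairs): per subject, session and pair class (AB or C),
#' the mean rating for intact pairs minus the mean for re-arranged pairs, on
#' the rating's 0-1 scale (chance 0). Experiment 2 (2AFC): the proportion of
#' trials choosing the true associate (chance 0.5). Group inference: two-sided
#' one-sample t against chance per session, and a paired t across sessions;
#' zero-variance inputs are flagged degenerate rather than tested.
#'
#' @param records Experiment 1: `subject, session, pair_type, rating`;
#'   Experiment 2: `subject, session, test_block, correct`.
#' @param experiment 1 or 2.
#' @return list with `scores` (tibble subject/session/pair_class/score/chance)
#'   and `group` (tibble of tests).
#' @export
score_explicit <- function(records, experiment = 1) {
  stopifnot(experiment %in% c(1, 2))
  df <- as.data.frame(records)
  rows <- list()
  if (experiment == 1) {
    df$pair_class <- sub("_(intact|rearranged)$", "", df$pair_type)
    for (cls in c("AB", "C")) {
      d <- df[df$pair_class == cls, ]
      if (nrow(d) == 0) next
      agg <- stats::aggregate(rating ~ subject + session + pair_type, data = d,
                              FUN = mean)
      wide <- stats::reshape(agg, idvar = c("subject", "session"),
                             timevar = "pair_type", direction = "wide")
      sc <- wide[[paste0("rating.", cls, "_intact")]] -
        wide[[paste0("rating.", cls, "_rearranged")]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = wide$subject, session = wide$session, pair_class = cls,
        score = sc, chance = 0)
    }
  } else {
    blk_class <- c(AB = "AB", C = "C")
    agg <- stats::aggregate(correct ~ subject + session + test_block, data = df,
                            FUN = mean)
    rows[[1]] <- tibble::tibble(subject = agg$subject, session = agg$session,
                                pair_class = blk_class[agg$test_block],
                                score = agg$correct, chance = 0.5)
  }
  scores <- do.call(rbind, rows)

  group <- list()
  for (cls in unique(scores$pair_class)) {
    sc <- scores[scores$pair_class == cls, ]
    for (ses in unique(sc$session)) {
      v <- sc$score[sc$session == ses]
      chance <- sc$chance[1]
      degen <- stats::sd(v) == 0
      tt <- if (!degen) stats::t.test(v, mu = chance) else NULL
      group[[length(group) + 1L]] <- tibble::tibble(
        pair_class = cls, test = paste0("one-sample vs chance (", ses, ")"),
        mean = mean(v), t = if (degen) NA_real_ else unname(tt$statistic),
        df = if (degen) NA_real_ else unname(tt$parameter),
        p = if (degen) NA_real_ else tt$p.value, degenerate = degen)
    }
    if (length(unique(sc$session)) == 2) {
      w <- stats::reshape(as.data.frame(sc[, c("subject", "session", "score")]),
                          idvar = "subject", timevar = "session",
                          direction = "wide")
      v1 <- w[[2]]; v2 <- w[[3]]
      degen <- stats::sd(v1 - v2) == 0
      tt <- if (!degen) stats::t.test(v1, v2, paired = TRUE) else NULL
      group[[length(group) + 1L]] <- tibble::tibble(
        pair_class = cls, test = "paired across sessions",
        mean = mean(v1 - v2), t = if (degen) NA_real_ else unname(tt$statistic),
        df = if (degen) NA_real_ else unname(tt$parameter),
        p = if (degen) NA_real_ else tt$p.value, degenerate = degen)
    }
  }
  list(scores = scores, group = do.call(rbind, group))
}
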