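utils::globalVariables(c())

kept_trials <- function(trials) {
  if ("excluded" %in% names(trials)) trials[!trials$excluded, ] else trials
}

#' Proportion of touches starting / ending in systole
#'
#' Events falling in the unassigned mid-cycle gap are excluded and the
#' proportions renormalised over assigned events, so systole + diastole
#' proportions sum to 1 and only the systole proportion needs analysing
#' (chance level 0.5).
#'
#' @param trials phase-annotated trials (see [annotate_phases()]); excluded
#'   trials are dropped.
#' @param min_trials minimum assigned events per cell (default 5); smaller
#'   cells give `NA`.
#' @param by_level additionally break gratings trials down by difficulty.
#' @return list with `table` (participant x condition rows:
#'   `prop_start_systole`, `prop_end_systole`, cell n's) and `tests` (per
#'   condition: paired t start vs end, one-sample t vs 0.5 for each event
#'   type).
#' @export
phase_proportions <- function(trials, min_trials = 5, by_level = FALSE) {
  tr <- kept_trials(trials)
  cell <- function(d) {
    ns <- sum(d$onset_window == "systole", na.rm = TRUE)
    nd <- sum(d$onset_window == "diastole", na.rm = TRUE)
    es <- sum(d$offset_window == "systole", na.rm = TRUE)
    ed <- sum(d$offset_window == "diastole", na.rm = TRUE)
    data.frame(n_start = ns + nd, n_end = es + ed,
               prop_start_systole = if (ns + nd >= min_trials) ns / (ns + nd) else NA_real_,
               prop_end_systole = if (es + ed >= min_trials) es / (es + ed) else NA_real_)
  }
  split_by <- if (by_level) {
    interaction(tr$participant, tr$condition, tr$level, drop = TRUE)
  } else {
    interaction(tr$participant, tr$condition, drop = TRUE)
  }
  parts <- split(tr, split_by)
  tab <- do.call(rbind, Map(function(d, nm) {
    cbind(data.frame(participant = d$participant[1], condition = d$condition[1],
                     level = if (by_level) d$level[1] else NA_character_),
          cell(d))
  }, parts, names(parts)))
  rownames(tab) <- NULL
  tests <- lapply(split(tab, tab$condition), function(d) {
    d <- d[stats::complete.cases(d[c("prop_start_systole", "prop_end_systole")]), ]
    if (nrow(d) < 3) return(NULL)
    list(start_vs_end = stats::t.test(d$prop_start_systole, d$prop_end_systole,
                                      paired = TRUE),
         start_vs_chance = stats::t.test(d$prop_start_systole, mu = 0.5),
         end_vs_chance = stats::t.test(d$prop_end_systole, mu = 0.5))
  })
  list(table = tab, tests = tests)
}

#' Hold duration by cardiac phase of touch initiation
#'
#' Summarises, per participant and condition, the central tendency of hold
#' durations for touches initiated in the systole vs the diastole window
#' (gap-initiated touches are excluded). The group contrast is paired on the
#' systole-minus-diastole differences (the diastole-minus-systole difference
#' score used for plotting is its negation, exported by
#' [variability_covariate_analysis()]): a Shapiro-Wilk check on the differences picks a
#' paired t-test or a Wilcoxon signed-rank fallback; the 95% CI of the mean
#' difference is t-based either way.
#'
#' @param trials phase-annotated trials.
#' @param stat `"mean"` or `"median"` within-participant central tendency to
#'   contrast (both are returned in the table).
#' @return list with `per_participant` and `contrasts` (one row per
#'   condition: estimates, diff = systole - diastole, CI, test used, p).
#' @export
duration_by_initiation_phase <- function(trials, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  tr <- kept_trials(trials)
  tr <- tr[tr$onset_window %in% c("systole", "diastole"), ]
  agg <- do.call(rbind, lapply(
    split(tr, interaction(tr$participant, tr$condition, tr$onset_window,
                          drop = TRUE)),
    function(d) data.frame(participant = d$participant[1],
                           condition = d$condition[1],
                           phase = d$onset_window[1], n = nrow(d),
                           mean_hold = mean(d$hold),
                           median_hold = stats::median(d$hold))))
  rownames(agg) <- NULL
  col <- paste0(stat, "_hold")
  contrasts <- do.call(rbind, lapply(split(agg, agg$condition), function(d) {
    wide <- merge(d[d$phase == "systole", c("participant", col)],
                  d[d$phase == "diastole", c("participant", col)],
                  by = "participant", suffixes = c("_sys", "_dia"))
    if (nrow(wide) < 3) return(NULL)
    diff <- wide[[paste0(col, "_sys")]] - wide[[paste0(col, "_dia")]]
    if (stats::sd(diff) == 0) {
      return(data.frame(condition = d$condition[1], n = nrow(wide),
                        stat = stat,
                        systole = mean(wide[[paste0(col, "_sys")]]),
                        diastole = mean(wide[[paste0(col, "_dia")]]),
                        diff = mean(diff), ci_lo = mean(diff),
                        ci_hi = mean(diff), shapiro_p = NA_real_,
                        test = "degenerate", statistic = NA_real_,
                        p = if (all(diff == 0)) 1 else NA_real_))
    }
    sw_p <- tryCatch(stats::shapiro.test(diff)$p.value, error = function(e) NA)
    tt <- stats::t.test(diff)
    if (!is.na(sw_p) && sw_p < 0.05) {
      wt <- stats::wilcox.test(diff, exact = FALSE)
      test <- "wilcoxon"; p <- wt$p.value; statv <- unname(wt$statistic)
    } else {
      test <- "t"; p <- tt$p.value; statv <- unname(tt$statistic)
    }
    data.frame(condition = d$condition[1], n = nrow(wide), stat = stat,
               systole = mean(wide[[paste0(col, "_sys")]]),
               diastole = mean(wide[[paste0(col, "_dia")]]),
               diff = mean(diff),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               shapiro_p = sw_p, test = test, statistic = statv, p = p)
  }))
  rownames(contrasts) <- NULL
  list(per_participant = agg, contrasts = contrasts)
}

#' Accuracy by cardiac phase, event type and difficulty
#'
#' Proportion of correct responses per participant for touches that started
#' (or ended) in each cardiac-phase window, optionally per difficulty level
#' — the input table for a phase x event-type x difficulty repeated-measures
#' analysis. Gratings condition only.
#'
#' @param trials phase-annotated trials.
#' @param by_level break down by difficulty (default TRUE).
#' @return tidy data.frame: `participant`, `event_type`, `phase`, `level`
#'   (`"all"` rows always included), `n`, `accuracy`.
#' @export
accuracy_by_phase <- function(trials, by_level = TRUE) {
  tr <- kept_trials(trials)
  tr <- tr[tr$condition == "gratings" & !is.na(tr$correct), ]
  rows <- list()
  for (ev in c("start", "end")) {
    wcol <- if (ev == "start") "onset_window" else "offset_window"
    d0 <- tr[tr[[wcol]] %in% c("systole", "diastole"), ]
    lv <- if (by_level) c("all", sort(unique(d0$level))) else "all"
    for (l in lv) {
      d1 <- if (l == "all") d0 else d0[d0$level == l, ]
      for (ph in c("systole", "diastole")) {
        d2 <- d1[d1[[wcol]] == ph, ]
        acc <- tapply(d2$correct, d2$participant, mean)
        nn <- tapply(d2$correct, d2$participant, length)
        if (is.null(acc) || !length(acc)) next
        rows[[length(rows) + 1L]] <-
          data.frame(participant = names(acc), event_type = ev, phase = ph,
                     level = l, n = as.integer(nn), accuracy = as.numeric(acc))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Touch-duration variability covariate analysis
#'
#' Computes each participant's hold-duration SD across all retained gratings
#' trials (the between-subject variability covariate), joins it to the
#' phase-duration table ready for a covariate-adjusted repeated-measures
#' analysis, and natively computes the Pearson correlation between overall
#' accuracy and the covariate.
#'
#' @param trials phase-annotated trials (gratings trials used).
#' @return list with `table` (participant, hold_sd, accuracy, diff
#'   dia-systole median/mean durations) and `pearson` (`r`, `p`, `n`); `r`
#'   is `NA` with a flag when the covariate has zero variance.
#' @export
variability_covariate_analysis <- function(trials) {
  tr <- kept_trials(trials)
  g <- tr[tr$condition == "gratings", ]
  ids <- sort(unique(g$participant))
  if (length(ids) < 3) stop("need at least 3 participants")
  cov_sd <- vapply(ids, function(id) stats::sd(g$hold[g$participant == id]),
                   numeric(1))
  acc <- vapply(ids, function(id) {
    k <- g$correct[g$participant == id]
    mean(k[!is.na(k)])
  }, numeric(1))
  dur <- duration_by_initiation_phase(trials, stat = "mean")$per_participant
  dur <- dur[dur$condition == "gratings", ]
  wide <- merge(dur[dur$phase == "systole", c("participant", "mean_hold")],
                dur[dur$phase == "diastole", c("participant", "mean_hold")],
                by = "participant", suffixes = c("_sys", "_dia"), all = TRUE)
  tab <- data.frame(participant = ids, hold_sd = cov_sd, accuracy = acc)
  tab <- merge(tab, wide, by = "participant", all.x = TRUE)
  tab$diff_dia_sys <- tab$mean_hold_dia - tab$mean_hold_sys
  if (stats::sd(cov_sd) == 0 || all(is.na(cov_sd))) {
    pearson <- list(r = NA_real_, p = NA_real_, n = length(ids),
                    note = "zero-variance covariate")
  } else {
    ct <- stats::cor.test(tab$accuracy, tab$hold_sd)
    pearson <- list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
  }
  list(table = tab, pearson = pearson)
}

#' Interbeat intervals around touch onset, by beat position
#'
#' Mean IBI per participant at beat positions -2..+2 relative to the cycle
#' containing the touch onset, decomposed into systole and diastole
#' sub-lengths; group means and Holm-corrected paired t-tests of position 0
#' against every other position (for the whole IBI and each sub-length).
#'
#' @param contexts stacked context table from [ibi_contexts()].
#' @return list with `per_participant`, `group` (means by position) and
#'   `posthoc` (position-0 contrasts with raw and adjusted p).
#' @export
ibi_position_analysis <- function(contexts) {
  agg <- stats::aggregate(cbind(ibi, systole, diastole) ~ participant + position,
                          data = contexts, FUN = mean)
  agg <- agg[order(agg$participant, agg$position), ]
  group <- stats::aggregate(cbind(ibi, systole, diastole) ~ position,
                            data = agg, FUN = mean)
  post <- list()
  for (meas in c("ibi", "systole", "diastole")) {
    w <- stats::reshape(agg[c("participant", "position", meas)],
                        idvar = "participant", timevar = "position",
                        direction = "wide")
    p0 <- w[[paste0(meas, ".0")]]
    for (pos in c(-2, -1, 1, 2)) {
      pk <- w[[paste0(meas, ".", pos)]]
      ok <- stats::complete.cases(p0, pk)
      dd <- p0[ok] - pk[ok]
      if (sum(ok) < 3 || stats::sd(dd) == 0) {
        # zero-variance differences (e.g. a constant electrical systole):
        # no test, by convention p = 1 when the difference is identically 0
        stat_v <- NA_real_
        p_v <- if (sum(ok) && all(dd == 0)) 1 else NA_real_
      } else {
        tt <- stats::t.test(dd)
        stat_v <- unname(tt$statistic)
        p_v <- tt$p.value
      }
      post[[length(post) + 1L]] <-
        data.frame(measure = meas, position = pos, n = sum(ok),
                   mean_diff = if (sum(ok)) mean(dd) else NA_real_,
                   statistic = stat_v, p = p_v)
    }
  }
  post <- do.call(rbind, post)
  post$p_adj <- NA_real_
  for (meas in unique(post$measure)) {
    i <- which(post$measure == meas & !is.na(post$p))
    if (length(i)) post$p_adj[i] <- holm_bonferroni(post$p[i])$p_adj
  }
  rownames(post) <- NULL
  list(per_participant = agg, group = group, posthoc = post)
}

#' Group-level circular summary of touch events
#'
#' Second-level circular analysis: one circular mean per participant per
#' cell (event type x condition, optionally x difficulty), then the group
#' circular mean and a Rayleigh uniformity test across participant means.
#' Per-difficulty p-values are Holm-corrected over the seven levels.
#'
#' @param trials phase-annotated trials (needs `onset_angle`, `hold_angle`,
#'   `offset_angle`).
#' @param by_level also test each difficulty level (gratings only).
#' @return data.frame with one row per cell: `condition`, `event_type`,
#'   `level`, `n` (participants), `mean_deg`, `resultant`, `z`, `p`,
#'   `p_adj` (within the 7-level families; `NA` for pooled cells).
#' @export
group_circular_summary <- function(trials, by_level = FALSE) {
  tr <- kept_trials(trials)
  ev_cols <- c(start = "onset_angle", hold = "hold_angle", end = "offset_angle")
  cell_row <- function(d, cond, ev, lev) {
    ang <- d[[ev_cols[[ev]]]]
    d <- d[!is.na(ang), ]
    means <- vapply(split(d[[ev_cols[[ev]]]], d$participant),
                    function(a) circular_mean(a)$mean_deg, numeric(1))
    means <- means[!is.na(means)]
    if (length(means) < 2) {
      return(data.frame(condition = cond, event_type = ev, level = lev,
                        n = length(means), mean_deg = NA_real_,
                        resultant = NA_real_, z = NA_real_, p = NA_real_))
    }
    rt <- rayleigh_test(means)
    data.frame(condition = cond, event_type = ev, level = lev,
               n = rt$n, mean_deg = rt$mean_deg, resultant = rt$resultant,
               z = rt$z, p = rt$p)
  }
  rows <- list()
  for (cond in unique(tr$condition)) {
    dc <- tr[tr$condition == cond, ]
    for (ev in names(ev_cols)) {
      rows[[length(rows) + 1L]] <- cell_row(dc, cond, ev, "all")
      if (by_level && cond == "gratings") {
        for (l in sort(unique(dc$level))) {
          rows[[length(rows) + 1L]] <- cell_row(dc[dc$level == l, ], cond, ev, l)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  if (by_level) {
    for (ev in unique(out$event_type)) {
      i <- which(out$event_type == ev & out$level != "all" &
                   out$condition == "gratings" & !is.na(out$p))
      if (length(i)) out$p_adj[i] <- holm_bonferroni(out$p[i])$p_adj
    }
  }
  rownames(out) <- NULL
  out
}
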