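# Heart-rate windowing and condition comparison.

#' Extract per-event heart-rate windows
#'
#' For every stimulus event, extracts three windows from the 1 Hz heart-rate
#' series: the 5 s stimulus window starting at onset, the 15 s post-stimulus
#' interval starting at offset, and the 15 s pre-stimulus interval ending at
#' onset (for the first event this is the final 15 s of the rest baseline).
#' Stimulus and post-ISI windows partition each event's 20 s with no overlap
#' and no gap.
#'
#' @param hr Data frame with columns `time_s`, `bpm` (1 Hz sampling).
#' @param protocol A `stim_protocol`.
#' @return Data frame with one row per event: `condition`, `event`, and
#'   `hr_mean` / `hr_max` for each of `stim`, `pre`, `post`.
#' @export
extract_hr_windows <- function(hr, protocol) {
  stopifnot(all(c("time_s", "bpm") %in% names(hr)))
  n <- nrow(hr)
  idx_of <- function(t) as.integer(round(t)) + 1L   # 1 Hz, t0 = 0
  out <- vector("list", nrow(protocol))
  for (e in seq_len(nrow(protocol))) {
    on <- protocol$onset_s[e]
    dur <- protocol$duration_s[e]
    isi <- attr(protocol, "isi_s")
    stim_i <- idx_of(on):(idx_of(on) + dur - 1L)
    post_i <- idx_of(on + dur):(idx_of(on + dur) + isi - 1L)
    pre_i <- (idx_of(on) - isi):(idx_of(on) - 1L)
    if (min(pre_i) < 1L || max(post_i) > n)
      stop(sprintf("event %d (%s at %.1f s): window outside heart-rate recording",
                   e, protocol$condition[e], on))
    out[[e]] <- data.frame(
      condition = protocol$condition[e], event = e,
      stim_mean = mean(hr$bpm[stim_i]), stim_max = max(hr$bpm[stim_i]),
      pre_mean = mean(hr$bpm[pre_i]), pre_max = max(hr$bpm[pre_i]),
      post_mean = mean(hr$bpm[post_i]), post_max = max(hr$bpm[post_i]))
  }
  do.call(rbind, out)
}

#' Aggregate heart-rate windows per condition
#'
#' Per condition, the across-event mean of the per-event window means and
#' maxima ("average maximal heart rate": the mean of the 15 per-event
#' maxima, not the maximum over all events).
#'
#' @param windows Per-event data frame from [extract_hr_windows()].
#' @param subject Optional subject label.
#' @return Data frame with one row per condition: `hrmean_stim`,
#'   `hrmax_stim`, `hrmean_pre`, `hrmax_pre`, `hrmean_post`, `hrmax_post`.
#' @export
aggregate_hr <- function(windows, subject = NA) {
  agg <- stats::aggregate(
    cbind(hrmean_stim = stim_mean, hrmax_stim = stim_max,
          hrmean_pre = pre_mean, hrmax_pre = pre_max,
          hrmean_post = post_mean, hrmax_post = post_max) ~ condition,
    data = windows, FUN = mean)
  cbind(subject = subject, agg)
}

#' Across-subject heart-rate summary table
#'
#' Mean, SD and SEM across subjects of the per-subject HRmean/HRmax
#' aggregates, per condition and window (stimulus, pre-ISI, post-ISI).
#'
#' @param summaries Stacked [aggregate_hr()] rows across subjects.
#' @return Data frame: `condition`, `window_kind`, `statistic`
#'   (`hr_mean`/`hr_max`), `mean`, `sd`, `sem`, `n`.
#' @export
hr_group_table <- function(summaries) {
  cols <- c(hrmean_stim = "stimulus.hr_mean", hrmax_stim = "stimulus.hr_max",
            hrmean_pre = "pre_isi.hr_mean", hrmax_pre = "pre_isi.hr_max",
            hrmean_post = "post_isi.hr_mean", hrmax_post = "post_isi.hr_max")
  out <- list()
  for (cn in unique(summaries$condition)) {
    s <- summaries[summaries$condition == cn, ]
    for (nm in names(cols)) {
      parts <- strsplit(cols[[nm]], ".", fixed = TRUE)[[1]]
      out[[length(out) + 1]] <- data.frame(
        condition = cn, window_kind = parts[1], statistic = parts[2],
        mean = mean(s[[nm]]), sd = stats::sd(s[[nm]]),
        sem = stats::sd(s[[nm]]) / sqrt(nrow(s)), n = nrow(s))
    }
  }
  do.call(rbind, out)
}

#' Compare stimulus and post-ISI heart rates across subjects
#'
#' Per condition, a paired Wilcoxon signed-rank test on the subject-level
#' difference HRmax(post-ISI) - HRmax(stimulus); the three p-values form one
#' BH-FDR family. A Friedman test across the three conditions on the
#' per-subject differences asks whether the stimuli differ in their
#' heart-rate effect. Subjects missing any condition are dropped.
#'
#' @param summaries Stacked [aggregate_hr()] rows across subjects (columns
#'   `subject`, `condition`, `hrmax_stim`, `hrmax_post`).
#' @param q_threshold FDR threshold (default 0.05).
#' @return List with `wilcoxon` (per-condition data frame incl. `q`),
#'   `friedman` (list), `n_subjects`, and `dropped` subject labels.
#' @export
compare_hr <- function(summaries, q_threshold = 0.05) {
  conds <- unique(summaries$condition)
  counts <- table(summaries$subject)
  keep <- names(counts)[counts == length(conds)]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " subject(s) with missing conditions")
  s <- summaries[summaries$subject %in% keep, ]
  if (length(keep) < 5) stop("need at least 5 complete subjects")
  diffs <- sapply(conds, function(cn) {
    sc <- s[s$condition == cn, ]
    sc <- sc[order(sc$subject), ]
    sc$hrmax_post - sc$hrmax_stim
  })
  rows <- lapply(seq_along(conds), function(i) {
    w <- wilcoxon_signed_rank(diffs[, i])
    data.frame(condition = conds[i], mean_diff_bpm = mean(diffs[, i]),
               p = w$p, z = w$z, n = w$n)
  })
  wil <- do.call(rbind, rows)
  f <- bh_fdr(wil$p, q_threshold)
  wil$q <- f$q; wil$significant <- f$significant
  fr <- friedman_test(diffs)
  list(wilcoxon = wil, friedman = fr, n_subjects = length(keep),
       dropped = dropped)
}
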