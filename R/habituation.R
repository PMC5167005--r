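# Habituation / sensitization screen: per-cell linear trend of the trial
# response amplitudes over the session.

#' Linear trend of trial response amplitudes
#'
#' Ordinary least-squares regression of the per-trial response amplitude on
#' the trial index (chronological order), with the two-sided t-test on the
#' slope. A significant positive slope is classified as sensitization
#' (growing response), a significant negative slope as habituation; anything
#' else as `"none"`. A constant input yields slope 0 and p = 1.
#'
#' @param trial_amplitudes Numeric vector of >= 5 amplitudes in
#'   chronological order.
#' @param alpha Significance level for the classification (default 0.05).
#' @return List with `slope`, `intercept`, `p`, `classification`.
#' @export
fit_trial_trend <- function(trial_amplitudes, alpha = 0.05) {
  y <- trial_amplitudes
  n <- length(y)
  if (n < 5) stop("need at least 5 trials")
  x <- seq_len(n)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  p <- if (rss <= .Machine$double.eps * sum(y^2) || rss == 0) {
    if (abs(slope) > 0) 0 else 1          # perfect line vs constant input
  } else {
    se <- sqrt(rss / (n - 2) / sxx)
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  classification <- if (p < alpha && slope > 0) "sensitization"
                    else if (p < alpha && slope < 0) "habituation"
                    else "none"
  list(slope = slope, intercept = intercept, p = p,
       classification = classification)
}

#' Habituation screen over a subject's trial tensor
#'
#' Fits [fit_trial_trend()] for every long channel, condition and
#' chromophore, using the same middle-2.5 s per-trial medians as the group
#' statistics. P-values are reported uncorrected (exploratory screen).
#'
#' @param tensor A preprocessed `trial_tensor` (or a [trial_scalars()] array).
#' @param layout A `probe_layout`.
#' @param subject Optional subject label carried into the result.
#' @param alpha Classification level (default 0.05).
#' @return Data frame: `subject`, `channel`, `condition`, `chromophore`,
#'   `slope`, `intercept`, `p`, `classification`.
#' @export
habituation_screen <- function(tensor, layout, subject = NA, alpha = 0.05) {
  sc <- if (inherits(tensor, "trial_tensor")) trial_scalars(tensor) else tensor
  conds <- dimnames(sc)[[3]]
  longs <- long_channels(layout)
  out <- expand.grid(channel = longs, condition = conds,
                     chromophore = CHROMOPHORES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- cbind(subject = subject, out)
  out$slope <- out$intercept <- out$p <- NA_real_
  out$classification <- NA_character_
  for (i in seq_len(nrow(out))) {
    v <- sc[, match(out$channel[i], layout$channels$id),
            out$condition[i], out$chromophore[i]]
    ft <- fit_trial_trend(v, alpha)
    out$slope[i] <- ft$slope; out$intercept[i] <- ft$intercept
    out$p[i] <- ft$p; out$classification[i] <- ft$classification
  }
  out
}

#' Summarise trend results across subjects
#'
#' Tabulates, per condition, how many subjects show at least one channel
#' with a significant positive (sensitization) or negative (habituation)
#' trend, and the per-subject counts of such channels. No group-level
#' inference is performed.
#'
#' @param results Data frame of stacked [habituation_screen()] outputs.
#' @return List with `per_subject` (counts of significant channels by sign,
#'   per subject and condition) and `per_condition` (numbers of subjects
#'   with >= 1 significant positive / negative channel).
#' @export
summarize_trends <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    empty <- data.frame(condition = character(0),
                        subjects_positive = integer(0),
                        subjects_negative = integer(0))
    return(list(per_subject = data.frame(), per_condition = empty))
  }
  results$sig_pos <- results$classification == "sensitization"
  results$sig_neg <- results$classification == "habituation"
  per_subject <- stats::aggregate(
    cbind(n_positive = sig_pos, n_negative = sig_neg) ~ subject + condition,
    data = results, FUN = sum)
  per_condition <- stats::aggregate(
    cbind(subjects_positive = n_positive > 0,
          subjects_negative = n_negative > 0) ~ condition,
    data = per_subject, FUN = sum)
  list(per_subject = per_subject, per_condition = per_condition)
}
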