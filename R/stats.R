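# Block/grand medians, responder classification, and the two-track
# nonparametric group analysis with Benjamini-Hochberg FDR control.

#' Sample indices of the middle 2.5 s response window
#'
#' The summary statistic of a segment is the median over the middle 2.5 s of
#' the 5 s stimulus, i.e. samples covering onset + 1.25 s to onset + 3.75 s,
#' offsets rounded to the nearest sample.
#'
#' @param segment_length Total samples in the segment.
#' @param fs Sampling rate in Hz.
#' @param stim_onset_index 1-based index of the first stimulus sample.
#' @return Integer vector of sample indices.
#' @examples
#' response_window_indices(99, 7.81, 31)   # 41..60 (20 samples)
#' @export
response_window_indices <- function(segment_length, fs, stim_onset_index) {
  idx <- stim_onset_index + seq.int(round(1.25 * fs), round(3.75 * fs))
  if (min(idx) < 1 || max(idx) > segment_length)
    stop("response window outside segment")
  idx
}

#' Median block average per channel and condition
#'
#' For every (channel, condition, chromophore) cell, the block-average trace
#' is the per-sample median across the trials; the response scalar is the
#' median of that trace over the middle 2.5 s of the stimulus window.
#'
#' @param tensor A fully preprocessed `trial_tensor`.
#' @return List with `traces` (array `[sample, channel, condition,
#'   chromophore]`), `scalars` (array `[channel, condition, chromophore]`)
#'   and the response-window indices used.
#' @export
block_average <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$data)
  if (d[2] < 3) stop("fewer than 3 trials per condition")
  # median across the trial dimension
  X <- aperm(tensor$data, c(2, 1, 3, 4, 5))
  traces <- array(col_medians(matrix(X, nrow = d[2])),
                  dim = d[c(1, 3, 4, 5)],
                  dimnames = dimnames(tensor$data)[c(1, 3, 4, 5)])
  rw <- response_window_indices(d[1], tensor$fs, tensor$pre + 1L)
  W <- matrix(traces[rw, , , ], nrow = length(rw))
  scalars <- array(col_medians(W), dim = d[c(3, 4, 5)],
                   dimnames = dimnames(tensor$data)[c(3, 4, 5)])
  list(traces = traces, scalars = scalars, response_window = rw)
}

#' Per-trial response scalars
#'
#' The per-trial summary used for responder classification and the
#' habituation screen: the median of each single trial's samples over the
#' middle 2.5 s of the stimulus window.
#'
#' @param tensor A preprocessed `trial_tensor`.
#' @return Array `[trial, channel, condition, chromophore]`.
#' @export
trial_scalars <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$data)
  rw <- response_window_indices(d[1], tensor$fs, tensor$pre + 1L)
  W <- matrix(tensor$data[rw, , , , ], nrow = length(rw))
  array(col_medians(W), dim = d[2:5], dimnames = dimnames(tensor$data)[2:5])
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample (or paired) signed-rank test. Zero differences are
#' dropped (Wilcoxon's convention). Without ties and for n <= `exact_max`
#' the exact null distribution is used; otherwise the normal approximation
#' with tie correction and continuity correction. The standardised statistic
#' `z` is reported in either case (negative when the rank mass lies below
#' the null median).
#'
#' @param x Numeric vector (differences, or first sample if `y` given).
#' @param y Optional second sample for a paired test.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `p`, `statistic` (V, the positive-rank sum), `z`, `n`
#'   (after zero removal) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  dif <- if (is.null(y)) x else x - y
  dif <- dif[is.finite(dif)]
  dif <- dif[dif != 0]
  n <- length(dif)
  if (n == 0) {
    warning("all differences are zero; p set to 1")
    return(list(p = 1, statistic = NA_real_, z = 0, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(dif))
  V <- sum(r[dif > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu) / sqrt(sigma2)
  has_ties <- any(tie_tab > 1)
  if (!has_ties && n <= exact_max) {
    p <- if (V > mu) 2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
         else 2 * stats::psignrank(V, n)
    method <- "exact"
  } else {
    corr <- sign(V - mu) * 0.5
    zc <- (V - mu - corr) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(zc))
    method <- "normal"
  }
  list(p = min(1, p), statistic = V, z = z, n = n, method = method)
}

#' Classify responder cells at the single-subject level
#'
#' A (channel, condition, chromophore) cell is a responder when the Wilcoxon
#' signed-rank test of its per-trial response scalars against zero is
#' significant at the (uncorrected, two-sided) single-subject level.
#'
#' @param tensor A preprocessed `trial_tensor`, or an array of per-trial
#'   scalars as returned by [trial_scalars()].
#' @param layout A `probe_layout`; only long channels are classified.
#' @param alpha_single Single-subject significance level (default 0.05).
#' @return Data frame: `channel`, `condition`, `chromophore`, `p`,
#'   `is_responder`.
#' @export
classify_responders <- function(tensor, layout, alpha_single = 0.05) {
  sc <- if (inherits(tensor, "trial_tensor")) trial_scalars(tensor) else tensor
  d <- dim(sc)
  conds <- dimnames(sc)[[3]]
  longs <- long_channels(layout)
  out <- expand.grid(channel = longs, condition = conds,
                     chromophore = CHROMOPHORES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- sc[, match(out$channel[i], layout$channels$id),
            out$condition[i], out$chromophore[i]]
    res <- if (all(v == 0)) list(p = 1)
           else wilcoxon_signed_rank(v)
    out$p[i] <- res$p
  }
  out$is_responder <- out$p < alpha_single
  out
}

#' Friedman test across the three conditions
#'
#' Rank-based test for a condition main effect on a subjects-by-conditions
#' matrix of response scalars; mid-ranks for ties with the usual tie
#' correction, p from the chi-squared distribution with k - 1 degrees of
#' freedom. Incomplete rows are dropped.
#'
#' @param m Numeric matrix, subjects x conditions.
#' @return List with `chi2`, `p`, `n` (complete rows used), `df`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("need at least 2 complete rows")
  ft <- stats::friedman.test(m)
  list(chi2 = unname(ft$statistic), p = ft$p.value, n = n, df = k - 1)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values for one family of p-values; `NA` entries (untestable
#' cells) are excluded from the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return List with `q` (same length as `p`) and `significant`
#'   (logical; `NA` where p was `NA`).
#' @export
bh_fdr <- function(p, q_threshold = 0.05) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(q = q, significant = q <= q_threshold)
}

#' Two-track group analysis
#'
#' For every long channel and chromophore: (a) a Friedman test across the
#' three conditions on the subjects' response scalars, (b) per-condition
#' Wilcoxon signed-rank tests of the scalars against zero, and (c) post hoc
#' paired Wilcoxon signed-rank tests for the three condition pairs. Each
#' test type is FDR-corrected across channels within its own family (one
#' family per test type x condition/pair x chromophore).
#'
#' Under `track = "All"` every subject contributes everywhere. Under
#' `track = "Responders"` a subject contributes to a channel x condition
#' cell only if classified a responder there (for the Friedman test: in all
#' three conditions; for a pairwise test: in both conditions of the pair).
#' Cells with fewer than `min_n` contributing subjects are marked missing
#' and excluded from their FDR family.
#'
#' @param scalars Data frame with columns `subject`, `channel`, `condition`,
#'   `chromophore`, `scalar` (one row per cell per subject), e.g. from
#'   [study_scalar_table()].
#' @param responders Data frame with columns `subject`, `channel`,
#'   `condition`, `chromophore`, `is_responder` (required for the
#'   Responders track).
#' @param track `"All"` or `"Responders"`.
#' @param layout A `probe_layout`.
#' @param q_threshold FDR threshold (default 0.05).
#' @param min_n Minimum subjects per testable cell (default 5).
#' @return List of data frames `friedman`, `vs_zero`, `posthoc`, each with
#'   uncorrected `p`, FDR `q`, the test statistic and `n`.
#' @export
run_group_analysis <- function(scalars, responders = NULL,
                               track = c("All", "Responders"),
                               layout = build_default_probe(),
                               q_threshold = 0.05, min_n = 5) {
  track <- match.arg(track)
  if (track == "Responders" && is.null(responders))
    stop("the Responders track requires a responder table")
  longs <- long_channels(layout)
  conds <- ordered_conditions(scalars$condition)
  pairs <- utils::combn(conds, 2, simplify = FALSE)

  cell_values <- function(ch, cr, cond) {
    rows <- scalars$channel == ch & scalars$chromophore == cr &
      scalars$condition == cond
    v <- scalars[rows, c("subject", "scalar")]
    if (track == "Responders") {
      rr <- responders[responders$channel == ch & responders$chromophore == cr &
                         responders$condition == cond & responders$is_responder, ]
      v <- v[v$subject %in% rr$subject, ]
    }
    v
  }

  friedman <- vs_zero <- posthoc <- list()
  for (cr in CHROMOPHORES) {
    for (ch in longs) {
      vals <- lapply(conds, function(cn) cell_values(ch, cr, cn))
      names(vals) <- conds
      # Friedman: subjects with all three conditions available
      common <- Reduce(intersect, lapply(vals, `[[`, "subject"))
      fr_row <- data.frame(channel = ch, chromophore = cr, track = track,
                           chi2 = NA_real_, p = NA_real_, n = length(common))
      if (length(common) >= min_n) {
        m <- sapply(vals, function(v) v$scalar[match(common, v$subject)])
        ft <- friedman_test(m)
        fr_row$chi2 <- ft$chi2; fr_row$p <- ft$p
      }
      friedman[[length(friedman) + 1]] <- fr_row
      for (cn in conds) {
        v <- vals[[cn]]
        zr <- data.frame(channel = ch, chromophore = cr, track = track,
                         condition = cn, p = NA_real_, z = NA_real_,
                         median = NA_real_, n = nrow(v))
        if (nrow(v) >= min_n) {
          w <- wilcoxon_signed_rank(v$scalar)
          zr$p <- w$p; zr$z <- w$z; zr$median <- stats::median(v$scalar)
        }
        vs_zero[[length(vs_zero) + 1]] <- zr
      }
      for (pr in pairs) {
        a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
        both <- intersect(a$subject, b$subject)
        ph <- data.frame(channel = ch, chromophore = cr, track = track,
                         pair = paste(pr, collapse = " vs "),
                         p = NA_real_, z = NA_real_, n = length(both))
        if (length(both) >= min_n) {
          w <- wilcoxon_signed_rank(a$scalar[match(both, a$subject)],
                                    b$scalar[match(both, b$subject)])
          ph$p <- w$p; ph$z <- w$z
        }
        posthoc[[length(posthoc) + 1]] <- ph
      }
    }
  }
  friedman <- do.call(rbind, friedman)
  vs_zero <- do.call(rbind, vs_zero)
  posthoc <- do.call(rbind, posthoc)

  # FDR within families: test type x chromophore (x condition or pair)
  friedman$q <- NA_real_; friedman$significant <- NA
  for (cr in CHROMOPHORES) {
    i <- friedman$chromophore == cr
    f <- bh_fdr(friedman$p[i], q_threshold)
    friedman$q[i] <- f$q; friedman$significant[i] <- f$significant
  }
  vs_zero$q <- NA_real_; vs_zero$significant <- NA
  for (cr in CHROMOPHORES) for (cn in conds) {
    i <- vs_zero$chromophore == cr & vs_zero$condition == cn
    f <- bh_fdr(vs_zero$p[i], q_threshold)
    vs_zero$q[i] <- f$q; vs_zero$significant[i] <- f$significant
  }
  posthoc$q <- NA_real_; posthoc$significant <- NA
  for (cr in CHROMOPHORES) for (pn in unique(posthoc$pair)) {
    i <- posthoc$chromophore == cr & posthoc$pair == pn
    f <- bh_fdr(posthoc$p[i], q_threshold)
    posthoc$q[i] <- f$q; posthoc$significant[i] <- f$significant
  }
  list(friedman = friedman, vs_zero = vs_zero, posthoc = posthoc)
}

#' Grand average across subjects with SEMed
#'
#' Per-sample median across subjects of the block-average traces, with the
#' standard error of the median estimated by a seeded bootstrap over
#' subjects (default) or by the Gaussian approximation `1.2533 * sd / sqrt(n)`.
#'
#' @param traces_by_subject List of per-subject trace arrays
#'   (`[sample, channel, condition, chromophore]`, from [block_average()]).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param method `"bootstrap"` or `"gaussian"`.
#' @return List with `median` and `semed` arrays of the per-subject shape,
#'   and `n_subjects`.
#' @export
grand_average <- function(traces_by_subject, n_boot = 1000, seed = 1,
                          method = c("bootstrap", "gaussian")) {
  method <- match.arg(method)
  ns <- length(traces_by_subject)
  d <- dim(traces_by_subject[[1]])
  X <- matrix(NA_real_, ns, prod(d))
  for (s in seq_len(ns)) X[s, ] <- as.numeric(traces_by_subject[[s]])
  med <- array(col_medians(X), dim = d, dimnames = dimnames(traces_by_subject[[1]]))
  semed <- if (method == "gaussian") {
    array(1.2533 * apply(X, 2, stats::sd) / sqrt(ns), dim = d,
          dimnames = dimnames(traces_by_subject[[1]]))
  } else {
    with_seed(seed, {
      acc <- matrix(0, 2, ncol(X))  # running sums for mean/variance
      for (b in seq_len(n_boot)) {
        mb <- col_medians(X[sample.int(ns, ns, replace = TRUE), , drop = FALSE])
        acc[1, ] <- acc[1, ] + mb
        acc[2, ] <- acc[2, ] + mb^2
      }
      v <- (acc[2, ] - acc[1, ]^2 / n_boot) / (n_boot - 1)
      array(sqrt(pmax(v, 0)), dim = d, dimnames = dimnames(traces_by_subject[[1]]))
    })
  }
  list(median = med, semed = semed, n_subjects = ns)
}
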