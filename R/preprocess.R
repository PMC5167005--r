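# Signal chain: Savitzky-Golay band-pass, segmentation, per-segment
# detrending, pre-stimulus median baselining, short-separation regression.

# Odd window length in samples for a window given in seconds.
sg_window_samples <- function(window_s, fs) {
  n <- as.integer(round(window_s * fs))
  if (n %% 2L == 0L) n <- n + 1L
  n
}

# Projection matrices of signal::sgolay are expensive to build for long
# windows; cache them per (order, window).
.sg_cache <- new.env(parent = emptyenv())

sg_projection <- function(p, n) {
  key <- paste(p, n, sep = "_")
  if (is.null(.sg_cache[[key]]))
    .sg_cache[[key]] <- unclass(signal::sgolay(p = p, n = n))
  .sg_cache[[key]]
}

# Savitzky-Golay smoothing of the columns of a matrix (samples x series).
# Interior samples by FFT convolution with the central projection row
# (kernel circularly centred so the output is index-aligned); the first/last
# half-windows by the terminal rows of the projection matrix, i.e.
# evaluation of the in-window polynomial fit (no reflection padding).
# `Xf`/`L` allow one forward FFT to be shared between several windows.
sg_smooth_mat <- function(X, n, p = 3, Xf = NULL, L = NULL) {
  ns <- nrow(X)
  if (n < p + 2) stop("SG window shorter than order + 2 samples")
  if (ns <= n) stop("series length must exceed the SG window")
  FPM <- sg_projection(p, n)
  k <- (n - 1L) %/% 2L
  h <- FPM[k + 1L, ]
  if (is.null(L)) L <- stats::nextn(ns + n, c(2, 3, 5))
  if (is.null(Xf))
    Xf <- stats::mvfft(rbind(X, matrix(0, L - ns, ncol(X))))
  hc <- numeric(L)
  hc[1:(k + 1L)] <- h[(k + 1L):n]
  hc[(L - k + 1L):L] <- h[1:k]
  S <- Re(stats::mvfft(Xf * stats::fft(hc), inverse = TRUE))[seq_len(ns), ,
                                                             drop = FALSE] / L
  # terminal windows: polynomial fit evaluated in-window
  S[1:k, ] <- FPM[1:k, , drop = FALSE] %*% X[1:n, , drop = FALSE]
  S[(ns - k + 1L):ns, ] <- FPM[(k + 2L):n, , drop = FALSE] %*%
    X[(ns - n + 1L):ns, , drop = FALSE]
  S
}

#' Savitzky-Golay band-pass filter
#'
#' Band-pass filtering as a difference of two third-degree Savitzky-Golay
#' smoothers: a short window (default 4 s) removes high-frequency noise and a
#' long window (default 80 s) estimates the slow physiological trend, which
#' is subtracted. Window lengths in seconds are converted to odd sample
#' counts (`round(s * fs)`, plus one if even; 31 and 625 samples at 7.81 Hz).
#' Recording edges are handled by evaluating the in-window polynomial fit
#' within the terminal window. A constant input, or any polynomial up to the
#' filter degree slower than the long window, is annihilated exactly.
#'
#' @param series A `channel_ts` (any kind; typically chromophore).
#' @param smooth_window_s Short smoothing window in seconds (default 4).
#' @param trend_window_s Trend window in seconds (default 80).
#' @param order Polynomial degree (default 3).
#' @return A `channel_ts` of the same shape.
#' @export
sg_bandpass <- function(series, smooth_window_s = 4, trend_window_s = 80,
                        order = 3) {
  stopifnot(inherits(series, "channel_ts"))
  d <- dim(series$values)
  n4 <- sg_window_samples(smooth_window_s, series$fs)
  n80 <- sg_window_samples(trend_window_s, series$fs)
  if (d[2] <= n80) stop("series shorter than the trend window")
  X <- matrix(aperm(series$values, c(2, 1, 3)), nrow = d[2])
  L <- stats::nextn(d[2] + n80, c(2, 3, 5))
  Xf <- stats::mvfft(rbind(X, matrix(0, L - d[2], ncol(X))))
  Y <- sg_smooth_mat(X, n4, order, Xf, L) - sg_smooth_mat(X, n80, order, Xf, L)
  out <- aperm(array(Y, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  dimnames(out) <- dimnames(series$values)
  channel_ts(out, fs = series$fs, t0 = series$t0, kind = series$kind)
}

#' Segment a recording into per-trial windows
#'
#' Cuts the filtered chromophore series into one segment per channel and
#' stimulus event: 3.9 s before onset (pre-stimulus part of the ISI), the 5 s
#' stimulus, and 3.9 s after offset. At 7.81 Hz this gives 30 + 39 + 30 = 99
#' samples; onsets are mapped to the nearest sample.
#'
#' @param series A `channel_ts` of kind `"chromophore"`.
#' @param protocol A `stim_protocol`.
#' @param pre_s,post_s Pre-/post-stimulus window lengths in seconds.
#' @return A `trial_tensor`: list with `data` (array
#'   `[sample, trial, channel, condition, chromophore]`), window sample
#'   counts `pre`/`stim`/`post`, `fs` and provenance `flags`.
#' @export
segment <- function(series, protocol, pre_s = 3.9, post_s = 3.9) {
  stopifnot(inherits(series, "channel_ts"), inherits(protocol, "stim_protocol"))
  fs <- series$fs
  npre <- n_samples(pre_s, fs)
  nstim <- n_samples(protocol$duration_s[1], fs)
  npost <- n_samples(post_s, fs)
  nseg <- npre + nstim + npost
  ns <- dim(series$values)[2]
  nch <- dim(series$values)[1]
  conds <- attr(protocol, "conditions") %||% unique(protocol$condition)
  n_trial <- max(table(factor(protocol$condition, levels = conds)))
  onset_idx <- as.integer(round(protocol$onset_s * fs)) + 1L
  for (e in seq_len(nrow(protocol))) {
    lo <- onset_idx[e] - npre
    hi <- onset_idx[e] + nstim + npost - 1L
    if (lo < 1L || hi > ns)
      stop(sprintf("event %d (%s at %.1f s) extends outside the recording",
                   e, protocol$condition[e], protocol$onset_s[e]))
  }
  data <- array(NA_real_, dim = c(nseg, n_trial, nch, length(conds), 2),
                dimnames = list(NULL, NULL, NULL, conds, CHROMOPHORES))
  trial_counter <- stats::setNames(integer(length(conds)), conds)
  rel <- seq.int(-npre, nstim + npost - 1L)
  for (e in seq_len(nrow(protocol))) {
    cn <- protocol$condition[e]
    trial_counter[[cn]] <- trial_counter[[cn]] + 1L
    idx <- onset_idx[e] + rel
    for (cr in 1:2)
      data[, trial_counter[[cn]], , cn, cr] <- t(series$values[, idx, cr])
  }
  structure(list(data = data, pre = npre, stim = nstim, post = npost,
                 fs = fs, conditions = conds,
                 flags = list(detrended = FALSE, baselined = FALSE,
                              ssr_applied = FALSE)),
            class = "trial_tensor")
}

#' Detrend and baseline every segment
#'
#' Per segment: subtracts the ordinary least-squares line fitted over the
#' full segment (removing slow within-segment drift), then subtracts the
#' median of the pre-stimulus samples, so that every segment's pre-stimulus
#' median is exactly zero.
#'
#' @param tensor A `trial_tensor` (not yet baselined).
#' @return The detrended and baselined `trial_tensor`.
#' @export
detrend_and_baseline <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (tensor$flags$baselined) stop("tensor is already baselined")
  d <- dim(tensor$data)
  nseg <- d[1]
  X <- matrix(tensor$data, nrow = nseg)
  tt <- seq_len(nseg)
  Tm <- cbind(1, tt)
  beta <- solve(crossprod(Tm), crossprod(Tm, X))   # 2 x m OLS coefficients
  X <- X - Tm %*% beta
  med_pre <- col_medians(X[seq_len(tensor$pre), , drop = FALSE])
  X <- sweep(X, 2, med_pre, "-")
  tensor$data <- array(X, dim = d, dimnames = dimnames(tensor$data))
  tensor$flags$detrended <- TRUE
  tensor$flags$baselined <- TRUE
  tensor
}

#' Short-separation regression of one segment
#'
#' Least-squares removal of a scaled short-channel segment from a
#' long-channel segment: `alpha = <long, short> / <short, short>`,
#' `corrected = long - alpha * short`. The corrected segment is orthogonal
#' to the short-channel segment. A flat short channel yields `alpha = 0`
#' (with a warning) and leaves the long channel untouched.
#'
#' @param long_segment,short_segment Equal-length numeric vectors.
#' @return List with `corrected` (numeric vector) and `alpha` (scalar).
#' @export
short_separation_regress <- function(long_segment, short_segment) {
  stopifnot(length(long_segment) == length(short_segment))
  ss <- sum(short_segment^2)
  if (ss == 0) {
    warning("short-channel segment is identically zero; alpha set to 0")
    return(list(corrected = long_segment, alpha = 0))
  }
  alpha <- sum(long_segment * short_segment) / ss
  list(corrected = long_segment - alpha * short_segment, alpha = alpha)
}

#' Apply short-separation regression across a trial tensor
#'
#' Replaces every long-channel segment by its SSR-corrected version, using
#' the time-aligned segment of the short channel mapped to it in the probe
#' layout (channels 1, 3-6 against channel 2; channels 7-9, 11-18 against
#' channel 10). The scaling factor is estimated per (segment, chromophore),
#' separately for oxy- and deoxyhemoglobin; short channels are retained
#' untouched.
#'
#' @param tensor A detrended and baselined `trial_tensor`.
#' @param layout A `probe_layout`.
#' @param scope `"recording"` (default) estimates one alpha per
#'   (channel, chromophore) across all concatenated segments, as in the
#'   original short-separation regression formulation; `"segment"` estimates
#'   one alpha per (segment, chromophore). With 99-sample segments and a
#'   temporally smooth superficial signal, per-segment least squares also
#'   projects out part of the evoked cerebral response (the regressor spans
#'   few effective degrees of freedom), so the recording-wide estimate is the
#'   default.
#' @return The corrected `trial_tensor`, with the estimated alphas in
#'   `$alphas` (array `[trial, channel, condition, chromophore]`).
#' @export
apply_ssr <- function(tensor, layout, scope = c("recording", "segment")) {
  stopifnot(inherits(tensor, "trial_tensor"))
  scope <- match.arg(scope)
  d <- dim(tensor$data)
  nch <- d[3]
  if (nch != nrow(layout$channels))
    stop("tensor channel count does not match layout")
  alphas <- array(NA_real_, dim = d[c(2, 3, 4, 5)],
                  dimnames = dimnames(tensor$data)[c(2, 3, 4, 5)])
  ids <- layout$channels$id
  for (key in names(layout$ssr_map)) {
    li <- match(as.integer(key), ids)
    si <- match(layout$ssr_map[[key]], ids)
    if (is.na(si) || all(is.na(tensor$data[, , si, , ])))
      stop("missing short-channel segments for channel ", key)
    L <- tensor$data[, , li, , , drop = FALSE]
    S <- tensor$data[, , si, , , drop = FALSE]
    if (scope == "segment") {
      num <- colSums(L * S)                 # [trial, 1, cond, chrom]
      den <- colSums(S * S)
      a <- ifelse(den == 0, 0, num / den)
      if (any(den == 0))
        warning("flat short-channel segment(s) for channel ", key,
                "; alpha set to 0")
    } else {
      num <- apply(L * S, c(5), sum)
      den <- apply(S * S, c(5), sum)
      a_ch <- ifelse(den == 0, 0, num / den)
      a <- array(rep(a_ch, each = prod(d[c(2, 4)])), dim = dim(colSums(L)))
    }
    tensor$data[, , li, , ] <- L - sweep(S, 2:5, a, "*")
    alphas[, li, , ] <- a
  }
  tensor$alphas <- alphas
  tensor$flags$ssr_applied <- TRUE
  tensor
}

#' Full single-subject preprocessing chain
#'
#' Runs the complete signal chain on a two-wavelength optical-density
#' recording: Beer-Lambert inversion with the age-dependent DPF,
#' Savitzky-Golay band-pass, segmentation, per-segment linear detrend,
#' pre-stimulus median baselining, and short-separation regression.
#'
#' @param od A `channel_ts` of kind `"optical_density"` (or `"intensity"`,
#'   which is first converted via [intensity_to_od()]).
#' @param layout A `probe_layout`.
#' @param protocol A `stim_protocol`.
#' @param age_years Subject age for the DPF (default 33.5).
#' @param smooth_window_s,trend_window_s,sg_order Band-pass settings.
#' @param pre_s,post_s Segmentation windows.
#' @param ssr_scope Alpha estimation scope, see [apply_ssr()].
#' @return A fully preprocessed `trial_tensor`.
#' @export
preprocess_subject <- function(od, layout, protocol, age_years = 33.5,
                               smooth_window_s = 4, trend_window_s = 80,
                               sg_order = 3, pre_s = 3.9, post_s = 3.9,
                               ssr_scope = "recording") {
  if (od$kind == "intensity")
    od <- intensity_to_od(od, baseline_s = attr(protocol, "baseline_s"))
  conc <- mbll_invert(od, layout, default_dpf(age_years))
  filt <- sg_bandpass(conc, smooth_window_s, trend_window_s, sg_order)
  tensor <- segment(filt, protocol, pre_s, post_s)
  tensor <- detrend_and_baseline(tensor)
  apply_ssr(tensor, layout, scope = ssr_scope)
}
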