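# Multichannel time-series container.

#' Construct a multichannel time series
#'
#' A `channel_ts` holds uniformly sampled multichannel data as a 3-d array
#' `[channel, sample, layer]`, where the third dimension is the wavelength
#' (for optical density, in nm) or the chromophore (for concentration
#' changes, `"O2Hb"`/`"HHb"`, in umol/L).
#'
#' @param values Numeric array `[channel, sample, layer]` with dimnames on
#'   the layer dimension.
#' @param fs Sampling rate in Hz (default 7.81).
#' @param t0 Start time in seconds.
#' @param kind One of `"intensity"`, `"optical_density"`, `"chromophore"`.
#' @return A `channel_ts` object.
#' @export
channel_ts <- function(values, fs = FS_DEFAULT, t0 = 0,
                       kind = c("optical_density", "chromophore", "intensity")) {
  kind <- match.arg(kind)
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("channel_ts values must all be finite")
  structure(list(values = values, fs = fs, t0 = t0, kind = kind),
            class = "channel_ts")
}

#' @export
print.channel_ts <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<channel_ts> %s: %d channels x %d samples x %d layers (%s), %.4g Hz, %.4g s\n",
              x$kind, d[1], d[2], d[3],
              paste(dimnames(x$values)[[3]], collapse = ", "),
              x$fs, d[2] / x$fs))
  invisible(x)
}

#' Number of samples for a duration at a sampling rate
#' @keywords internal
#' @noRd
n_samples <- function(duration_s, fs) as.integer(round(duration_s * fs))

#' Convert raw light intensity to optical density
#'
#' OD is defined as the negative decadic log of the detected intensity
#' relative to a reference intensity; the reference is the per-channel mean
#' intensity over the initial rest baseline.
#'
#' @param ts A `channel_ts` of kind `"intensity"` (strictly positive values).
#' @param baseline_s Length of the reference window in seconds (default 300).
#' @return A `channel_ts` of kind `"optical_density"`.
#' @export
intensity_to_od <- function(ts, baseline_s = 300) {
  stopifnot(inherits(ts, "channel_ts"), ts$kind == "intensity")
  if (any(ts$values <= 0)) stop("intensity values must be strictly positive")
  nb <- max(1L, min(dim(ts$values)[2], n_samples(baseline_s, ts$fs)))
  ref <- apply(ts$values[, seq_len(nb), , drop = FALSE], c(1, 3), mean)
  od <- -log10(sweep(ts$values, c(1, 3), ref, "/"))
  channel_ts(od, fs = ts$fs, t0 = ts$t0, kind = "optical_density")
}
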