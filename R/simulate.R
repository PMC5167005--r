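# Synthetic-data generator: forward model of the study's recordings.
#
# The generator emulates, per subject: condition-dependent cerebral
# hemodynamic responses in the two ROIs, a condition-dependent superficial
# (scalp) component shared within each ROI, slow drift, cardiac/respiratory/
# Mayer-wave oscillations and white measurement noise, projected to optical
# densities through the forward Beer-Lambert relation; plus a 1 Hz heart-rate
# series with a stimulus-locked transient.

#' Default simulation parameters
#'
#' Returns the simulator's free parameters. The defaults encode the study
#' conditions: cerebral oxyhemoglobin response amplitudes ordered
#' PAPain > PA30 > Brush (= 0) in both ROIs, a deoxyhemoglobin response at
#' -25% of the oxyhemoglobin amplitude, a superficial scalp component whose
#' task-locked amplitude is largest for the painful condition and negligible
#' for brushing, physiological oscillators below the 3.9 Hz Nyquist limit,
#' slow drift and white optical-density noise. Amplitudes are in umol/L,
#' oscillator/drift/noise levels in optical-density units.
#'
#' @param seed Integer seed; fully determines the simulated recording.
#' @param ... Named overrides of any default field.
#' @return A list of simulation parameters (`sim_params`).
#' @export
default_sim_params <- function(seed = 1, ...) {
  p <- list(
    sampling_rate_hz = FS_DEFAULT,
    # cerebral O2Hb response amplitude (umol/L) by condition x ROI
    hrf_amplitude = matrix(c(0.27, 0.30,   # PAPain: SMA, S1
                             0.20, 0.22,   # PA30
                             0.00, 0.00),  # Brush
                           nrow = 3, byrow = TRUE,
                           dimnames = list(CONDITIONS, c("SMA", "S1"))),
    hhb_ratio = -0.25,          # cerebral HHb amplitude as fraction of O2Hb
    hrf_peak_s = 4,             # main response peak, within the stimulus window
    hrf_width = 0.8,            # gamma dispersion of the main bump (s)
    hrf_undershoot_s = 10,
    hrf_undershoot_ratio = 0.05,
    # superficial (scalp) component, shared within each ROI
    scalp_amplitude = c(PAPain = 0.35, PA30 = 0.18, Brush = 0.02),
    scalp_hhb_ratio = 0.1,
    scalp_peak_s = 2.5,         # scalp blood-flow response is faster
    scalp_width = 0.5,          # gamma dispersion of the scalp response (s)
    # spontaneous superficial fluctuations, shared within each ROI (umol/L):
    # Mayer waves, respiration, and a slow AR(1) component
    scalp_mayer = c(freq_hz = 0.095, amp = 0.35, freq_jitter = 0.10),
    scalp_resp = c(freq_hz = 0.25, amp = 0.45, freq_jitter = 0.10),
    scalp_fluct_sd = 0.15,      # slow AR(1) scalp fluctuation, umol/L
    scalp_fluct_ar = 0.94,      # AR(1) coefficient of the fluctuation
    # inter-subject / inter-trial variability (lognormal sd on log scale)
    subject_gain_sd = 0.25,
    cond_gain_sd = 0.25,        # per subject x condition
    channel_gain_sd = 0.15,
    trial_gain_sd = 0.30,
    # per-channel nuisance oscillators in OD space (non-shared physiology:
    # cardiac pulsatility plus small residual respiratory/Mayer components)
    oscillators = data.frame(
      freq_hz = c(1.10, 0.25, 0.095),
      amp_od = c(8e-4, 2e-4, 2e-4),
      freq_jitter = c(0.05, 0.10, 0.10)),
    drift_slope_sd = 2e-5,      # OD per second, per channel/wavelength
    drift_rw_sd = 1e-5,         # OD random-walk step per sample
    noise_sd = 1.5e-3,          # white OD noise
    subject_age_years = 33.5,
    # heart rate
    hr_baseline_bpm = 65,
    hr_transient_amp = 3,       # bpm, condition-independent
    hr_transient_peak_s = 7,    # peaks after stimulus offset (post-ISI)
    hr_noise_sd = 1.5,
    seed = seed
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(p)) stop("unknown simulation parameter: ", nm)
    p[[nm]] <- overrides[[nm]]
  }
  structure(p, class = "sim_params")
}

#' Parameters emulating the study's reported effect structure
#'
#' Both pressure conditions carry equal, moderate cerebral amplitudes while
#' brushing is null, and the superficial scalp component keeps its default
#' ordering (largest for painful pressure). Under this configuration the
#' group analysis is expected to reproduce the study's qualitative pattern:
#' pressure conditions significant against zero after FDR, brushing not,
#' pressure-vs-brush contrasts significant, pain-vs-nonpainful not.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [default_sim_params()].
#' @export
pattern_sim_params <- function(seed = 1, ...) {
  default_sim_params(
    seed = seed,
    hrf_amplitude = matrix(c(0.12, 0.14,
                             0.12, 0.14,
                             0.00, 0.00),
                           nrow = 3, byrow = TRUE,
                           dimnames = list(CONDITIONS, c("SMA", "S1"))),
    ...
  )
}

#' Parameters with all task effects and nuisance signals switched off
#' except white noise (for null-calibration simulations).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [default_sim_params()].
#' @export
null_sim_params <- function(seed = 1, ...) {
  default_sim_params(
    seed = seed,
    hrf_amplitude = matrix(0, 3, 2, dimnames = list(CONDITIONS, c("SMA", "S1"))),
    scalp_amplitude = c(PAPain = 0, PA30 = 0, Brush = 0),
    ...
  )
}

# Gamma-shaped unit-peak impulse response: peak at `peak_s`, dispersion `b`.
gamma_bump <- function(t, peak_s, b = 0.9) {
  a <- peak_s / b
  g <- ifelse(t <= 0, 0, exp(a * log(pmax(t, 1e-12) / peak_s) + (peak_s - t) / b))
  g
}

# Event-response kernel: canonical double-gamma shape (main bump peaking
# near the stimulus offset, small late undershoot), unit peak. The evoked
# response per event is amplitude x this kernel.
hrf_event_kernel <- function(fs, peak_s = 4, width = 0.8, undershoot_s = 10,
                             undershoot_ratio = 0.05, span_s = 30) {
  t <- seq(0, span_s, by = 1 / fs)
  k <- gamma_bump(t, peak_s, b = width) -
    undershoot_ratio * gamma_bump(t, undershoot_s, b = 0.8)
  k / max(k)
}

# Faster, undershoot-free kernel for the superficial (scalp) response.
scalp_event_kernel <- function(fs, peak_s = 2.5, width = 0.5, span_s = 20) {
  t <- seq(0, span_s, by = 1 / fs)
  k <- gamma_bump(t, peak_s, b = width)
  k / max(k)
}

# Convolve per-condition impulse trains (gains at onset samples) with an
# event kernel, all conditions in one padded FFT batch.
event_trains <- function(n, onset_idx, gains, condition, conds, kernel) {
  L <- stats::nextn(n + length(kernel), c(2, 3, 5))
  U <- matrix(0, L, length(conds))
  for (j in seq_along(conds)) {
    sel <- condition == conds[j]
    U[onset_idx[sel], j] <- gains[sel]
  }
  Hf <- stats::fft(c(kernel, numeric(L - length(kernel))))
  S <- Re(stats::mvfft(stats::mvfft(U) * Hf, inverse = TRUE)) / L
  colnames(S) <- conds
  S[seq_len(n), , drop = FALSE]
}

#' Simulate a two-wavelength optical-density recording
#'
#' Forward-simulates one subject's recording for a given probe layout and
#' stimulus protocol. Cerebral responses (amplitude x canonical double-gamma
#' event response) are placed on the long channels of each ROI; the
#' superficial component (task-locked scalp response plus a shared
#' spontaneous fluctuation) is placed identically on *all* channels of an
#' ROI, including its short channel, which carries no cerebral term.
#' Chromophore signals are projected to optical density through
#' [forward_mbll()]; oscillators, drift and white noise are added in OD
#' space. The output is fully reproducible from `params$seed`.
#'
#' @param layout A `probe_layout`.
#' @param protocol A `stim_protocol`.
#' @param params A `sim_params` list, see [default_sim_params()].
#' @return List with elements `od` (`channel_ts`, optical density) and
#'   `truth` (list: `cerebral` and `superficial` chromophore `channel_ts`,
#'   `protocol`, `params`).
#' @export
simulate_recording <- function(layout, protocol, params = default_sim_params()) {
  fs <- params$sampling_rate_hz
  if (any(protocol$duration_s <= 0)) stop("negative or zero stimulus duration")
  if (any(params$oscillators$freq_hz >= fs / 2))
    stop("oscillator frequency at or above Nyquist (", fs / 2, " Hz)")
  n <- n_samples(attr(protocol, "total_s"), fs)
  nch <- nrow(layout$channels)
  t <- (seq_len(n) - 1) / fs
  onset_idx <- as.integer(round(protocol$onset_s * fs)) + 1L
  if (any(onset_idx < 1 | onset_idx > n)) stop("event onset outside recording")
  conds <- rownames(params$hrf_amplitude)
  rois <- layout$channels$roi
  is_short <- layout$channels$is_short

  with_seed(params$seed, {
    n_ev <- nrow(protocol)
    trial_gain <- stats::rlnorm(n_ev, -params$trial_gain_sd^2 / 2, params$trial_gain_sd)
    g_subj <- stats::rlnorm(1, -params$subject_gain_sd^2 / 2, params$subject_gain_sd)
    g_cond <- stats::setNames(
      stats::rlnorm(length(conds), -params$cond_gain_sd^2 / 2, params$cond_gain_sd), conds)
    g_chan <- stats::rlnorm(nch, -params$channel_gain_sd^2 / 2, params$channel_gain_sd)

    hrf_k <- hrf_event_kernel(fs, params$hrf_peak_s, params$hrf_width,
                              params$hrf_undershoot_s, params$hrf_undershoot_ratio)
    scalp_k <- scalp_event_kernel(fs, params$scalp_peak_s, params$scalp_width)

    shape_hrf <- event_trains(n, onset_idx, trial_gain, protocol$condition,
                              conds, hrf_k)
    shape_scalp <- event_trains(n, onset_idx, trial_gain, protocol$condition,
                                conds, scalp_k)

    # cerebral response per ROI (umol/L O2Hb)
    resp_roi <- sapply(c("SMA", "S1"), function(r) {
      out <- numeric(n)
      for (cn in conds)
        out <- out + g_cond[[cn]] * params$hrf_amplitude[cn, r] * shape_hrf[, cn]
      out
    })
    cerebral <- array(0, c(nch, n, 2), dimnames = list(NULL, NULL, CHROMOPHORES))
    for (i in seq_len(nch)) {
      if (is_short[i]) next
      o2 <- g_subj * g_chan[i] * resp_roi[, rois[i]]
      cerebral[i, , "O2Hb"] <- o2
      cerebral[i, , "HHb"] <- params$hhb_ratio * o2
    }

    # superficial component, identical on every channel of an ROI
    superficial <- array(0, c(nch, n, 2), dimnames = list(NULL, NULL, CHROMOPHORES))
    for (r in c("SMA", "S1")) {
      task <- numeric(n)
      for (cn in conds)
        task <- task + params$scalp_amplitude[[cn]] * shape_scalp[, cn]
      task <- g_subj * task
      fluct <- numeric(n)
      if (params$scalp_fluct_sd > 0) {
        ar <- params$scalp_fluct_ar
        innov_sd <- params$scalp_fluct_sd * sqrt(1 - ar^2)
        fluct <- fluct + as.numeric(stats::filter(
          stats::rnorm(n, 0, innov_sd), ar, method = "recursive"))
      }
      for (osc in list(params$scalp_mayer, params$scalp_resp)) {
        if (osc[["amp"]] == 0) next
        f <- osc[["freq_hz"]] * (1 + stats::rnorm(1, 0, osc[["freq_jitter"]]))
        fluct <- fluct + osc[["amp"]] * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
      sup_o2 <- task + fluct
      for (i in which(rois == r)) {
        superficial[i, , "O2Hb"] <- sup_o2
        superficial[i, , "HHb"] <- params$scalp_hhb_ratio * sup_o2
      }
    }

    dpf <- default_dpf(params$subject_age_years)
    total <- channel_ts(cerebral + superficial, fs = fs, kind = "chromophore")
    od <- forward_mbll(total, layout, dpf)

    # nuisance signals in OD space
    nuis <- matrix(0, nch, n)
    for (j in seq_len(nrow(params$oscillators))) {
      f0 <- params$oscillators$freq_hz[j]
      amp <- params$oscillators$amp_od[j]
      if (amp == 0) next
      jit <- params$oscillators$freq_jitter[j]
      f_ch <- f0 * (1 + stats::rnorm(nch, 0, jit))
      phi <- stats::runif(nch, 0, 2 * pi)
      nuis <- nuis + amp * sin(outer(2 * pi * f_ch, t) + phi)
    }
    odv <- od$values
    for (w in 1:2) {
      slope <- stats::rnorm(nch, 0, params$drift_slope_sd)
      drift <- outer(slope, t)
      if (params$drift_rw_sd > 0)
        drift <- drift + t(apply(matrix(stats::rnorm(nch * n, 0, params$drift_rw_sd),
                                        nch, n), 1, cumsum))
      noise <- if (params$noise_sd > 0)
        matrix(stats::rnorm(nch * n, 0, params$noise_sd), nch, n) else 0
      odv[, , w] <- odv[, , w] + nuis + drift + noise
    }

    list(
      od = channel_ts(odv, fs = fs, kind = "optical_density"),
      truth = list(
        cerebral = channel_ts(cerebral, fs = fs, kind = "chromophore"),
        superficial = channel_ts(superficial, fs = fs, kind = "chromophore"),
        protocol = protocol,
        params = params
      )
    )
  })
}

#' Simulate a 1 Hz heart-rate series
#'
#' Baseline heart rate plus a condition-independent stimulus-locked transient
#' peaking `hr_transient_peak_s` seconds after stimulus onset (i.e. inside
#' the post-stimulus interval) and smooth AR(1) noise. Values are clamped to
#' the physiological range (25, 250) bpm.
#'
#' @param protocol A `stim_protocol`.
#' @param params A `sim_params` list.
#' @param seed Seed (defaults to `params$seed + 1`).
#' @return Data frame with columns `time_s`, `bpm` (1 Hz sampling).
#' @export
simulate_heart_rate <- function(protocol, params = default_sim_params(),
                                seed = params$seed + 1) {
  n <- as.integer(ceiling(attr(protocol, "total_s")))
  t <- seq_len(n) - 1
  kern_t <- 0:25
  kern <- gamma_bump(kern_t, params$hr_transient_peak_s, b = 1.6)
  kern <- kern / max(kern)
  with_seed(seed, {
    u <- numeric(n)
    u[pmin(n, as.integer(round(protocol$onset_s)) + 1L)] <- 1
    transient <- stats::convolve(u, rev(kern), type = "open")[seq_len(n)]
    noise <- as.numeric(stats::filter(
      stats::rnorm(n, 0, params$hr_noise_sd * sqrt(1 - 0.8^2)), 0.8,
      method = "recursive"))
    bpm <- params$hr_baseline_bpm + params$hr_transient_amp * transient + noise
    data.frame(time_s = t, bpm = pmin(249, pmax(26, bpm)))
  })
}
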