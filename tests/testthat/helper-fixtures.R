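# Shared fixtures: all synthetic, built in code.

PROBE <- build_default_probe()
LONGS <- long_channels(PROBE)

# Parameters with every stochastic/nuisance term switched off.
zero_noise_overrides <- function() list(
  scalp_mayer = c(freq_hz = 0.095, amp = 0, freq_jitter = 0),
  scalp_resp = c(freq_hz = 0.25, amp = 0, freq_jitter = 0),
  scalp_fluct_sd = 0,
  subject_gain_sd = 0, cond_gain_sd = 0, channel_gain_sd = 0,
  trial_gain_sd = 0,
  oscillators = data.frame(freq_hz = 1, amp_od = 0, freq_jitter = 0),
  drift_slope_sd = 0, drift_rw_sd = 0, noise_sd = 0
)

clean_sim_params <- function(seed = 1, ...) {
  do.call(default_sim_params,
          c(list(seed = seed), zero_noise_overrides(), list(...)))
}

# A chromophore channel_ts with identical values in both layers.
conc_ts <- function(x, nch = 1, fs = 7.81) {
  arr <- array(rep(x, each = nch * 1), c(nch, length(x), 2))
  for (i in seq_len(nch)) for (cr in 1:2) arr[i, , cr] <- x
  dimnames(arr) <- list(NULL, NULL, c("O2Hb", "HHb"))
  channel_ts(arr, fs = fs, kind = "chromophore")
}

# Exact two-sided signed-rank p by full 2^n sign enumeration.
enumerate_signrank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}
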