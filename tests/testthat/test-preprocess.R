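test_that("SG band-pass annihilates constants and in-window cubics", {
  t <- (0:5999) / 7.81
  const <- conc_ts(rep(2.5, 6000))
  expect_lt(max(abs(sg_bandpass(const)$values)), 1e-10)
  tc <- t / max(t) - 0.5
  cubic <- conc_ts(1 + 2 * tc - 3 * tc^2 + 4 * tc^3)
  out <- sg_bandpass(cubic)
  expect_lt(max(abs(out$values)) / max(abs(cubic$values)), 1e-6)
})

test_that("SG band-pass frequency response matches its computed profile", {
  fs <- 7.81
  gain <- function(f) {
    x <- sin(2 * pi * f * (0:12000) / fs)
    y <- sg_bandpass(conc_ts(x))$values[1, , 1]
    i <- 3000:9000
    sqrt(sum(y[i]^2) / sum(x[i]^2))
  }
  expect_lt(gain(0.01), 0.2)    # slow drift band: attenuated >= 80%
  expect_gt(gain(0.08), 0.85)   # task band: passed
  expect_gt(gain(0.2), 0.85)
  expect_lt(gain(1.0), 0.05)    # cardiac band: suppressed
})

test_that("an evoked response keeps most of its peak through the band-pass", {
  k <- nirspine:::hrf_event_kernel(7.81)
  x <- numeric(6000)
  x[3000:(2999 + length(k))] <- k
  y <- sg_bandpass(conc_ts(x))$values[1, , 1]
  expect_gt(max(y) / max(x), 0.75)
})

test_that("segmentation yields 15 trials per condition with 99-sample segments", {
  proto <- generate_protocol(seed = 6)
  prm <- clean_sim_params(seed = 6)
  rec <- simulate_recording(PROBE, proto, prm)
  tens <- segment(rec$truth$cerebral, proto)
  expect_equal(dim(tens$data), c(99, 15, 18, 3, 2))
  expect_equal(tens$pre, 30)
  expect_equal(tens$stim, 39)
  expect_equal(tens$post, 30)
  expect_false(any(is.na(tens$data)))

  proto1 <- generate_protocol(1, 5, 15, 60, seed = 1)
  rec1 <- simulate_recording(PROBE, proto1, clean_sim_params())
  expect_equal(dim(segment(rec1$od, proto1)$data)[2], 1)

  proto_bad <- generate_protocol(1, 5, 15, 2, seed = 1)  # event at t = 2 s
  rec_bad <- simulate_recording(PROBE, proto_bad, clean_sim_params())
  expect_error(segment(rec_bad$od, proto_bad), "outside the recording")
})

test_that("detrending removes lines exactly and baselining zeroes the pre-stimulus median", {
  proto <- generate_protocol(2, 5, 15, 60, seed = 8)
  n <- nirspine:::n_samples(attr(proto, "total_s"), 7.81)
  line <- 0.7 + 0.01 * seq_len(n)
  tens <- detrend_and_baseline(segment(conc_ts(line), proto))
  expect_lt(max(abs(tens$data)), 1e-9)

  rec <- simulate_recording(PROBE, proto, default_sim_params(seed = 8))
  tens2 <- detrend_and_baseline(segment(mbll_invert(rec$od, PROBE), proto))
  pre_med <- apply(tens2$data[1:tens2$pre, , , , , drop = FALSE], 2:5, median)
  expect_lt(max(abs(pre_med)), 1e-12)
  expect_error(detrend_and_baseline(tens2), "already baselined")
})

test_that("detrend-and-baseline agrees with an independent lm() oracle on a step", {
  # a step of height h riding on a line: the OLS line absorbs part of the
  # step, leaving ~0.56 h in the mid-stimulus median (segment conventions)
  h <- 2
  seg <- 0.5 + 0.03 * (1:99) + c(rep(0, 30), rep(h, 69))
  proto <- generate_protocol(1, 5, 15, 30, seed = 1)
  n_total <- nirspine:::n_samples(attr(proto, "total_s"), 7.81)
  full <- c(rep(0.5, nirspine:::n_samples(30, 7.81) - 30), seg)
  full <- c(full, rep(0, n_total - length(full)))
  # oracle: explicit lm + median on the same segment
  fit <- stats::lm(seg ~ seq_len(99))
  d_ref <- seg - stats::fitted(fit)
  d_ref <- d_ref - stats::median(d_ref[1:30])
  tens <- detrend_and_baseline(segment(conc_ts(full), proto))
  expect_equal(tens$data[, 1, 1, proto$condition[1], "O2Hb"], unname(d_ref),
               tolerance = 1e-9)
  expect_equal(stats::median(d_ref[31:69]) / h, 0.558, tolerance = 0.01)
})

test_that("short-separation regression follows the least-squares geometry", {
  s <- sin(seq(0, 6 * pi, length.out = 99))
  res <- short_separation_regress(2 * s, s)
  expect_equal(res$alpha, 2)
  expect_lt(max(abs(res$corrected)), 1e-12)

  l <- cos(seq(0, 6 * pi, length.out = 99))
  l <- l - s * sum(l * s) / sum(s^2)   # orthogonalise
  res2 <- short_separation_regress(l, s)
  expect_equal(res2$alpha, 0, tolerance = 1e-12)
  expect_equal(res2$corrected, l)

  expect_warning(res3 <- short_separation_regress(l, rep(0, 99)), "zero")
  expect_equal(res3$alpha, 0)
  expect_equal(res3$corrected, l)
})

test_that("SSR maps each long channel to its ROI's short channel", {
  proto <- generate_protocol(2, 5, 15, 60, seed = 9)
  n <- nirspine:::n_samples(attr(proto, "total_s"), 7.81)
  arr <- array(0, c(18, n, 2), dimnames = list(NULL, NULL, c("O2Hb", "HHb")))
  sig_sma <- sin(2 * pi * 0.11 * (0:(n - 1)) / 7.81)
  sig_s1 <- cos(2 * pi * 0.13 * (0:(n - 1)) / 7.81)
  for (cr in 1:2) {
    arr[2, , cr] <- sig_sma          # SMA short channel
    arr[5, , cr] <- 3 * sig_sma      # proportional to channel 2 only
    arr[10, , cr] <- sig_s1
    arr[17, , cr] <- -2 * sig_s1     # proportional to channel 10 only
  }
  tens <- detrend_and_baseline(segment(channel_ts(arr, kind = "chromophore"), proto))
  out <- apply_ssr(tens, PROBE, scope = "segment")
  expect_lt(max(abs(out$data[, , 5, , ])), 1e-9)    # removed via channel 2
  expect_lt(max(abs(out$data[, , 17, , ])), 1e-9)   # removed via channel 10
  # short channels retained untouched
  expect_equal(out$data[, , 2, , ], tens$data[, , 2, , ])
  expect_equal(out$data[, , 10, , ], tens$data[, , 10, , ])
  expect_true(out$flags$ssr_applied)
})

test_that("a second SSR pass is a no-op (alphas ~ 0) under segment scope", {
  proto <- generate_protocol(2, 5, 15, 60, seed = 10)
  prm <- clean_sim_params(seed = 10, scalp_fluct_sd = 0.2)
  rec <- simulate_recording(PROBE, proto, prm)
  tens <- detrend_and_baseline(segment(mbll_invert(rec$od, PROBE), proto))
  once <- apply_ssr(tens, PROBE, scope = "segment")
  twice <- apply_ssr(once, PROBE, scope = "segment")
  expect_lt(max(abs(twice$alphas[, LONGS, , ])), 1e-10)
})

test_that("SSR cancels a shared superficial component exactly (noiseless short channel)", {
  proto <- generate_protocol(3, 5, 15, 80, seed = 11)
  prm <- clean_sim_params(seed = 11,
    hrf_amplitude = matrix(0, 3, 2, dimnames = list(c("PAPain", "PA30", "Brush"),
                                                    c("SMA", "S1"))),
    scalp_fluct_sd = 0.2,
    scalp_mayer = c(freq_hz = 0.095, amp = 0.3, freq_jitter = 0.1))
  rec <- simulate_recording(PROBE, proto, prm)
  tens <- detrend_and_baseline(segment(mbll_invert(rec$od, PROBE), proto))
  pre_var <- stats::var(as.numeric(tens$data[, , LONGS, , ]))
  for (scope in c("recording", "segment")) {
    out <- apply_ssr(tens, PROBE, scope = scope)
    expect_lt(stats::var(as.numeric(out$data[, , LONGS, , ])), 0.01 * pre_var)
  }
})

test_that("SSR does not increase the aggregate error against the cerebral truth", {
  proto <- generate_protocol(5, 5, 15, 100, seed = 12)
  prm <- clean_sim_params(seed = 12, scalp_fluct_sd = 0.15,
    scalp_mayer = c(freq_hz = 0.095, amp = 0.35, freq_jitter = 0.1),
    scalp_resp = c(freq_hz = 0.25, amp = 0.45, freq_jitter = 0.1))
  rec <- simulate_recording(PROBE, proto, prm)
  truth <- detrend_and_baseline(segment(rec$truth$cerebral, proto))
  tens <- detrend_and_baseline(segment(mbll_invert(rec$od, PROBE), proto))
  corrected <- apply_ssr(tens, PROBE)
  err <- function(x) sum((x$data[, , LONGS, , ] - truth$data[, , LONGS, , ])^2)
  expect_lte(err(corrected), err(tens))
})

test_that("the chain is linear in the input up to SSR", {
  proto <- generate_protocol(2, 5, 15, 60, seed = 13)
  rec <- simulate_recording(PROBE, proto, default_sim_params(seed = 13))
  pre <- function(od) {
    conc <- mbll_invert(od, PROBE)
    detrend_and_baseline(segment(sg_bandpass(conc), proto))$data
  }
  a <- pre(rec$od)
  scaled <- channel_ts(3 * rec$od$values, kind = "optical_density")
  b <- pre(scaled)
  expect_equal(b, 3 * a, tolerance = 1e-9)
})
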