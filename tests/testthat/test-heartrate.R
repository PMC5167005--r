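test_that("heart-rate windows partition each event with no overlap or gap", {
  proto <- generate_protocol(seed = 16)
  hr <- data.frame(time_s = 0:1199, bpm = seq_len(1200))  # unique values
  w <- extract_hr_windows(hr, proto)
  expect_equal(nrow(w), 45)
  for (e in c(1, 20, 45)) {
    on <- proto$onset_s[e]
    stim_vals <- hr$bpm[hr$time_s >= on & hr$time_s < on + 5]
    post_vals <- hr$bpm[hr$time_s >= on + 5 & hr$time_s < on + 20]
    pre_vals <- hr$bpm[hr$time_s >= on - 15 & hr$time_s < on]
    expect_equal(w$stim_mean[e], mean(stim_vals))
    expect_equal(w$stim_max[e], max(stim_vals))
    expect_equal(w$post_mean[e], mean(post_vals))
    expect_equal(w$post_max[e], max(post_vals))
    expect_equal(w$pre_mean[e], mean(pre_vals))
    # stimulus + post-ISI partition the 20 s exactly
    expect_equal(length(stim_vals) + length(post_vals), 20)
    expect_equal(max(w$stim_max[e], w$post_max[e]), max(hr$bpm[hr$time_s >= on & hr$time_s < on + 20]))
  }
  # first event's pre-ISI lies in the final 15 s of the baseline
  expect_equal(w$pre_mean[1], mean(hr$bpm[hr$time_s >= 285 & hr$time_s < 300]))
})

test_that("constant and spiked series give the expected window summaries", {
  proto <- generate_protocol(seed = 17)
  hr <- data.frame(time_s = 0:1199, bpm = rep(60, 1200))
  w <- extract_hr_windows(hr, proto)
  expect_true(all(w$stim_mean == 60 & w$stim_max == 60 &
                    w$post_mean == 60 & w$post_max == 60))
  expect_true(all(w$post_max >= w$post_mean))

  hr$bpm[proto$onset_s[7] + 9] <- 90   # inside event 7's post-ISI window
  w2 <- extract_hr_windows(hr, proto)
  expect_equal(w2$post_max[7], 90)
  expect_lt(w2$post_mean[7], 90)
  expect_equal(w2$stim_max[7], 60)

  short_hr <- hr[1:500, ]
  expect_error(extract_hr_windows(short_hr, proto), "outside")
})

test_that("a stimulus-locked transient makes post-ISI maxima exceed stimulus maxima", {
  proto <- generate_protocol(seed = 18)
  prm <- default_sim_params(seed = 18, hr_noise_sd = 0)
  hr <- simulate_heart_rate(proto, prm)
  agg <- aggregate_hr(extract_hr_windows(hr, proto), subject = "S01")
  expect_true(all(agg$hrmax_post > agg$hrmax_stim))
})

test_that("heart-rate comparison finds the post-vs-stimulus effect but no condition effect", {
  summaries <- list()
  for (s in 1:20) {
    proto <- generate_protocol(seed = 100 + s)
    prm <- default_sim_params(seed = 100 + s)
    hr <- simulate_heart_rate(proto, prm, seed = 200 + s)
    summaries[[s]] <- aggregate_hr(extract_hr_windows(hr, proto),
                                   subject = sprintf("S%02d", s))
  }
  cmp <- compare_hr(do.call(rbind, summaries))
  expect_true(all(cmp$wilcoxon$significant))
  expect_true(all(cmp$wilcoxon$mean_diff_bpm > 0))
  expect_gt(cmp$friedman$p, 0.05)
  expect_equal(cmp$n_subjects, 20)
})

test_that("the across-subject group table summarises every condition and window", {
  set.seed(12)
  summaries <- do.call(rbind, lapply(1:8, function(s) {
    proto <- generate_protocol(seed = s)
    hr <- simulate_heart_rate(proto, default_sim_params(seed = s))
    aggregate_hr(extract_hr_windows(hr, proto), subject = sprintf("S%02d", s))
  }))
  tab <- hr_group_table(summaries)
  expect_equal(nrow(tab), 3 * 3 * 2)   # condition x window x statistic
  expect_true(all(tab$n == 8))
  expect_equal(tab$sem, tab$sd / sqrt(8))
  row <- tab[tab$condition == "PAPain" & tab$window_kind == "post_isi" &
               tab$statistic == "hr_max", ]
  expect_equal(row$mean,
               mean(summaries$hrmax_post[summaries$condition == "PAPain"]))
})

test_that("identical stimulus and post-ISI heart rates give p = 1", {
  conds <- c("PAPain", "PA30", "Brush")
  s <- expand.grid(subject = sprintf("S%02d", 1:6), condition = conds,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s$hrmax_stim <- 70
  s$hrmax_post <- 70
  cmp <- suppressWarnings(compare_hr(s))
  expect_true(all(cmp$wilcoxon$p == 1))

  # subjects missing a condition are dropped with a message
  s2 <- s[-1, ]
  s2$hrmax_post <- s2$hrmax_stim + rep(c(1, 2, 3), length.out = nrow(s2))
  expect_message(cmp2 <- compare_hr(s2), "dropping")
  expect_equal(cmp2$n_subjects, 5)
})
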