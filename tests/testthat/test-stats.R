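test_that("response window covers the middle 2.5 s of the stimulus", {
  idx <- response_window_indices(99, 7.81, 31)
  expect_equal(idx, 41:60)                 # onset + 1.25 s .. onset + 3.75 s
  expect_equal(length(idx), 20)            # 2.5 s within one sample
  expect_equal(response_window_indices(99, 7.81, 32), idx + 1)
  expect_error(response_window_indices(50, 7.81, 31), "outside")
})

test_that("block averaging is the per-sample median across trials", {
  proto <- generate_protocol(seed = 14)
  prm <- clean_sim_params(seed = 14)
  rec <- simulate_recording(PROBE, proto, prm)
  tens <- preprocess_subject(rec$od, PROBE, proto)

  # 15 identical trials: the trace is that trial curve
  v <- cos(seq(0, 4, length.out = 99))
  tens$data[, , 7, "PAPain", "O2Hb"] <- v
  ba <- block_average(tens)
  expect_equal(ba$traces[, 7, "PAPain", "O2Hb"], v)

  # median robustness: one corrupted trial leaves the trace unchanged
  tens2 <- tens
  tens2$data[, 3, 7, "PAPain", "O2Hb"] <- 1000
  ba2 <- block_average(tens2)
  expect_equal(ba2$traces[, 7, "PAPain", "O2Hb"], ba$traces[, 7, "PAPain", "O2Hb"])

  # trials k * shape: the trace is the 8th order statistic, per brute force
  tens3 <- tens
  shape <- sin(seq(0, pi, length.out = 99))
  for (k in 1:15) tens3$data[, k, 5, "PA30", "O2Hb"] <- k * shape
  ba3 <- block_average(tens3)
  oracle <- apply(tens3$data[, , 5, "PA30", "O2Hb"], 1, median)
  expect_equal(ba3$traces[, 5, "PA30", "O2Hb"], oracle)
  expect_equal(ba3$traces[, 5, "PA30", "O2Hb"], 8 * shape)

  expect_error(block_average(list()), "trial_tensor")
})

test_that("exact signed-rank p-values match full sign enumeration for n <= 15", {
  set.seed(31)
  for (n in c(5, 8, 11, 15)) {
    x <- round(rnorm(n, 0.3), 3)
    while (any(x == 0) || any(duplicated(abs(x)))) x <- round(rnorm(n, 0.3), 3)
    w <- wilcoxon_signed_rank(x)
    expect_equal(w$p, enumerate_signrank_p(x), tolerance = 1e-10)
    ref <- stats::wilcox.test(x, exact = TRUE)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(w$statistic), unname(ref$statistic))
  }
})

test_that("signed-rank handles the documented edge cases", {
  # symmetric pairs: V = n(n+1)/4 exactly, p = 1
  x <- c(1.3, -1.3, 0.7, -0.7, 2.1, -2.1, 0.25, -0.25)
  w <- wilcoxon_signed_rank(x)
  expect_equal(w$statistic, length(x) * (length(x) + 1) / 4)
  expect_equal(w$p, 1)
  # n = 6 all positive: two-sided exact p = 2/2^6 = 1/32
  w6 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(w6$p, 1 / 32)
  # zeros dropped; all-zero input is a p = 1 degenerate case
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5, 6))$p, 1 / 32)
  expect_warning(w0 <- wilcoxon_signed_rank(rep(0, 10)), "zero")
  expect_equal(w0$p, 1)
  # ties force the normal approximation; p stays in (0, 1]
  wt <- wilcoxon_signed_rank(c(1, 1, 1, -1, 2, 2, 3, 3.5))
  expect_equal(wt$method, "normal")
  expect_gt(wt$p, 0)
  expect_lte(wt$p, 1)
})

test_that("Friedman test matches the closed form and an enumeration oracle", {
  # n = 10 identical rankings: chi2 = 12/(10*3*4)*(10^2+20^2+30^2) - 3*10*4 = 20
  m <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  ft <- friedman_test(m)
  expect_equal(ft$chi2, 20)
  expect_lt(ft$p, 1e-4)

  # n = 5: compare against the full permutation distribution over (3!)^5
  set.seed(7)
  m5 <- matrix(rnorm(15), 5, 3)
  ft5 <- friedman_test(m5)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  stat_of <- function(R) {
    rj <- colSums(R)
    12 / (5 * 3 * 4) * sum(rj^2) - 3 * 5 * 4
  }
  obs <- stat_of(t(apply(m5, 1, rank)))
  expect_equal(ft5$chi2, obs)
  idx <- expand.grid(1:6, 1:6, 1:6, 1:6, 1:6)
  stats_all <- apply(idx, 1, function(ii) stat_of(perms[unlist(ii), ]))
  p_exact <- mean(stats_all >= obs - 1e-12)
  expect_lt(abs(ft5$p - p_exact), 0.05)

  # incomplete rows are dropped
  m_na <- rbind(m, c(NA, 1, 2))
  expect_equal(friedman_test(m_na)$n, 10)
})

test_that("Friedman null rejection rate is nominal", {
  set.seed(42)
  rej <- replicate(2000, {
    m <- matrix(rnorm(60), 20, 3)
    friedman_test(m)$p < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("BH-FDR reproduces the hand-applied step-up rule", {
  f <- bh_fdr(c(0.001, 0.01, 0.02, 0.9))
  expect_equal(f$q, c(0.004, 0.02, 0.08 / 3, 0.9), tolerance = 1e-12)
  expect_identical(f$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 6))$significant, rep(FALSE, 6))
  # q >= p elementwise, non-decreasing in sorted order, order-invariant
  set.seed(2)
  p <- runif(40)^2
  f2 <- bh_fdr(p)
  expect_true(all(f2$q >= p))
  expect_true(all(diff(f2$q[order(p)]) >= -1e-12))
  perm <- sample(40)
  f3 <- bh_fdr(p[perm])
  expect_equal(f3$q, f2$q[perm])
  # NA cells stay out of the family
  f4 <- bh_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(f4$q[2]))
  expect_equal(f4$q[c(1, 3)], bh_fdr(c(0.01, 0.02))$q)
})

test_that("responder classification works at the trial-scalar level", {
  proto <- generate_protocol(seed = 15)
  prm <- clean_sim_params(seed = 15,
                          scalp_amplitude = c(PAPain = 0, PA30 = 0, Brush = 0))
  rec <- simulate_recording(PROBE, proto, prm)
  tens <- suppressWarnings(preprocess_subject(rec$od, PROBE, proto))
  rs <- suppressWarnings(classify_responders(tens, PROBE))
  expect_equal(nrow(rs), 16 * 3 * 2)
  # deterministic positive responses: strong responders on pressure conditions
  o2 <- rs[rs$chromophore == "O2Hb", ]
  expect_true(all(o2$is_responder[o2$condition == "PAPain"]))

  # all-zero cells are non-responders with p = 1 by convention
  sc <- array(0, c(15, 18, 3, 2),
              dimnames = list(NULL, NULL, c("PAPain", "PA30", "Brush"),
                              c("O2Hb", "HHb")))
  sc[, 7, "PAPain", "O2Hb"] <- 0.5 + 0.01 * (1:15)
  rs0 <- suppressWarnings(classify_responders(sc, PROBE))
  hit <- rs0$channel == 7 & rs0$condition == "PAPain" & rs0$chromophore == "O2Hb"
  expect_true(all(rs0$is_responder[hit]))
  expect_true(all(!rs0$is_responder[!hit]))
  expect_true(all(rs0$p[!hit] == 1))
})

test_that("group analysis respects track subsetting and reports sensible effects", {
  set.seed(99)
  n_sub <- 12
  subjects <- sprintf("S%02d", seq_len(n_sub))
  grid <- expand.grid(subject = subjects, channel = LONGS,
                      condition = c("PAPain", "PA30", "Brush"),
                      chromophore = c("O2Hb", "HHb"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff <- c(PAPain = 0.3, PA30 = 0.3, Brush = 0)
  grid$scalar <- eff[grid$condition] * (grid$chromophore == "O2Hb") +
    rnorm(nrow(grid), 0, 0.1)
  responders <- grid
  responders$is_responder <- responders$scalar > 0
  g_all <- run_group_analysis(grid, responders, track = "All", layout = PROBE)
  g_res <- run_group_analysis(grid, responders, track = "Responders", layout = PROBE)

  # responders track never has more contributing subjects than All
  expect_true(all(g_res$vs_zero$n <= g_all$vs_zero$n))
  expect_true(all(g_res$friedman$n <= g_all$friedman$n))

  vz <- g_all$vs_zero[g_all$vs_zero$chromophore == "O2Hb", ]
  expect_true(all(vz$significant[vz$condition == "PAPain"]))
  ph <- g_all$posthoc[g_all$posthoc$chromophore == "O2Hb", ]
  expect_true(all(ph$significant[ph$pair == "PAPain vs Brush"]))
  expect_false(any(ph$significant[ph$pair == "PAPain vs PA30"] %in% TRUE))
  # q never below p inside a family
  expect_true(all(g_all$vs_zero$q >= g_all$vs_zero$p - 1e-12, na.rm = TRUE))
  # cells with too few subjects are excluded, not errors
  few <- grid[grid$subject %in% subjects[1:3], ]
  g_few <- run_group_analysis(few, NULL, track = "All", layout = PROBE)
  expect_true(all(is.na(g_few$friedman$p)))
})

test_that("grand averages report median traces with a seeded SEMed", {
  set.seed(5)
  traces <- lapply(1:9, function(s)
    array(rnorm(99 * 2 * 3 * 2, mean = s %% 3), c(99, 2, 3, 2)))
  ga1 <- grand_average(traces, n_boot = 200, seed = 3)
  ga2 <- grand_average(traces, n_boot = 200, seed = 3)
  expect_identical(ga1$semed, ga2$semed)
  expect_equal(dim(ga1$median), c(99, 2, 3, 2))
  expect_true(all(ga1$semed >= 0))
  oracle <- apply(simplify2array(traces), 1:4, median)
  expect_equal(ga1$median, oracle)
  gg <- grand_average(traces, method = "gaussian")
  expect_equal(dim(gg$semed), c(99, 2, 3, 2))
})
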