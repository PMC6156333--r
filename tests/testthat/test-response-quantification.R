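test_that("PSTH binning follows the half-open [-20, 50) ms convention", {
  # one spike exactly at the contact time lands in bin [0, 1)
  p <- compute_psth(c(5.0), events = 5.0)
  expect_equal(sum(p$counts), 1)
  expect_equal(p$bin_left[which(p$counts[1, ] == 1)], 0)
  # left window edge included, right edge excluded
  p <- compute_psth(c(5 - 0.020, 5 + 0.050), events = 5.0)
  expect_equal(sum(p$counts), 1)
  expect_equal(p$bin_left[which(p$counts[1, ] == 1)], -20)
  # 70 bins of 1 ms
  expect_equal(ncol(p$counts), 70)
  expect_equal(p$bin_left, seq(-20, 49))
  expect_error(compute_psth(c(1, 2), events = numeric()), "no events")
})

test_that("PSTH counts are conserved across random spike trains", {
  set.seed(31)
  for (k in 1:20) {
    sp <- sort(runif(300, 0, 30))
    ev <- sort(runif(8, 1, 29))
    p <- compute_psth(sp, ev)
    manual <- sum(vapply(ev, function(t)
      sum(sp >= t - 0.02 & sp < t + 0.05), 0))
    expect_equal(sum(p$counts), manual)
    expect_equal(p$rate, colMeans(p$counts) * 1000)
  }
})

test_that("homogeneous Poisson spikes give flat PSTHs at the true rate", {
  sp <- poisson_spikes(100, 1000, seed = 8)
  ev <- seq(1, 999, by = 1)
  p <- compute_psth(sp, ev)
  se <- sqrt(100 / (0.001 * length(ev)))  # Poisson SE per 1 ms bin
  expect_true(all(abs(p$rate - 100) < 3.5 * se))
  expect_lt(abs(mean(p$rate) - 100), 3 * se / sqrt(70) * 3)
})

test_that("unit inclusion reproduces the 3 SD arithmetic", {
  flat <- fake_psth(rep(10, 70))
  expect_false(include_unit(flat))
  driven <- fake_psth(c(rep(10, 20), rep(100, 10), rep(10, 40)))
  expect_true(include_unit(driven))
  # borderline synthetic case equals direct recomputation
  set.seed(5)
  for (k in 1:10) {
    r <- rpois(70, 12)
    p <- fake_psth(r)
    b <- r[1:10]
    expect_equal(include_unit(p), mean(r[21:30]) > mean(b) + 3 * sd(b))
  }
})

test_that("evoked peak = max of baseline-corrected 3 ms boxcar in [0, 10) ms", {
  expect_equal(evoked_peak(fake_psth(rep(7, 70))), 0)
  # single-bin impulse of height h on zero baseline smooths to h/3
  r <- rep(0, 70); r[25] <- 90
  expect_equal(evoked_peak(fake_psth(r)), 30)
  # triangular kernel fixture vs direct convolution oracle
  r <- rep(5, 70); r[22:28] <- 5 + c(10, 25, 40, 55, 40, 25, 10)
  sm <- sapply(1:70, function(i) mean(r[max(1, i - 1):min(70, i + 1)])) - 5
  expect_equal(evoked_peak(fake_psth(r)), max(sm[21:30]))
  # shrink-to-valid edges: impulse in the first bin averages over 2 bins
  r <- rep(0, 70); r[1] <- 60
  expect_equal(boxcar_smooth(r)[1], 30)
})

test_that("gating summary ratios match hand computation on a 3-trial toy", {
  # whisking trials at 10, 20, 30 s; non-whisking at 40, 50, 60 s
  # evoked spikes ([0,10) ms): W 1,2,0; NW 2,3,4; baselines 0
  sp <- sort(c(10.001, 20.001, 20.005, 40.002, 40.006, 50.001, 50.004,
               50.007, 60.001, 60.003, 60.005, 60.008))
  u <- unit_record(sp, "toy")
  cl <- data.frame(contact_time = c(10, 20, 30, 40, 50, 60),
                   label = rep(c("whisking", "non_whisking"), each = 3),
                   matched = TRUE)
  g <- gating_summary(u, cl)
  # W PSTH mean evoked rates: 3 spikes/3 trials; peak bin rate after boxcar
  pw <- compute_psth(u, c(10, 20, 30))
  pn <- compute_psth(u, c(40, 50, 60))
  expect_equal(g$W_max, max(boxcar_smooth(pw$rate)[21:30]))
  expect_equal(g$NW_max, max(boxcar_smooth(pn$rate)[21:30]))
  expect_equal(g$evoked_ratio, g$W_max / g$NW_max)
  expect_equal(g$mean_baseline_W, 0)
  expect_true(g$infinite_baseline_ratio)
  expect_error(gating_summary(u, within(cl, matched <- label == "whisking")),
               "zero matched")
})

test_that("scaled PSTH pairs give evoked and per-peak gating equal to the scale", {
  base <- rep(8, 70)
  base[24:31] <- 8 + c(30, 90, 140, 90, 45, 25, 12, 5)
  base[36:40] <- 8 + c(30, 70, 95, 60, 20)   # second peak at ~17 ms
  for (c_scale in c(0.5, 0.7, 1.3)) {
    pw <- fake_psth(c_scale * base)
    pn <- fake_psth(base)
    expect_equal(evoked_peak(pw) / evoked_peak(pn), c_scale,
                 tolerance = 1e-10)
    pk <- detect_peaks(pw, pn)
    expect_true(pk$valid)
    expect_equal(pk$first_peak$gating, c_scale, tolerance = 1e-10)
    expect_false(is.null(pk$second_peak))
    expect_equal(pk$second_peak$gating, c_scale, tolerance = 1e-10)
  }
})

test_that("peak detection enforces separation, threshold and the 5 ms pairing rule", {
  single <- rep(5, 70); single[25] <- 150
  p1 <- fake_psth(single)
  pk <- detect_peaks(p1, p1)
  expect_true(pk$valid)
  expect_null(pk$second_peak)
  # peaks recovered within 1 ms on a clean double-peak pair (4 and 15 ms)
  r <- rep(5, 70); r[24:26] <- c(80, 160, 80); r[34:36] <- c(60, 120, 60)
  pk2 <- detect_peaks(fake_psth(0.7 * r), fake_psth(r))
  expect_lt(abs(pk2$first_peak$latency_NW - 4.5), 1)
  expect_lt(abs(pk2$second_peak$latency_NW - 14.5), 1)
  # W peak at 5 ms vs NW peak at 12 ms -> invalid pair
  w <- rep(5, 70); w[26] <- 150
  nw <- rep(5, 70); nw[33] <- 150
  expect_false(detect_peaks(fake_psth(w), fake_psth(nw))$valid)
  # flat psth: no qualifying peak
  expect_false(detect_peaks(fake_psth(rep(5, 70)), fake_psth(rep(5, 70)))$valid)
})

test_that("generator double peaks are recovered and equally gated on a clean fixture", {
  # large second peak and strong rates so both peaks clear the 3 SD threshold
  p <- tiny_preset("intact_pr5", n_units = 8, trial_count = 250)
  p$double_peak_fraction <- 1
  p$evoked_peak_rate_dist <- list(dist = "lnorm", meanlog = log(400),
                                  sdlog = 0.1, mean = 400, sd = NA)
  gen <- generate_session(p, 21)
  cl <- match_decelerations(
    classify_contacts(extract_contact_windows(gen$session))$classification)
  g <- analyze_gating(gen$session, cl)
  ok <- !is.na(g$gating_peak1) & !is.na(g$gating_peak2)
  expect_gte(sum(ok), 4)
  # both peaks scaled equally by the generator: per-peak gating difference
  # not significant across units
  t <- signed_rank_test(g$gating_peak1[ok] - g$gating_peak2[ok])
  expect_gt(t$p_value, 0.05)
})

test_that("trial-wise gating divides evoked counts by the non-whisking median", {
  # counts W: 2; NW: 3,4,5 (median 4) -> ratio 0.5
  sp <- sort(c(10.001, 10.004,
               40.001, 40.003, 40.005,
               50.001, 50.003, 50.005, 50.007,
               60.001, 60.003, 60.005, 60.007, 60.009))
  u <- unit_record(sp, "toy")
  cl <- data.frame(contact_time = c(10, 40, 50, 60),
                   label = c("whisking", rep("non_whisking", 3)),
                   matched = TRUE)
  tg <- trialwise_gating(u, cl)
  expect_equal(tg$ratio, 0.5)
  # all counts equal -> all ratios 1
  sp2 <- sort(c(10.002, 40.002, 50.002, 60.002))
  tg2 <- trialwise_gating(unit_record(sp2, "t2"), cl)
  expect_equal(tg2$ratio, 1)
  # zero non-whisking median is an error
  u3 <- unit_record(c(10.001), "t3")
  expect_error(trialwise_gating(u3, cl), "zero median")
})
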