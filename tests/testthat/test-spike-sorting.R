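test_that("trough detection, deduplication and artifact rejection", {
  rate <- 40000
  set.seed(6)
  base <- rnorm(4000, sd = 5)   # noise floor keeps spikes under 10 trace SDs
  mk_volt <- function(v) voltage_trace(v, rate = rate)
  # two troughs 0.5 ms apart: only the more negative survives
  v <- base
  v[1000] <- -35; v[1020] <- -45
  sn <- detect_snippets(mk_volt(v), threshold = -25)
  expect_equal(nrow(sn$waveforms), 1)
  expect_equal(round(sn$trough_times * rate) + 1, 1020)
  # order independence of the dedup rule
  v2 <- base; v2[1000] <- -45; v2[1020] <- -35
  sn2 <- detect_snippets(mk_volt(v2), threshold = -25)
  expect_equal(round(sn2$trough_times * rate) + 1, 1000)
  # troughs > 1 ms apart both survive
  v3 <- base; v3[1000] <- -35; v3[1050] <- -45
  expect_equal(nrow(detect_snippets(mk_volt(v3), threshold = -25)$waveforms), 2)
  # artifact: sample beyond 10 trace SDs is removed
  v4 <- rep(0, 4000); v4[2000] <- -60
  sn4 <- detect_snippets(voltage_trace(v4, rate), threshold = -30,
                         artifact_sd = 10)
  expect_equal(nrow(sn4$waveforms), 0)   # lone spike is 10+ SD of quiet trace
  # invariant: no two retained snippets within 1 ms
  set.seed(2)
  noisy <- voltage_trace(rnorm(40000, sd = 10), rate)
  sn5 <- detect_snippets(noisy, threshold_sd = 3)
  if (length(sn5$trough_times) > 1)
    expect_true(all(diff(sn5$trough_times) >= 0.001 - 1e-9))
  expect_true(all(abs(sn5$waveforms) <= 10 * sd(noisy$samples)))
  # pure noise at -8 SD: essentially no snippets
  expect_lte(nrow(detect_snippets(noisy, threshold_sd = 8)$waveforms), 1)
  expect_error(detect_snippets(noisy, threshold = 5), "negative")
  # trace shorter than one snippet yields an empty result
  expect_equal(nrow(detect_snippets(voltage_trace(rnorm(10), rate),
                                    threshold = -1)$waveforms), 0)
})

test_that("snippet geometry: 45 samples with the trough at sample 13", {
  rate <- 40000
  set.seed(7)
  v <- rnorm(2000, sd = 5); v[500] <- -40
  sn <- detect_snippets(voltage_trace(v, rate), threshold = -25)
  expect_equal(ncol(sn$waveforms), 45)
  expect_equal(unname(apply(sn$waveforms, 1, which.min)), 13)
})

test_that("PCA + k-means separates well-separated templates deterministically", {
  s <- flat_session(list(poisson_spikes(25, 60, seed = 1),
                         poisson_spikes(25, 60, seed = 2)), dur = 60)
  vt <- generate_voltage_trace(s, noise_sd = 5, seed = 3,
                               amplitudes = c(120, 170))
  sn <- detect_snippets(vt$voltage, threshold_sd = 3)
  # >= 95% of true spikes detected within 0.1 ms at this SNR
  d <- vapply(vt$truth$time, function(t) min(abs(sn$trough_times - t)), 0)
  expect_gt(mean(d <= 1e-4), 0.95)
  m <- embed_and_cluster(sn, k = 2, seed = 5)
  near <- vapply(sn$trough_times, function(t) {
    i <- which.min(abs(vt$truth$time - t))
    if (abs(vt$truth$time[i] - t) <= 2e-4) vt$truth$unit_id[i] else NA_character_
  }, "")
  ok <- !is.na(near)
  tab <- table(factor(near[ok]), factor(m$assignments[ok], levels = 1:2))
  agree <- max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
  expect_gt(agree, 0.95)
  # determinism
  m2 <- embed_and_cluster(sn, k = 2, seed = 5)
  expect_identical(m$assignments, m2$assignments)
  expect_error(embed_and_cluster(sn, k = nrow(sn$waveforms) + 1, seed = 1),
               "exceeds")
  # identical snippets collapse to one cluster with zero variance
  same <- list(waveforms = matrix(rep(c(rep(0, 12), -50, rep(0, 32)), 10),
                                  nrow = 10, byrow = TRUE),
               trough_times = seq(0.1, 1, by = 0.1), rate = 40000)
  m3 <- embed_and_cluster(same, k = 1, seed = 1)
  expect_equal(length(unique(m3$assignments)), 1)
  expect_lt(sum(apply(m3$features, 2, var)), 1e-12)
})

test_that("unit grading applies the ISI and separation criteria", {
  mk_model <- function(f1, f2) list(
    features = rbind(f1, f2),
    assignments = rep(1:2, c(nrow(f1), nrow(f2))),
    centroids = rbind(colMeans(f1), colMeans(f2)), k = 2)
  set.seed(8)
  f1 <- matrix(rnorm(300, 0, 1), ncol = 3)
  f2 <- matrix(rnorm(300, 12, 1), ncol = 3)
  good_times <- list(seq(1, 100, by = 1)[1:100], seq(1.0005, 100, by = 1)[1:100])
  sn <- list(trough_times = c(good_times[[1]], good_times[[2]]))
  q <- grade_units(mk_model(f1, f2), sn)
  expect_equal(q$grade, c("single", "single"))
  # 5% sub-millisecond ISIs force multi
  bad <- sort(c(seq(1, 95, by = 1), seq(2, 82, by = 20) + 5e-4))
  stopifnot(length(bad) == 100)
  sn_bad <- list(trough_times = c(bad, good_times[[2]][1:100]))
  q2 <- grade_units(mk_model(f1, f2), sn_bad)
  expect_equal(q2$grade[1], "multi")
  expect_gt(q2$isi_violation_fraction[1], 0.01)
  # merged clusters (overlapping features) fail the separation criterion
  f3 <- matrix(rnorm(300, 1.5, 1), ncol = 3)
  q3 <- grade_units(mk_model(f1, f3), sn)
  expect_equal(q3$grade, c("multi", "multi"))
})

test_that("sorting then gating reproduces the ground-truth gating mean within 0.05", {
  # Sessions each carry one contact-responsive unit (the deepest template)
  # plus two background units, so evoked-window template collisions -- which
  # the 1 ms trough deduplication resolves by discarding the shallower
  # waveform -- do not systematically thin the responsive unit's evoked
  # spikes. The gating mean is compared across the population of responsive
  # units.
  diffs <- vapply(1:5, function(seed) {
    p <- generator_preset("intact_pr5", n_units = 1, trial_count = 300)
    p$double_peak_fraction <- 0
    p$evoked_peak_rate_dist <- list(dist = "lnorm", meanlog = log(150),
                                    sdlog = 0.1, mean = 150, sd = NA)
    gen <- generate_session(p, seed)
    s <- gen$session
    dur <- length(s$trace$samples) / s$trace$rate
    s$units <- c(s$units, list(
      unit_record(poisson_spikes(15, dur - 0.1, seed = 100 + seed), "bg1"),
      unit_record(poisson_spikes(25, dur - 0.1, seed = 200 + seed), "bg2")))
    vt <- generate_voltage_trace(s, noise_sd = 5, seed = 4,
                                 amplitudes = c(230, 120, 170))
    srt <- sort_voltage(vt$voltage, k = 3, threshold_sd = 3, seed = 6)
    cl <- match_decelerations(
      classify_contacts(extract_contact_windows(s))$classification)
    g_true <- analyze_gating(s, cl)
    s_sorted <- s
    s_sorted$units <- srt$units
    g_sort <- analyze_gating(s_sorted, cl)
    mean(g_sort$evoked_ratio[g_sort$included %in% TRUE]) -
      mean(g_true$evoked_ratio[g_true$included %in% TRUE])
  }, 0)
  expect_lt(abs(mean(diffs)), 0.05)
})
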