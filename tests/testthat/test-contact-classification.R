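test_that("preprocessing preserves DC, attenuates 200 Hz, and resamples to 1 kHz", {
  # constant trace passes unchanged
  const <- whisker_trace(rep(0.005, 4000), 2000)
  out <- preprocess_trace(const)
  expect_equal(out$rate, 1000)
  expect_lt(max(abs(out$samples - 0.005)), 1e-9)

  # 200 Hz sinusoid: two passes of a 3rd-order 100 Hz Butterworth attenuate
  # |H|^2 = 1/(1+2^6) ~ 1.5%, so well below 10% of the input amplitude
  t <- (0:7999) / 2000
  sine <- whisker_trace(1e-3 * sin(2 * pi * 200 * t), 2000)
  out <- preprocess_trace(sine)
  core <- out$samples[500:3500]  # avoid filter edge transients
  expect_lt(max(abs(core)), 0.1 * 1e-3)

  # length: N samples at 2 kHz -> floor(N/2) +/- 1 at 1 kHz
  n_in <- 4001
  out <- preprocess_trace(whisker_trace(rep(0, n_in), 2000))
  expect_lte(abs(length(out$samples) - floor(n_in / 2)), 1)

  expect_error(preprocess_trace(whisker_trace(rep(0, 100), 150)),
               "below 200 Hz")
})

test_that("kinematic derivatives match closed forms", {
  rate <- 1000
  t <- (0:999) / rate
  # linear ramp at 0.1 m/s
  k <- derive_kinematics(whisker_trace(0.1 * t, rate))
  expect_lt(max(abs(k$velocity - 0.1)), 1e-9)
  expect_lt(max(abs(k$acceleration[3:998])), 1e-6)
  # sinusoid A sin(2 pi f t): peak velocity 2 pi f A
  A <- 0.004; f <- 8
  k <- derive_kinematics(whisker_trace(A * sin(2 * pi * f * t), rate))
  expect_equal(max(k$velocity), 2 * pi * f * A, tolerance = 0.01)
  # constant trace: zero velocity and acceleration
  k <- derive_kinematics(whisker_trace(rep(1, 100), rate))
  expect_true(all(k$velocity == 0) && all(k$acceleration == 0))
  expect_error(derive_kinematics(whisker_trace(c(1, 2), rate)), "3 samples")
})

test_that("contact windows have 151 samples and exclusion matches a brute-force scan", {
  # hand-placed events on a quiet trace
  tr <- whisker_trace(rep(0, 20000), 2000)
  set.seed(42)
  ct <- sort(runif(40, 0.2, 9.8))
  lk <- sort(runif(30, 0.2, 9.8))
  s <- whisk_session(tr, data.frame(time = ct, reward = TRUE),
                     data.frame(time = lk), units = list(),
                     metadata = list(session_id = "x"))
  w <- extract_contact_windows(s)
  expect_true(all(vapply(w[vapply(w, `[[`, TRUE, "valid")],
                         function(x) length(x$position), 0L) == 151))
  # O(n^2) interval-overlap oracle
  for (i in seq_along(ct)) {
    second <- any(abs(ct[-i] - ct[i]) <= 0.075)
    lick <- any(abs(lk - ct[i]) <= 0.075)
    boundary <- ct[i] < 0.075 || ct[i] > 10 - 0.075
    expect_equal(w[[i]]$valid, !(second || lick || boundary),
                 info = paste("contact", i))
  }
  # two contacts 50 ms apart are both excluded
  s2 <- whisk_session(tr, data.frame(time = c(1, 1.05), reward = TRUE),
                      data.frame(time = numeric()), units = list())
  w2 <- extract_contact_windows(s2)
  expect_equal(vapply(w2, `[[`, "", "reason"),
               c("second_contact", "second_contact"))
  # a lick 100 ms after the contact leaves the window valid
  s3 <- whisk_session(tr, data.frame(time = 1, reward = TRUE),
                      data.frame(time = 1.1), units = list())
  expect_true(extract_contact_windows(s3)[[1]]$valid)
  # contact at the trace boundary is excluded with reason "boundary"
  s4 <- whisk_session(tr, data.frame(time = 0.01, reward = TRUE),
                      data.frame(time = numeric()), units = list())
  expect_equal(extract_contact_windows(s4)[[1]]$reason, "boundary")
})

test_that("classification applies the 2-sigma and RMS criteria", {
  # 100 rest windows (tiny velocities) + 60 whisking windows (0.3 m/s)
  wn <- c(lapply(1:100, function(i) fake_window(i, 0, vel_sd = 5e-5, seed = i)),
          lapply(1:60, function(i) fake_window(200 + i, 0.3, vel_sd = 0.02,
                                               seed = i)))
  res <- classify_contacts(wn)
  lab <- res$classification$label
  expect_gte(mean(lab[1:100] == "non_whisking"), 0.85)
  expect_true(all(lab[101:160] == "whisking"))
  expect_gt(res$fit$sigma, 0)
  # invariant: every non-whisking label satisfies both criteria
  cl <- res$classification
  nw <- cl$label == "non_whisking"
  expect_true(all(cl$pre_contact_mean_velocity[nw] >= res$fit$nonwhisk_band[1] &
                  cl$pre_contact_mean_velocity[nw] <= res$fit$nonwhisk_band[2]))
  expect_true(all(cl$pre_contact_rms_velocity[nw] < 0.001))
  # a window violating only the RMS criterion is whisking even at zero mean:
  # an oscillation with near-zero 10 ms mean but large 75 ms RMS
  osc <- fake_window(999, 0, vel_sd = 0, seed = 1)
  osc$velocity <- 0.2 * sin(2 * pi * 40 * (0:150) / 1000)
  osc$velocity[66:75] <- 0   # apex in the final 10 ms before contact
  res2 <- classify_contacts(c(wn, list(osc)))
  expect_equal(res2$classification$label[161], "whisking")
  expect_error(classify_contacts(wn[1:10]), "fewer than 20")
})

test_that("classification is invariant to a constant position offset", {
  gen <- generate_session(tiny_preset(n_units = 1, trial_count = 60), 6)
  s <- gen$session
  l1 <- classify_contacts(extract_contact_windows(s))$classification$label
  s$trace$samples <- s$trace$samples + 0.01
  l2 <- classify_contacts(extract_contact_windows(s))$classification$label
  expect_identical(l1, l2)
})

test_that("classifier recovers generator ground-truth labels", {
  r <- acc_run("intact_pr5", 1, onsets = TRUE, unmatched = TRUE)
  expect_gt(r$agreement, 0.9)
})

test_that("deceleration matching selects the percentile-range intersection", {
  mk <- function(labs, dec) data.frame(
    contact_time = seq_along(labs), label = labs,
    pre_contact_mean_velocity = 0, pre_contact_rms_velocity = 0,
    min_peri_deceleration = dec, mean_velocity_20ms = 0,
    mean_acceleration_20ms = 0, position_at_contact = 0,
    exclusion_reason = NA, matched = NA)
  set.seed(1)
  # identical class distributions: intersection equals the common 5-95%
  # range, so every trial inside it is matched (~90% of each class)
  dec <- rnorm(200, -30, 5)
  cl <- mk(rep(c("whisking", "non_whisking"), each = 100), c(dec[1:100], dec[1:100]))
  m <- match_decelerations(cl)
  rng <- attr(m, "match_range")
  q <- quantile(dec[1:100], c(0.05, 0.95), names = FALSE)
  expect_equal(rng, q)
  expect_identical(m$matched,
                   cl$min_peri_deceleration >= q[1] &
                     cl$min_peri_deceleration <= q[2])
  expect_gte(mean(m$matched), 0.85)
  # disjoint distributions raise
  cl2 <- mk(rep(c("whisking", "non_whisking"), each = 50),
            c(rnorm(50, -100, 1), rnorm(50, -10, 1)))
  expect_error(match_decelerations(cl2), "no overlap")
  # percentile oracle on overlapping classes
  cl3 <- mk(rep(c("whisking", "non_whisking"), each = 80),
            c(rnorm(80, -35, 8), rnorm(80, -25, 8)))
  m3 <- match_decelerations(cl3)
  lo <- max(quantile(cl3$min_peri_deceleration[1:80], 0.05),
            quantile(cl3$min_peri_deceleration[81:160], 0.05))
  hi <- min(quantile(cl3$min_peri_deceleration[1:80], 0.95),
            quantile(cl3$min_peri_deceleration[81:160], 0.95))
  expect_identical(m3$matched, cl3$min_peri_deceleration >= lo &
                     cl3$min_peri_deceleration <= hi)
  expect_error(match_decelerations(mk(rep("whisking", 10), rnorm(10))),
               "non-empty")
})
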