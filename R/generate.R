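# Synthetic active-touch sessions with full ground truth.
#
# A session is a sequence of trials, half containing a rest->whisk transition
# followed by an active (whisking) contact and half a passive (non-whisking)
# contact where the object strikes the stationary whisker. Contacts arise
# from whisker-object crossings; spike trains are inhomogeneous Bernoulli
# (1 ms resolution) realisations of per-unit rate profiles that combine a
# rest baseline, a whisking elevation, a whisking-onset increment, and a
# contact-evoked kernel whose amplitude is multiplied by the unit's gating
# factor on whisking contacts.

GEN_FS <- 2000            # native trace rate (Hz)
TRIAL_W_DUR <- 1.625      # whisking-trial duration (s), multiple of 125 ms
TRIAL_NW_DUR <- 0.875     # non-whisking-trial duration (s)
WHISK_ONSET_OFF <- 0.375  # rest->whisk transition offset within trial (s)
ONSET_STEP_DUR <- 0.5     # duration of the onset rate increment (s)
ONSET_RAMP_DUR <- 0.15    # ramp from onset increment to sustained rate (s)
TREMOR_AMP <- 3e-6        # rest-state tremor amplitude (m)
SENSOR_NOISE_SD <- 3e-7   # white sensor noise (m)
OBJ_NOISE_SD <- 1e-3      # sd of the 5 Hz low-passed object noise (m)
DECEL_DV_W <- 0.12        # median whisking contact velocity deficit (m/s)
DECEL_DV_NW <- 0.115      # median non-whisking contact velocity deficit (m/s)
DECEL_SDLOG <- 0.22
DECEL_DELAY <- 0.004      # mechanical deceleration onset after sensor contact (s)
DECEL_RAMP <- 0.004       # raised-cosine build-up of the velocity deficit (s)
DECEL_HOLD <- 0.004       # dwell at full deficit before elastic rebound (s)
DECEL_RELAX <- 0.08       # elastic recovery of the displacement (s)
LICK_OFFSETS <- c(0.18, 0.235, 0.29, 0.345, 0.40)  # consummatory burst (s)

sub_seeds <- function(seed, n = 8) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# half-open [a, b) sample index range at rate fs, 1-based, t0 = 0
seg_idx <- function(a, b, fs, n) {
  i1 <- max(1L, floor(a * fs) + 1L)
  i2 <- min(n, floor(b * fs + 1e-9))
  if (i2 < i1) integer() else i1:i2
}

# Contact-induced deceleration: the object removes a velocity deficit dv
# from the whisker (the whisker is stopped against / pushed by the rod).
# The deficit builds up as a raised cosine over DECEL_RAMP starting
# DECEL_DELAY after the sensor timestamp (contact is detected at first
# touch; mechanical deceleration develops with whisker compliance), holds
# briefly, and the displacement relaxes back elastically. The gentle onset,
# the delay and the short dwell keep the zero-phase-filtered pre-contact
# kinematic windows essentially causal (backward filter ring stays well
# below the 1 mm/s RMS classification criterion).
decel_perturbation <- function(dv, fs) {
  nr <- round(DECEL_RAMP * fs)
  v <- c(rep(0, round(DECEL_DELAY * fs)),
         -dv * (1 - cos(pi * seq_len(nr) / nr)) / 2,
         rep(-dv, round(DECEL_HOLD * fs)))
  x <- cumsum(v) / fs
  relax <- seq(x[length(x)], 0, length.out = round(DECEL_RELAX * fs))
  c(x, relax[-1])
}

# evoked-response kernel sampled at 1 ms resolution, peak normalised to 1
make_kernel <- function(shape, double_peak, rng_u) {
  lat <- stats::runif(1, shape$latency_ms[1], shape$latency_ms[2])
  tau <- (0:59) + 0.5   # ms, bin centres after contact
  if (isTRUE(shape$late_component)) {
    # fast rise, ~7 ms decay: rates reach baseline ~30 ms after contact
    x <- pmax(0, tau - lat)
    s <- (1 - exp(-x / 0.8)) * exp(-x / 7)
    s[tau < lat] <- 0
  } else {
    width <- if (is.na(shape$width_ms)) 2 else shape$width_ms
    sig <- width / 2.355   # FWHM -> sd
    s <- exp(-(tau - lat)^2 / (2 * sig^2))
    s[abs(tau - lat) > 3.5 * sig] <- 0
  }
  s <- s / max(s)
  peak1 <- tau[which.max(s)]
  second <- NA_real_
  if (double_peak) {
    second <- stats::runif(1, max(6, peak1 + 3.5), 25)
    a2 <- stats::runif(1, 0.4, 0.9)
    sig2 <- stats::runif(1, 1, 2)
    s <- s + a2 * exp(-(tau - second)^2 / (2 * sig2^2))
    s <- s / max(s)
  }
  list(values = s, latency_ms = lat, first_peak_ms = peak1,
       second_peak_ms = second)
}

#' Generate a synthetic recording session
#'
#' Produces a `whisk_session` (whisker trace, object trajectory, contact and
#' lick events, unit spike trains) together with the generating ground truth,
#' deterministically from `(preset, seed)`.
#'
#' The whisker trace alternates rest epochs (micro-tremor, |velocity| RMS far
#' below 0.001 m/s) with whisking epochs (6-10 Hz, ~12 mm amplitude).
#' The object trajectory is 5 Hz low-pass filtered white noise riding on the
#' task's approach ramps; contacts are whisker-object crossings. Whisking
#' contacts receive stronger contact decelerations than non-whisking ones,
#' with overlapping distributions. Spike trains follow an inhomogeneous
#' point process: rest baseline, whisking baseline elevation (per-unit
#' baseline ratio), a whisking-onset rate increment confined to the first
#' 500 ms of each whisk bout, and a contact-evoked kernel multiplied by the
#' unit's gating factor on whisking contacts (both peaks of double-peaked
#' kernels scaled equally).
#'
#' @param preset a `generator_preset` (or preset name)
#' @param seed integer master seed; component sub-streams are derived from it
#' @return list with elements `session` (a `whisk_session`) and
#'   `ground_truth` (per-contact true state, transition times, and a per-unit
#'   table of true gating factors, baseline ratios, onset increments and
#'   kernel descriptions)
#' @export
generate_session <- function(preset, seed) {
  if (is.character(preset)) preset <- generator_preset(preset)
  if (!inherits(preset, "generator_preset")) stop("invalid preset")
  validate_preset(preset)
  fs <- GEN_FS
  seeds <- sub_seeds(seed)

  ## ---- trial layout ----
  set.seed(seeds[1])
  n_trials <- as.integer(preset$trial_count)
  n_w <- round(n_trials * preset$whisking_fraction)
  states <- sample(rep(c("whisking", "non_whisking"), c(n_w, n_trials - n_w)))
  durs <- ifelse(states == "whisking", TRIAL_W_DUR, TRIAL_NW_DUR)
  starts <- cumsum(c(0, durs[-n_trials]))
  total_T <- sum(durs) + 0.5
  n <- round(total_T * fs)
  tt <- (seq_len(n) - 1) / fs

  ## ---- background motion: tremor + sensor noise ----
  set.seed(seeds[2])
  f_tr <- stats::runif(1, 8, 11)
  phi <- stats::runif(1, 0, 2 * pi)
  w <- TREMOR_AMP * sin(2 * pi * f_tr * tt + phi) +
    stats::rnorm(n, sd = SENSOR_NOISE_SD)

  ## ---- object noise: white noise low-passed at 5 Hz (Butterworth, 3rd) ----
  set.seed(seeds[3])
  bf <- signal::butter(3, 5 / (fs / 2), type = "low")
  onoise <- signal::filtfilt(bf, stats::rnorm(n))
  onoise <- onoise / stats::sd(onoise) * OBJ_NOISE_SD
  o <- rep(0.02, n) + onoise

  ## ---- per-trial kinematics, crossings, decelerations ----
  set.seed(seeds[4])
  freq <- stats::runif(n_trials, 6, 10)
  amp <- stats::rlnorm(n_trials, log(0.012), 0.15)
  decel <- stats::rlnorm(n_trials, log(ifelse(states == "whisking",
                                              DECEL_DV_W, DECEL_DV_NW)),
                         DECEL_SDLOG)
  lick_jit <- matrix(stats::runif(n_trials * length(LICK_OFFSETS),
                                  -0.008, 0.008), nrow = n_trials)

  contact_time <- rep(NA_real_, n_trials)
  transitions <- numeric(0)
  lick_times <- vector("list", n_trials)

  for (i in seq_len(n_trials)) {
    s0 <- starts[i]
    if (states[i] == "whisking") {
      f <- freq[i]; A <- amp[i]
      onset <- s0 + WHISK_ONSET_OFF
      whisk_dur <- floor(0.9 * f) / f
      wend <- onset + whisk_dur
      idx <- seg_idx(onset, wend, fs, n)
      w[idx] <- w[idx] + A * (1 - cos(2 * pi * f * (tt[idx] - onset))) / 2
      transitions <- c(transitions, onset)
      # object approach: drop from standoff to 0.55 A during the retraction
      # preceding the target protraction, hold, retreat after contact
      k_drop <- max(2, round(0.75 * f - 0.25))
      t_drop <- onset + min(k_drop / f, whisk_dur - 1 / f)
      lvl <- 0.45 * A
      i_hi <- seg_idx(s0, t_drop, fs, n)
      o[i_hi] <- o[i_hi] - 0.02 + (A + 0.005)
      i_dr <- seg_idx(t_drop, t_drop + 0.25 / f, fs, n)
      o[i_dr] <- o[i_dr] - 0.02 +
        seq(A + 0.005, lvl, length.out = length(i_dr))
      i_lo <- seg_idx(t_drop + 0.25 / f, s0 + durs[i], fs, n)
      o[i_lo] <- o[i_lo] - 0.02 + lvl
      search <- seg_idx(t_drop + 0.002, wend - 0.05, fs, n)
    } else {
      # object strikes the resting whisker
      appr0 <- s0 + 0.1
      i_hi <- seg_idx(s0, appr0, fs, n)
      o[i_hi] <- o[i_hi] - 0.02 + 0.012
      i_dr <- seg_idx(appr0, appr0 + 0.3, fs, n)
      o[i_dr] <- o[i_dr] - 0.02 +
        seq(0.012, -0.002, length.out = length(i_dr))
      i_lo <- seg_idx(appr0 + 0.3, s0 + durs[i], fs, n)
      o[i_lo] <- o[i_lo] - 0.02 - 0.002
      search <- seg_idx(appr0, appr0 + 0.5, fs, n)
    }
    hit <- search[which(w[search] >= o[search])[1]]
    if (!is.na(hit)) {
      tc <- tt[hit]
      contact_time[i] <- tc
      # whisker deceleration at contact
      pert <- decel_perturbation(decel[i], fs)
      ip <- hit:min(n, hit + length(pert) - 1L)
      w[ip] <- w[ip] + pert[seq_along(ip)]
      # object retreats
      ir <- seg_idx(tc + 0.005, s0 + durs[i], fs, n)
      if (length(ir))
        o[ir] <- o[ir] + pmin((tt[ir] - tc - 0.005) * 0.5, 0.05)
      lt <- tc + LICK_OFFSETS + lick_jit[i, ]
      lick_times[[i]] <- lt[lt < s0 + durs[i] - 0.05]
    }
  }

  contacts <- data.frame(time = contact_time[!is.na(contact_time)],
                         reward = TRUE)
  contact_state <- states[!is.na(contact_time)]
  licks <- data.frame(time = sort(unlist(lick_times)))

  ## ---- per-unit parameters ----
  set.seed(seeds[5])
  nu <- as.integer(preset$n_units)
  n_int <- min(preset$n_interneurons %||% 0L, nu)
  is_int <- seq_len(nu) <= n_int
  g <- draw_lnorm(nu, preset$gating_factor_dist)
  bratio <- draw_lnorm(nu, preset$baseline_ratio_dist)
  if (n_int > 0)
    bratio[is_int] <- draw_lnorm(n_int, preset$interneuron_baseline_ratio_dist)
  rest <- draw_lnorm(nu, preset$rest_baseline_rate_dist)
  zero_base <- stats::runif(nu) < preset$zero_baseline_fraction
  whisk_rate_zero <- draw_lnorm(nu, preset$rest_baseline_rate_dist)
  rest[zero_base] <- 0
  peak <- draw_lnorm(nu, preset$evoked_peak_rate_dist)
  inc <- draw_lnorm(nu, preset$onset_increment_dist)
  dbl <- stats::runif(nu) < preset$double_peak_fraction
  kernels <- lapply(seq_len(nu), function(u)
    make_kernel(preset$kernel_shape, dbl[u], NULL))
  quality <- ifelse(is_int, "single",
                    sample(c("single", "multi"), nu, replace = TRUE))
  rf <- if (preset$nucleus == "Sp5i") {
    ifelse(is_int, "SW", sample(c("SW", "MW"), nu, replace = TRUE,
                                prob = c(0.2, 0.8)))
  } else {
    c("MW", rep("SW", nu - 1))[sample.int(nu)]
  }

  ## ---- spike trains: 1 ms Bernoulli thinning of the rate profile ----
  n1k <- round(total_T * 1000)
  t1k <- (seq_len(n1k) - 0.5) / 1000
  contact_bin <- floor(contacts$time * 1000) + 1L
  w_idx_list <- lapply(which(states == "whisking"), function(i) {
    onset <- starts[i] + WHISK_ONSET_OFF
    wend <- onset + floor(0.9 * freq[i]) / freq[i]
    list(step = seg_idx(onset, onset + ONSET_STEP_DUR, 1000, n1k),
         ramp = seg_idx(onset + ONSET_STEP_DUR,
                        onset + ONSET_STEP_DUR + ONSET_RAMP_DUR, 1000, n1k),
         sustained = seg_idx(onset + ONSET_STEP_DUR + ONSET_RAMP_DUR,
                             wend, 1000, n1k))
  })

  units <- vector("list", nu)
  set.seed(seeds[6])
  for (u in seq_len(nu)) {
    r0 <- rest[u]
    sus <- if (zero_base[u]) whisk_rate_zero[u] else r0 * bratio[u]
    rate <- rep(r0, n1k)
    for (wi in w_idx_list) {
      rate[wi$step] <- r0 + inc[u]
      if (length(wi$ramp))
        rate[wi$ramp] <- seq(r0 + inc[u], sus, length.out = length(wi$ramp))
      rate[wi$sustained] <- sus
    }
    kv <- kernels[[u]]$values * peak[u]
    for (ci in seq_len(nrow(contacts))) {
      gain <- if (contact_state[ci] == "whisking") g[u] else 1
      ib <- contact_bin[ci]:min(n1k, contact_bin[ci] + length(kv) - 1L)
      rate[ib] <- rate[ib] + gain * kv[seq_along(ib)]
    }
    sp <- t1k[stats::runif(n1k) < pmin(rate / 1000, 0.98)]
    units[[u]] <- unit_record(sp, unit_id = sprintf("u%02d", u),
                              quality = quality[u],
                              receptive_field = rf[u],
                              nucleus = preset$nucleus)
  }

  session <- whisk_session(
    trace = whisker_trace(w, fs),
    object = whisker_trace(o, fs),
    contacts = contacts, licks = licks, units = units,
    metadata = list(group = preset$group, nucleus = preset$nucleus,
                    session_id = sprintf("%s_seed%d", preset$name,
                                         as.integer(seed)))
  )
  ground_truth <- list(
    contact_state = contact_state,
    contact_time = contacts$time,
    contact_deceleration = decel[!is.na(contact_time)],
    transitions = transitions,
    units = data.frame(
      unit_id = vapply(units, `[[`, "", "unit_id"),
      gating_factor = g,
      baseline_ratio = ifelse(zero_base, Inf, bratio),
      onset_increment = inc,
      rest_rate = rest,
      whisking_rate = ifelse(zero_base, whisk_rate_zero, rest * bratio),
      evoked_peak_rate = peak,
      double_peak = dbl,
      first_peak_ms = vapply(kernels, `[[`, 0, "first_peak_ms"),
      second_peak_ms = vapply(kernels, `[[`, 0, "second_peak_ms"),
      interneuron = is_int,
      stringsAsFactors = FALSE
    ),
    preset = preset$name, seed = as.integer(seed)
  )
  list(session = session, ground_truth = ground_truth)
}

#' Synthesize an extracellular voltage trace from a session's spike trains
#'
#' Sums per-unit biphasic spike templates (distinct amplitudes and widths)
#' at the session's spike times, adds white noise, and band-passes the result
#' to 200-5000 Hz at 40 kHz, mirroring the recording chain the sorting stage
#' expects. Snippet-level ground truth (true trough time and unit identity)
#' is returned alongside.
#'
#' @param session a `whisk_session` with spike trains
#' @param noise_sd white-noise standard deviation (microvolts), > 0
#' @param seed integer seed for the noise stream
#' @param rate output sampling rate (Hz)
#' @param amplitudes optional per-unit template trough amplitudes (uV);
#'   defaults to 120, 210, 300, ... Note the artifact-rejection stage of the
#'   sorter removes waveforms beyond 10 trace SDs, so very large templates on
#'   quiet traces are discarded by design
#' @return list with `voltage` (a `voltage_trace`) and `truth` (data.frame of
#'   trough `time` and `unit_id` per placed spike)
#' @export
generate_voltage_trace <- function(session, noise_sd = 6, seed = 1,
                                   rate = 40000, amplitudes = NULL) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  nu <- length(session$units)
  if (is.null(amplitudes)) amplitudes <- 120 + 90 * (seq_len(nu) - 1)
  dur <- length(session$trace$samples) / session$trace$rate
  n <- round(dur * rate)
  set.seed(sub_seeds(seed, 1))
  v <- stats::rnorm(n, sd = noise_sd)
  tau <- ((-12):32) / rate * 1000   # ms, trough at sample 13
  truth <- list()
  for (u in seq_len(nu)) {
    A <- amplitudes[u]
    s1 <- 0.15 + 0.04 * ((u - 1) %% 3)
    tmpl <- -A * exp(-tau^2 / (2 * s1^2)) +
      0.45 * A * exp(-(tau - 0.35)^2 / (2 * 0.25^2))
    st <- session$units[[u]]$spike_times
    ci <- round(st * rate) + 1L
    ci <- ci[ci > 12 & ci <= n - 32]
    for (j in ci) v[(j - 12):(j + 32)] <- v[(j - 12):(j + 32)] + tmpl
    truth[[u]] <- data.frame(time = (ci - 1) / rate,
                             unit_id = rep(session$units[[u]]$unit_id,
                                           length(ci)))
  }
  bp <- signal::butter(3, c(200, 5000) / (rate / 2), type = "pass")
  v <- signal::filtfilt(bp, v)
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$time), , drop = FALSE]
  rownames(truth) <- NULL
  list(voltage = voltage_trace(v, rate = rate), truth = truth)
}
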