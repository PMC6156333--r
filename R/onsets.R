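# Whisking-onset detection away from contacts, onset-triggered firing, and
# kinematics-spiking relationships.

#' Detect whisking onsets with a sliding velocity-ratio window
#'
#' Slides a 500 ms window with 75% overlap (125 ms stride) across the 1 kHz
#' trace and computes the ratio of mean absolute velocities between the
#' second and first window halves. Windows are retained when the ratio
#' exceeds the session's 95th percentile of all windows' ratios, the
#' first-half mean absolute velocity is below 0.1 m/s, and no contact or
#' lick falls inside the window. The onset is the window midpoint. A session
#' is valid for onset analyses only with at least `min_windows` retained
#' windows.
#'
#' @param trace preprocessed 1 kHz `whisker_trace`
#' @param contacts contact times (s) or the session contact data.frame
#' @param licks lick times (s) or the session lick data.frame
#' @param window_s window length (s)
#' @param overlap fractional overlap of consecutive windows
#' @param rest_velocity first-half mean |velocity| ceiling (m/s)
#' @param percentile ratio percentile a window must exceed
#' @param min_windows minimum retained windows for a valid session
#' @return list (WhiskOnsetSet): `onset_times`, `velocity_ratio`,
#'   `window` (s), `session_valid`, `n_candidates`
#' @export
detect_whisking_onsets <- function(trace, contacts = numeric(),
                                   licks = numeric(), window_s = 0.5,
                                   overlap = 0.75, rest_velocity = 0.1,
                                   percentile = 0.95, min_windows = 10) {
  if (is.data.frame(contacts)) contacts <- contacts$time
  if (is.data.frame(licks)) licks <- licks$time
  if (trace$rate != 1000) stop("onset detection expects the 1 kHz trace")
  n <- length(trace$samples)
  win <- round(window_s * trace$rate)
  if (n < win) stop("trace shorter than one onset window")
  half <- win %/% 2
  step <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, n - win + 1L, by = step)
  v <- abs(derive_kinematics(trace)$velocity)
  cs <- c(0, cumsum(v))
  m1 <- (cs[starts + half] - cs[starts]) / half
  m2 <- (cs[starts + win] - cs[starts + half]) / half
  ratio <- ifelse(m1 > 0, m2 / m1, NA_real_)
  thr <- stats::quantile(ratio, percentile, na.rm = TRUE, names = FALSE)
  t_start <- trace$t0 + (starts - 1) / trace$rate
  t_end <- t_start + window_s
  ev <- sort(c(contacts, licks))
  has_event <- vapply(seq_along(starts), function(i)
    any(ev >= t_start[i] & ev <= t_end[i]), TRUE)
  # strict exceedance with a tiny relative guard so degenerate sessions
  # (all ratios equal up to rounding) retain nothing
  keep <- !is.na(ratio) & ratio > thr * (1 + 1e-9) & m1 < rest_velocity &
    !has_event
  onsets <- t_start[keep] + window_s / 2
  structure(list(onset_times = onsets, velocity_ratio = ratio[keep],
                 window = window_s, session_valid = sum(keep) >= min_windows,
                 n_candidates = length(starts), threshold = thr),
            class = "whisk_onset_set")
}

#' Onset-triggered firing of one unit
#'
#' Bins each unit's spikes around every retained onset, computes per-window
#' firing rates in the pre- and post-onset halves (250 ms each), the
#' baseline-subtracted onset-triggered rate trace (10 ms bins), the
#' post-minus-pre rate increment, and the AUC effect size between the
#' per-window pre and post rates. Units with fewer than `min_pre_spikes`
#' spikes pooled over the pre-onset halves are ineligible.
#'
#' @param unit a `unit_record`
#' @param onsets a `whisk_onset_set` (must be session-valid)
#' @param bin rate-trace bin width (s)
#' @param min_pre_spikes eligibility threshold on pooled pre-onset spikes
#' @return list (OnsetResponse): `unit_id`, `eligible`, `pre_rate`,
#'   `post_rate`, `increment` (Hz), `effect_size`, `rate_trace`
#'   (data.frame, baseline-subtracted), `n_windows`
#' @export
onset_response <- function(unit, onsets, bin = 0.01, min_pre_spikes = 10) {
  if (!isTRUE(onsets$session_valid))
    stop("session has fewer than the minimum number of onset windows")
  half <- onsets$window / 2
  sp <- unit$spike_times
  ot <- onsets$onset_times
  cnt <- function(a, b) {  # spikes in [a, b) per onset window
    findInterval(b - 1e-9, sp) - findInterval(a - 1e-9, sp)
  }
  pre <- cnt(ot - half, ot)
  post <- cnt(ot, ot + half)
  out <- list(unit_id = unit$unit_id, n_windows = length(ot),
              eligible = sum(pre) >= min_pre_spikes)
  if (!out$eligible) {
    out$reason <- sprintf("only %d pre-onset spikes (minimum %d)",
                          sum(pre), min_pre_spikes)
    return(out)
  }
  pre_r <- pre / half
  post_r <- post / half
  p <- compute_psth(unit, ot, window = c(-half, half), bin = bin)
  base <- mean(pre_r)
  out$pre_rate <- base
  out$post_rate <- mean(post_r)
  out$increment <- out$post_rate - base
  out$effect_size <- auc_effect_size(post_r, pre_r)
  out$rate_trace <- data.frame(time_ms = p$bin_left, rate = p$rate - base)
  out
}

#' Onset analysis over all units of a session
#'
#' @param session a `whisk_session`
#' @param onsets a `whisk_onset_set`; sessions with too few windows
#'   contribute no units
#' @return data.frame with one row per eligible unit (`unit_id`, `pre_rate`,
#'   `post_rate`, `increment`, `effect_size`) plus attribute `n_excluded`
#' @export
analyze_onsets <- function(session, onsets) {
  if (!isTRUE(onsets$session_valid)) {
    out <- data.frame(unit_id = character(), pre_rate = numeric(),
                      post_rate = numeric(), increment = numeric(),
                      effect_size = numeric())
    attr(out, "n_excluded") <- length(session$units)
    return(out)
  }
  res <- lapply(session$units, onset_response, onsets = onsets)
  ok <- vapply(res, `[[`, TRUE, "eligible")
  rows <- lapply(res[ok], function(r)
    data.frame(unit_id = r$unit_id, pre_rate = r$pre_rate,
               post_rate = r$post_rate, increment = r$increment,
               effect_size = r$effect_size, stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), pre_rate = numeric(),
               post_rate = numeric(), increment = numeric(),
               effect_size = numeric())
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Trial-wise kinematics and their relationship to spiking and gating
#'
#' Builds the per-trial kinematic table (whisker position at contact, raw
#' and normalised to the interquartile range of whisking-trial positions;
#' mean pre-contact velocity and acceleration over [-20, 0) ms; minimum
#' peri-contact acceleration over [-5, +5] ms), computes per-unit,
#' per-state Pearson correlations of evoked spike counts ([0, 10) ms) with
#' each parameter, Spearman correlations of trial-wise gating ratios with
#' pre-contact velocity and acceleration, and a population signed-rank test
#' of whether each correlation distribution differs from zero.
#'
#' @param units list of `unit_record`
#' @param classification matched classification data.frame (from
#'   [classify_contacts()] + [match_decelerations()])
#' @param min_trials minimum trials per state for a correlation
#' @return list (KinematicsTable): `trials`, `unit_correlations`,
#'   `gating_correlations`, `population_tests`
#' @export
kinematics_analysis <- function(units, classification, min_trials = 5) {
  cl <- classification[classification$matched %in% TRUE, , drop = FALSE]
  iqr_w <- stats::IQR(cl$position_at_contact[cl$label == "whisking"])
  trials <- data.frame(
    contact_time = cl$contact_time, label = cl$label,
    position = cl$position_at_contact,
    position_norm = if (iqr_w > 0) cl$position_at_contact / iqr_w else
      NA_real_,
    pre_velocity = cl$mean_velocity_20ms,
    pre_acceleration = cl$mean_acceleration_20ms,
    min_acceleration = cl$min_peri_deceleration
  )
  params <- c("position", "pre_velocity", "pre_acceleration",
              "min_acceleration")
  safe_cor <- function(x, y, method = "pearson") {
    if (length(x) < min_trials || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, method = method)
  }
  unit_rows <- list(); gate_rows <- list()
  for (u in units) {
    p <- compute_psth(u, trials$contact_time)
    counts <- rowSums(p$counts[, psth_bins_in(p, EVOKED_MS), drop = FALSE])
    for (st in c("whisking", "non_whisking")) {
      m <- trials$label == st
      if (sum(m) < min_trials) next
      unit_rows[[paste(u$unit_id, st)]] <- data.frame(
        unit_id = u$unit_id, state = st,
        t(vapply(params, function(pp)
          safe_cor(trials[[pp]][m], counts[m]), 0)),
        stringsAsFactors = FALSE)
    }
    tg <- try(trialwise_gating(u, classification), silent = TRUE)
    if (!inherits(tg, "try-error")) {
      m <- match(tg$contact_time, trials$contact_time)
      gate_rows[[u$unit_id]] <- data.frame(
        unit_id = u$unit_id,
        velocity = safe_cor(trials$pre_velocity[m], tg$ratio, "spearman"),
        acceleration = safe_cor(trials$pre_acceleration[m], tg$ratio,
                                "spearman"),
        stringsAsFactors = FALSE)
    }
  }
  ucor <- if (length(unit_rows)) do.call(rbind, unit_rows) else NULL
  gcor <- if (length(gate_rows)) do.call(rbind, gate_rows) else NULL
  pop <- list()
  if (!is.null(ucor)) {
    for (pp in params) {
      x <- ucor[[pp]][is.finite(ucor[[pp]])]
      if (length(x) >= 5 && any(x != 0))
        pop[[pp]] <- signed_rank_test(x, mu = 0)
    }
  }
  if (!is.null(gcor)) {
    for (pp in c("velocity", "acceleration")) {
      x <- gcor[[pp]][is.finite(gcor[[pp]])]
      if (length(x) >= 5 && any(x != 0))
        pop[[paste0("gating_", pp)]] <- signed_rank_test(x, mu = 0)
    }
  }
  rownames(ucor) <- rownames(gcor) <- NULL
  list(trials = trials, unit_correlations = ucor,
       gating_correlations = gcor, population_tests = pop)
}
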