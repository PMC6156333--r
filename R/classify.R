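# Whisker-trace preprocessing, contact windowing and whisking/non-whisking
# classification from pre-contact kinematics.

#' Preprocess a raw whisker trace
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth low-pass at 100 Hz,
#' followed by a 7.5 ms median filter, then resampling to 1 kHz aligned to
#' the input time base. Zero-phase filtering is used so that contact-aligned
#' response latencies are not shifted by the filter delay.
#'
#' @param raw a `whisker_trace` at >= 1 kHz
#' @param lowpass_hz low-pass corner frequency (Hz)
#' @param median_width_s median-filter width (s)
#' @param out_rate output rate (Hz)
#' @return a `whisker_trace` at `out_rate`
#' @export
preprocess_trace <- function(raw, lowpass_hz = 100, median_width_s = 0.0075,
                             out_rate = 1000) {
  if (raw$rate < 200)
    stop("trace rate below 200 Hz: low-pass filter undefined near Nyquist")
  x <- raw$samples
  bf <- signal::butter(3, lowpass_hz / (raw$rate / 2), type = "low")
  # odd-reflection padding removes the forward-backward filter's edge
  # transients (the unpadded startup would bleed ~50 ms into the trace)
  n <- length(x)
  k <- min(n - 1, round(raw$rate / lowpass_hz) * 10)
  if (k > 1) {
    xp <- c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
    x <- signal::filtfilt(bf, xp)[(k + 1):(k + n)]
  } else {
    x <- signal::filtfilt(bf, x)
  }
  k <- round(median_width_s * raw$rate)
  if (k %% 2 == 0) k <- k + 1
  if (k >= 3 && k < length(x)) x <- stats::runmed(x, k, endrule = "keep")
  if (raw$rate == out_rate) return(whisker_trace(x, out_rate, raw$t0))
  n_out <- floor(length(x) * out_rate / raw$rate)
  t_out <- raw$t0 + (seq_len(n_out) - 1) / out_rate
  y <- stats::approx(trace_times(raw), x, xout = t_out, rule = 2)$y
  whisker_trace(y, out_rate, raw$t0)
}

#' Derive velocity and acceleration from a position trace
#'
#' Central first differences scaled by the sampling rate (one-sided at the
#' ends); acceleration is the same operator applied to the velocity.
#'
#' @param trace a `whisker_trace` (typically the preprocessed 1 kHz trace)
#' @return list with numeric vectors `velocity` (m/s) and `acceleration`
#'   (m/s^2), same length as the trace
#' @export
derive_kinematics <- function(trace) {
  x <- trace$samples
  if (length(x) < 3) stop("trace shorter than 3 samples")
  v <- central_diff(x) * trace$rate
  a <- central_diff(v) * trace$rate
  list(velocity = v, acceleration = a)
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Extract peri-contact kinematic windows
#'
#' One window per contact, spanning [-75, +75] ms at 1 kHz (151 samples).
#' Windows containing a lick or another contact are marked excluded, as are
#' contacts too close to the trace boundary.
#'
#' @param session a `whisk_session`
#' @param trace optional preprocessed 1 kHz trace (computed from
#'   `session$trace` if omitted)
#' @param half_width_s half window width (s)
#' @return list of `contact_window` objects with fields `contact_time`,
#'   `position`, `velocity`, `acceleration` (151-sample arrays), `valid` and
#'   `reason`
#' @export
extract_contact_windows <- function(session, trace = NULL,
                                    half_width_s = 0.075) {
  if (is.null(trace)) trace <- preprocess_trace(session$trace)
  if (trace$rate != 1000) stop("windows are defined on the 1 kHz trace")
  kin <- derive_kinematics(trace)
  times <- trace_times(trace)
  nh <- round(half_width_s * trace$rate)
  ct <- session$contacts$time
  lk <- session$licks$time
  lapply(seq_along(ct), function(i) {
    tc <- ct[i]
    ic <- round((tc - trace$t0) * trace$rate) + 1L
    out <- list(contact_time = tc, position = NULL, velocity = NULL,
                acceleration = NULL, valid = TRUE, reason = NA_character_)
    if (ic - nh < 1 || ic + nh > length(times)) {
      out$valid <- FALSE; out$reason <- "boundary"
    } else {
      idx <- (ic - nh):(ic + nh)
      out$position <- trace$samples[idx]
      out$velocity <- kin$velocity[idx]
      out$acceleration <- kin$acceleration[idx]
      lo <- tc - half_width_s; hi <- tc + half_width_s
      if (any(ct[-i] >= lo & ct[-i] <= hi)) {
        out$valid <- FALSE; out$reason <- "second_contact"
      } else if (any(lk >= lo & lk <= hi)) {
        out$valid <- FALSE; out$reason <- "lick"
      }
    }
    class(out) <- "contact_window"
    out
  })
}

# window sample index of the contact (t = 0) for 151-sample windows
.W0 <- 76L

window_scalars <- function(wnd) {
  v <- wnd$velocity; a <- wnd$acceleration
  c(mean_vel_10 = mean(v[(.W0 - 10):(.W0 - 1)]),
    rms_vel_75 = sqrt(mean(v[(.W0 - 75):(.W0 - 1)]^2)),
    min_acc_5 = min(a[(.W0 - 5):(.W0 + 5)]),
    mean_vel_20 = mean(v[(.W0 - 20):(.W0 - 1)]),
    mean_acc_20 = mean(a[(.W0 - 20):(.W0 - 1)]),
    position_at_contact = wnd$position[.W0])
}

#' Classify contacts as whisking or non-whisking
#'
#' Builds the histogram of pre-contact mean velocities (10 ms preceding
#' contact), fits a Gaussian to the peak closest to zero by least squares,
#' and labels a contact non-whisking iff its mean pre-contact velocity lies
#' within two fitted standard deviations of the fitted mean AND the RMS
#' whisker velocity over the 75 ms before contact is below 0.001 m/s.
#' All other (valid) contacts are labelled whisking.
#'
#' Because the rest-state velocity mode is orders of magnitude narrower than
#' the whisking mode, the Gaussian is fitted on a refined Freedman-Diaconis
#' histogram of the velocities within 0.02 m/s of zero after the zero-adjacent
#' mode has been located on the global histogram.
#'
#' @param windows list of `contact_window` from [extract_contact_windows()]
#' @param rms_threshold RMS velocity criterion (m/s)
#' @return list with `classification` (data.frame: `contact_time`, `label`,
#'   `pre_contact_mean_velocity`, `pre_contact_rms_velocity`,
#'   `min_peri_deceleration`, `mean_velocity_20ms`, `mean_acceleration_20ms`,
#'   `position_at_contact`, `matched`) and `fit`
#'   (a `velocity_distribution_fit`: histogram, Gaussian mu/sigma/amplitude,
#'   non-whisking band)
#' @export
classify_contacts <- function(windows, rms_threshold = 0.001) {
  valid <- vapply(windows, `[[`, TRUE, "valid")
  if (sum(valid) < 20)
    stop("fewer than 20 valid contact windows: velocity histogram fit unreliable")
  sc <- t(vapply(windows[valid],
                 function(w) window_scalars(w), numeric(6)))
  mv <- sc[, "mean_vel_10"]
  fit <- fit_zero_velocity_mode(mv)
  band <- c(fit$mu - 2 * fit$sigma, fit$mu + 2 * fit$sigma)

  lab <- rep("excluded", length(windows))
  pm <- pr <- md <- v20 <- a20 <- pos <- rep(NA_real_, length(windows))
  j <- 0L
  for (i in seq_along(windows)) {
    if (!valid[i]) next
    j <- j + 1L
    pm[i] <- sc[j, "mean_vel_10"]; pr[i] <- sc[j, "rms_vel_75"]
    md[i] <- sc[j, "min_acc_5"]; v20[i] <- sc[j, "mean_vel_20"]
    a20[i] <- sc[j, "mean_acc_20"]; pos[i] <- sc[j, "position_at_contact"]
    lab[i] <- if (pm[i] >= band[1] && pm[i] <= band[2] &&
                  pr[i] < rms_threshold) "non_whisking" else "whisking"
  }
  cls <- data.frame(
    contact_time = vapply(windows, `[[`, 0, "contact_time"),
    label = lab,
    pre_contact_mean_velocity = pm,
    pre_contact_rms_velocity = pr,
    min_peri_deceleration = md,
    mean_velocity_20ms = v20,
    mean_acceleration_20ms = a20,
    position_at_contact = pos,
    exclusion_reason = vapply(windows, `[[`, "", "reason"),
    matched = NA,
    stringsAsFactors = FALSE
  )
  list(classification = cls, fit = fit)
}

# Locate the velocity-histogram mode nearest zero and least-squares fit a
# Gaussian to it. Bin width by Freedman-Diaconis with a 60-bin fallback.
fit_zero_velocity_mode <- function(mv, zero_radius = 0.02) {
  fd_breaks <- function(x, fallback = 60) {
    iqr <- stats::IQR(x)
    h <- 2 * iqr / length(x)^(1 / 3)
    if (!is.finite(h) || h <= 0) h <- diff(range(x)) / fallback
    if (h <= 0) h <- 1e-6
    nb <- max(10, ceiling(diff(range(x)) / h))
    seq(min(x) - h / 2, max(x) + h / 2, length.out = nb + 1)
  }
  hist_all <- graphics::hist(mv, breaks = fd_breaks(mv), plot = FALSE)
  near <- mv[abs(mv) <= zero_radius]
  if (length(near) < 10)
    stop("bimodality not detected: no velocity mode adjacent to zero")
  h <- graphics::hist(near, breaks = fd_breaks(near), plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  pk <- which.max(cnt)
  # contiguous bins down to half maximum around the mode
  lo <- pk; while (lo > 1 && cnt[lo - 1] >= cnt[pk] / 2) lo <- lo - 1
  hi <- pk; while (hi < length(cnt) && cnt[hi + 1] >= cnt[pk] / 2) hi <- hi + 1
  lo <- max(1, lo - 1); hi <- min(length(cnt), hi + 1)
  xs <- mids[lo:hi]; ys <- cnt[lo:hi]
  if (length(xs) < 3) stop("bimodality not detected: degenerate zero mode")
  # least-squares Gaussian; moment-based start values
  mu0 <- sum(xs * ys) / sum(ys)
  s0 <- sqrt(max(sum(ys * (xs - mu0)^2) / sum(ys), 1e-12))
  fit <- try(suppressWarnings(
    stats::nls(ys ~ A * exp(-(xs - mu)^2 / (2 * sg^2)),
               start = list(A = max(ys), mu = mu0, sg = s0),
               control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    A <- max(ys); mu <- mu0; sg <- s0
  } else {
    cf <- stats::coef(fit)
    A <- cf[["A"]]; mu <- cf[["mu"]]; sg <- abs(cf[["sg"]])
  }
  if (!is.finite(sg) || sg <= 0)
    stop("degenerate velocity-mode fit: sigma = 0")
  structure(list(histogram = list(breaks = hist_all$breaks,
                                  counts = hist_all$counts),
                 mu = mu, sigma = sg, amplitude = A,
                 nonwhisk_band = c(mu - 2 * sg, mu + 2 * sg)),
            class = "velocity_distribution_fit")
}

#' Deceleration-matched trial selection
#'
#' Whisking contacts carry systematically stronger contact decelerations; to
#' avoid force biases, only trials whose minimum peri-contact acceleration
#' ([-5, +5] ms) falls in the overlap of the two classes' distributions are
#' retained. Overlap is taken as the intersection of the per-class
#' [5th, 95th] percentile ranges.
#'
#' @param classification data.frame from [classify_contacts()]
#' @param probs percentile bounds defining each class's range
#' @return the classification with the `matched` flag set
#' @export
match_decelerations <- function(classification, probs = c(0.05, 0.95)) {
  w <- classification$label == "whisking"
  nw <- classification$label == "non_whisking"
  if (!any(w) || !any(nw))
    stop("both contact classes must be non-empty for deceleration matching")
  qw <- stats::quantile(classification$min_peri_deceleration[w], probs,
                        na.rm = TRUE, names = FALSE)
  qn <- stats::quantile(classification$min_peri_deceleration[nw], probs,
                        na.rm = TRUE, names = FALSE)
  lo <- max(qw[1], qn[1]); hi <- min(qw[2], qn[2])
  if (lo > hi) stop("no overlap; cannot match")
  classification$matched <- (w | nw) &
    classification$min_peri_deceleration >= lo &
    classification$min_peri_deceleration <= hi
  classification$matched[is.na(classification$matched)] <- FALSE
  attr(classification, "match_range") <- c(lo, hi)
  classification
}
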