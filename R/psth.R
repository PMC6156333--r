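# Peri-contact PSTHs and per-unit sensory-gating statistics.
#
# Conventions (used by every analysis in the package): peri-contact window
# [-20, 50) ms at 1 ms resolution (70 half-open bins); "baseline" is the
# 10 ms window [-20, -10) ms before contact and "evoked" the window
# [0, 10) ms after contact.

PSTH_WINDOW <- c(-0.02, 0.05)
PSTH_BIN <- 0.001
BASE_MS <- c(-20, -10)
EVOKED_MS <- c(0, 10)

#' Peri-event spike-time histogram
#'
#' Bins each unit's spikes into half-open 1 ms bins relative to each event.
#' A spike exactly at the event time falls into bin [0, 1) ms; the window is
#' half-open, so a spike at the left window edge is counted and one at the
#' right edge is not.
#'
#' @param unit a `unit_record` or numeric vector of spike times (s)
#' @param events event (contact) times (s); at least one required
#' @param window peri-event window (s), default [-20, 50) ms
#' @param bin bin width (s)
#' @return object of class `psth`: `counts` (trials x bins matrix),
#'   `bin_left` (ms, left edges), `rate` (Hz, mean across trials),
#'   `trial_count`
#' @export
compute_psth <- function(unit, events, window = PSTH_WINDOW, bin = PSTH_BIN) {
  sp <- if (inherits(unit, "unit_record")) unit$spike_times else as.numeric(unit)
  events <- as.numeric(events)
  if (!length(events)) stop("no events: PSTH undefined")
  nb <- round(diff(window) / bin)
  counts <- matrix(0L, nrow = length(events), ncol = nb)
  if (length(sp)) {
    tiny <- 1e-9
    i1 <- findInterval(events + window[1] - tiny, sp) + 1L
    i2 <- findInterval(events + window[2] - tiny, sp)
    for (k in seq_along(events)) {
      if (i2[k] < i1[k]) next
      off <- sp[i1[k]:i2[k]] - events[k] - window[1]
      b <- floor((off + 1e-12) / bin) + 1L
      b <- b[b >= 1 & b <= nb]
      counts[k, ] <- tabulate(b, nbins = nb)
    }
  }
  structure(list(counts = counts,
                 bin_left = (window[1] + bin * (seq_len(nb) - 1)) * 1000,
                 bin = bin, window = window,
                 trial_count = length(events),
                 rate = colMeans(counts) / bin),
            class = "psth")
}

psth_bins_in <- function(psth, range_ms) {
  psth$bin_left >= range_ms[1] & psth$bin_left < range_ms[2]
}

#' 3 ms boxcar smoothing with shrink-to-valid edges
#'
#' Edge bins are averaged over the neighbours that exist, so no out-of-window
#' rates are fabricated.
#' @param x numeric vector (rate trace)
#' @param width boxcar width in bins (odd)
#' @return smoothed vector
#' @export
boxcar_smooth <- function(x, width = 3) {
  n <- length(x); h <- (width - 1) %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), 0)
}

#' Unit inclusion criterion
#'
#' A unit is analysed only if its evoked firing rate (mean over [0, 10) ms)
#' exceeds the baseline rate by three standard deviations, where baseline
#' mean and SD are taken across the ten 1 ms baseline bins ([-20, -10) ms)
#' of the trial-averaged PSTH over all valid trials.
#'
#' @param psth a `psth` computed over all valid trials
#' @return logical flag
#' @export
include_unit <- function(psth) {
  b <- psth$rate[psth_bins_in(psth, BASE_MS)]
  e <- psth$rate[psth_bins_in(psth, EVOKED_MS)]
  mean(e) > mean(b) + 3 * stats::sd(b)
}

#' Peak evoked rate
#'
#' Subtracts the state's mean baseline rate, smooths the corrected rate trace
#' with a centred 3 ms boxcar, and returns the maximum over the evoked window
#' [0, 10) ms.
#'
#' @param psth a `psth` for one trial state
#' @return peak evoked rate (Hz, baseline-corrected)
#' @export
evoked_peak <- function(psth) {
  base <- mean(psth$rate[psth_bins_in(psth, BASE_MS)])
  sm <- boxcar_smooth(psth$rate - base)
  max(sm[psth_bins_in(psth, EVOKED_MS)])
}

#' Per-unit gating summary
#'
#' Computes whisking (W) and non-whisking (NW) PSTHs on deceleration-matched
#' trials, the per-state baseline rates W-bar and NW-bar, the evoked-peak
#' ratio W_max/NW_max and the baseline ratio W-bar/NW-bar (flagged infinite
#' when the non-whisking baseline is zero), plus the 3 SD inclusion flag
#' computed on all valid trials.
#'
#' @param unit a `unit_record`
#' @param classification matched classification data.frame (needs columns
#'   `contact_time`, `label`, `matched`)
#' @param matched_only use only deceleration-matched trials (default TRUE)
#' @return one-row data.frame (GatingSummary)
#' @export
gating_summary <- function(unit, classification, matched_only = TRUE) {
  sel <- if (matched_only) classification$matched %in% TRUE else
    classification$label != "excluded"
  tw <- classification$contact_time[sel & classification$label == "whisking"]
  tn <- classification$contact_time[sel & classification$label == "non_whisking"]
  if (!length(tw) || !length(tn))
    stop("unit ", unit$unit_id, ": a contact class has zero matched trials")
  all_t <- classification$contact_time[classification$label != "excluded"]
  psth_all <- compute_psth(unit, all_t)
  pw <- compute_psth(unit, tw)
  pn <- compute_psth(unit, tn)
  bw <- mean(pw$rate[psth_bins_in(pw, BASE_MS)])
  bn <- mean(pn$rate[psth_bins_in(pn, BASE_MS)])
  wmax <- evoked_peak(pw)
  nwmax <- evoked_peak(pn)
  data.frame(unit_id = unit$unit_id,
             W_max = wmax, NW_max = nwmax,
             mean_baseline_W = bw, mean_baseline_NW = bn,
             evoked_ratio = wmax / nwmax,
             baseline_ratio = if (bn == 0) Inf else bw / bn,
             infinite_baseline_ratio = bn == 0,
             n_whisking = length(tw), n_non_whisking = length(tn),
             included = include_unit(psth_all),
             stringsAsFactors = FALSE)
}

#' Extract the first two evoked peaks per state and their gating
#'
#' On each 3 ms boxcar-smoothed PSTH, finds the first two local maxima after
#' contact that exceed the baseline mean by three baseline SDs and are at
#' least 3 ms apart. W and NW peaks are paired by order; the pair is
#' invalidated if corresponding latencies differ by more than 5 ms. Per-peak
#' gating is the ratio of baseline-corrected W and NW peak rates.
#'
#' @param psth_W,psth_NW per-state `psth` objects
#' @return list (PeakPair): `first_peak`, `second_peak` (each with per-state
#'   latency/rate and `gating`, or NULL), `valid`
#' @export
detect_peaks <- function(psth_W, psth_NW) {
  find2 <- function(psth) {
    base_bins <- psth$rate[psth_bins_in(psth, BASE_MS)]
    thr <- mean(base_bins) + 3 * stats::sd(base_bins)
    sm <- boxcar_smooth(psth$rate)
    post <- which(psth$bin_left >= 0)
    pk <- integer(0)
    for (i in post) {
      if (i > 1 && i < length(sm) && sm[i] > sm[i - 1] && sm[i] >= sm[i + 1] &&
          sm[i] > thr) {
        if (!length(pk)) pk <- i
        else if (psth$bin_left[i] - psth$bin_left[pk[1]] >= 3) {
          pk <- c(pk, i); break
        }
      }
    }
    list(idx = pk, lat = psth$bin_left[pk] + 0.5,
         rate = sm[pk] - mean(base_bins))
  }
  w <- find2(psth_W); nw <- find2(psth_NW)
  out <- list(first_peak = NULL, second_peak = NULL, valid = FALSE)
  if (!length(w$idx) || !length(nw$idx)) return(out)
  mk <- function(k) list(latency_W = w$lat[k], latency_NW = nw$lat[k],
                         rate_W = w$rate[k], rate_NW = nw$rate[k],
                         gating = w$rate[k] / nw$rate[k])
  if (abs(w$lat[1] - nw$lat[1]) > 5) return(out)
  out$first_peak <- mk(1)
  out$valid <- TRUE
  if (length(w$idx) >= 2 && length(nw$idx) >= 2) {
    if (abs(w$lat[2] - nw$lat[2]) <= 5) out$second_peak <- mk(2)
  }
  out
}

#' Trial-wise sensory gating
#'
#' Divides the evoked spike count ([0, 10) ms) of each whisking trial by the
#' median evoked count across all non-whisking trials; values below 1
#' indicate gating.
#'
#' @param unit a `unit_record`
#' @param classification matched classification data.frame
#' @param matched_only use matched trials only
#' @return data.frame with `contact_time` and `ratio`, one row per whisking
#'   trial
#' @export
trialwise_gating <- function(unit, classification, matched_only = TRUE) {
  sel <- if (matched_only) classification$matched %in% TRUE else
    classification$label != "excluded"
  tw <- classification$contact_time[sel & classification$label == "whisking"]
  tn <- classification$contact_time[sel & classification$label == "non_whisking"]
  if (!length(tn)) stop("trialwise gating undefined: no non-whisking trials")
  count10 <- function(ev) {
    p <- compute_psth(unit, ev)
    rowSums(p$counts[, psth_bins_in(p, EVOKED_MS), drop = FALSE])
  }
  mednw <- stats::median(count10(tn))
  if (mednw == 0)
    stop("trialwise gating undefined: zero median non-whisking count")
  data.frame(contact_time = tw, ratio = count10(tw) / mednw)
}

#' Gating analysis over all units of a session
#'
#' Runs [gating_summary()] and [detect_peaks()] for every unit; units for
#' which a contact class has no matched trials are reported as excluded
#' rather than dropped.
#'
#' @param session a `whisk_session`
#' @param classification matched classification data.frame
#' @param matched_only use matched trials only
#' @return data.frame with one row per unit (gating summary plus peak-pair
#'   fields); attribute `"psth"` carries the per-unit state PSTHs
#' @export
analyze_gating <- function(session, classification, matched_only = TRUE) {
  rows <- list(); psths <- list()
  for (u in session$units) {
    g <- try(gating_summary(u, classification, matched_only), silent = TRUE)
    if (inherits(g, "try-error")) {
      rows[[u$unit_id]] <- data.frame(
        unit_id = u$unit_id, W_max = NA_real_, NW_max = NA_real_,
        mean_baseline_W = NA_real_, mean_baseline_NW = NA_real_,
        evoked_ratio = NA_real_, baseline_ratio = NA_real_,
        infinite_baseline_ratio = NA, n_whisking = 0L, n_non_whisking = 0L,
        included = FALSE, first_peak_W_ms = NA_real_,
        second_peak_W_ms = NA_real_, gating_peak1 = NA_real_,
        gating_peak2 = NA_real_, peaks_valid = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    sel <- if (matched_only) classification$matched %in% TRUE else
      classification$label != "excluded"
    pw <- compute_psth(u, classification$contact_time[
      sel & classification$label == "whisking"])
    pn <- compute_psth(u, classification$contact_time[
      sel & classification$label == "non_whisking"])
    pall <- compute_psth(u, classification$contact_time[
      classification$label != "excluded"])
    pk <- detect_peaks(pw, pn)
    g$first_peak_W_ms <- if (pk$valid) pk$first_peak$latency_W else NA_real_
    g$second_peak_W_ms <- if (!is.null(pk$second_peak))
      pk$second_peak$latency_W else NA_real_
    g$gating_peak1 <- if (pk$valid) pk$first_peak$gating else NA_real_
    g$gating_peak2 <- if (!is.null(pk$second_peak))
      pk$second_peak$gating else NA_real_
    g$peaks_valid <- pk$valid
    rows[[u$unit_id]] <- g
    psths[[u$unit_id]] <- list(W = pw, NW = pn, all = pall)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "psth") <- psths
  out
}
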