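# Shared fixtures: small generator presets, hand-built sessions and PSTHs,
# and a cache so the acceptance criteria can share simulated sessions.

tiny_preset <- function(name = "intact_pr5", n_units = 2, trial_count = 40) {
  generator_preset(name, n_units = n_units, trial_count = trial_count)
}

# a session with a flat (noise-only) whisker trace and hand-chosen spike
# trains; useful for sorting and PSTH fixtures
flat_session <- function(unit_spikes, dur = 60, rate = 1000, seed = 1) {
  set.seed(seed)
  tr <- whisker_trace(stats::rnorm(dur * rate, sd = 3e-7), rate)
  units <- lapply(seq_along(unit_spikes), function(i)
    unit_record(unit_spikes[[i]], unit_id = sprintf("f%02d", i)))
  whisk_session(tr, contacts = data.frame(time = numeric(),
                                          reward = logical()),
                licks = data.frame(time = numeric()), units = units,
                metadata = list(group = "intact", nucleus = "Pr5",
                                session_id = "fixture"))
}

# Poisson spike train on [0, dur) (true Poisson, not the generator's path)
poisson_spikes <- function(rate_hz, dur, seed) {
  set.seed(seed)
  n <- stats::rpois(1, rate_hz * dur)
  sp <- sort(stats::runif(n, 0, dur))
  sp[!duplicated(floor(sp * 1000))]   # acquisition-style 1 ms uniqueness
}

# fabricate a psth object from a known rate profile (Hz per 1 ms bin)
fake_psth <- function(rate, trial_count = 100) {
  structure(list(counts = matrix(rep(rate * 1e-3, each = trial_count),
                                 nrow = trial_count),
                 bin_left = seq(-20, 49), bin = 1e-3,
                 window = c(-0.02, 0.05), trial_count = trial_count,
                 rate = rate),
            class = "psth")
}

# a synthetic contact window with given velocity level (m/s)
fake_window <- function(contact_time, vel, vel_sd = 5e-5, seed = 1) {
  set.seed(seed + round(contact_time * 1000))
  v <- vel + stats::rnorm(151, sd = vel_sd)
  pos <- cumsum(v) / 1000
  a <- c(0, diff(v)) * 1000
  structure(list(contact_time = contact_time, position = pos, velocity = v,
                 acceleration = a, valid = TRUE, reason = NA_character_),
            class = "contact_window")
}

## ---- shared session analyses (used heavily by the acceptance suite) ----

.acc_cache <- new.env(parent = emptyenv())

acc_run <- function(preset, seed, onsets = FALSE, unmatched = FALSE) {
  key <- paste(preset, seed, onsets, unmatched, sep = "|")
  hit <- get0(key, envir = .acc_cache)
  if (!is.null(hit)) return(hit)
  gen <- generate_session(preset, seed)
  gt <- gen$ground_truth
  trace1k <- preprocess_trace(gen$session$trace)
  windows <- extract_contact_windows(gen$session, trace1k)
  cls <- classify_contacts(windows)
  cl <- match_decelerations(cls$classification)
  g <- analyze_gating(gen$session, cl)
  inc <- g$included %in% TRUE
  psths <- attr(g, "psth")
  rates <- t(vapply(psths[g$unit_id[inc]], function(p) p$all$rate,
                    numeric(70)))
  baselines <- vapply(psths[g$unit_id[inc]], function(p)
    mean(p$all$rate[p$all$bin_left >= -20 & p$all$bin_left < -10]), 0)
  out <- list(
    gating = g,
    agreement = mean(cl$label == gt$contact_state),
    matched_w = sum(cl$matched & cl$label == "whisking"),
    matched_nw = sum(cl$matched & cl$label == "non_whisking"),
    rates = rates, baselines = baselines,
    true_gating = gt$units$gating_factor
  )
  if (onsets) {
    on <- detect_whisking_onsets(trace1k, gen$session$contacts,
                                 gen$session$licks)
    out$onsets <- analyze_onsets(gen$session, on)
    out$onsets_valid <- on$session_valid
  }
  if (unmatched) {
    gu <- analyze_gating(gen$session, cl, matched_only = FALSE)
    out$evoked_unmatched <- gu$evoked_ratio[gu$included %in% TRUE]
  }
  assign(key, out, envir = .acc_cache)
  out
}
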