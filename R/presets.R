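# Named parameter bundles driving the synthetic-session generator.
#
# Per-unit quantities with a stated population mean and sd are drawn from
# log-normal distributions moment-matched to (mean, sd): the generator
# requires nonnegative support, and a truncated normal would shift the mean.

lnorm_from_mean_sd <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(dist = "lnorm", meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog,
       mean = mean, sd = sd)
}

lnorm_from_median <- function(median, sdlog) {
  list(dist = "lnorm", meanlog = log(median), sdlog = sdlog,
       mean = median * exp(sdlog^2 / 2), sd = NA_real_)
}

draw_lnorm <- function(n, d) stats::rlnorm(n, d$meanlog, d$sdlog)

#' Synthetic-session generator presets
#'
#' Returns the parameter bundle for one of the named recording conditions:
#' `"intact_pr5"` (lemniscal Pr5 units in intact animals: evoked gating
#' factor mean 0.7, sd 0.2; whisking/rest baseline ratio mean 3.8, sd 4.4;
#' 10/23 double-peaked units), `"lesioned_pr5"` (Pr5 after S1/S2 lesion:
#' gating mean 1.1, sd 0.6; baseline ratio mean 2.6, sd 2.0; narrow
#' single-peaked responses, no late component), `"sp5i"` (extralemniscal
#' interpolaris population: gating mean 1.1, sd 0.5; 17 of 64 units are
#' putative single-whisker interneurons with baseline ratio mean 1.1,
#' sd 0.5), and `"sp5i_interneuron"` (the interneuron subset alone).
#'
#' Whisking-onset rate increments are log-normal with median 13.6 Hz and
#' sdlog 1.266, reproducing the reported 46.9/8.5 interquartile ratio (a
#' log-normal cannot match that median and both quartiles simultaneously).
#'
#' @param name preset name
#' @param n_units number of units (defaults to the condition's population n)
#' @param trial_count number of trials per session (default 400; 47% carry
#'   whisking contacts, balancing per-class trial counts after
#'   deceleration matching)
#' @param zero_baseline_fraction probability that a unit has zero rest-state
#'   baseline rate (its rest/whisking baseline ratio is then infinite)
#' @return a list of class `generator_preset`
#' @export
generator_preset <- function(name = c("intact_pr5", "lesioned_pr5", "sp5i",
                                      "sp5i_interneuron"),
                             n_units = NULL, trial_count = 400,
                             zero_baseline_fraction = NULL) {
  name <- match.arg(name)
  base <- list(
    name = name,
    trial_count = trial_count,
    # rest-state baseline rates; median chosen so that the 10 ms x ~160-trial
    # baseline windows estimate per-state baselines stably (see vignette)
    rest_baseline_rate_dist = lnorm_from_median(12, 0.4),
    # narrower evoked responses carry comparable per-contact spike counts,
    # hence higher peak rates (lesioned/Sp5i kernels are much narrower)
    evoked_peak_rate_dist = lnorm_from_median(150, 0.4),
    onset_increment_dist = lnorm_from_median(13.6, 1.266),
    zero_baseline_fraction = 0,
    double_peak_fraction = 0,
    whisking_fraction = 0.47
  )
  p <- switch(name,
    intact_pr5 = modifyList(base, list(
      n_units = 23,
      gating_factor_dist = lnorm_from_mean_sd(0.7, 0.2),
      baseline_ratio_dist = lnorm_from_mean_sd(3.8, 4.4),
      double_peak_fraction = 10 / 23,
      kernel_shape = list(latency_ms = c(2, 5), width_ms = NA,
                          late_component = TRUE),
      group = "intact", nucleus = "Pr5"
    )),
    lesioned_pr5 = modifyList(base, list(
      n_units = 53,
      gating_factor_dist = lnorm_from_mean_sd(1.1, 0.6),
      baseline_ratio_dist = lnorm_from_mean_sd(2.6, 2.0),
      kernel_shape = list(latency_ms = c(2, 3.5), width_ms = 2,
                          late_component = FALSE),
      evoked_peak_rate_dist = lnorm_from_median(300, 0.4),
      group = "lesioned", nucleus = "Pr5"
    )),
    sp5i = modifyList(base, list(
      n_units = 64,
      n_interneurons = 17,
      gating_factor_dist = lnorm_from_mean_sd(1.1, 0.5),
      baseline_ratio_dist = lnorm_from_mean_sd(1.4, 1.0),
      interneuron_baseline_ratio_dist = lnorm_from_mean_sd(1.1, 0.5),
      zero_baseline_fraction = 0.1,
      kernel_shape = list(latency_ms = c(2, 5), width_ms = 3,
                          late_component = FALSE),
      evoked_peak_rate_dist = lnorm_from_median(200, 0.4),
      group = "intact", nucleus = "Sp5i"
    )),
    sp5i_interneuron = modifyList(base, list(
      n_units = 17,
      n_interneurons = 17,
      gating_factor_dist = lnorm_from_mean_sd(1.1, 0.5),
      baseline_ratio_dist = lnorm_from_mean_sd(1.1, 0.5),
      interneuron_baseline_ratio_dist = lnorm_from_mean_sd(1.1, 0.5),
      zero_baseline_fraction = 0.1,
      kernel_shape = list(latency_ms = c(2, 5), width_ms = 3,
                          late_component = FALSE),
      evoked_peak_rate_dist = lnorm_from_median(200, 0.4),
      group = "intact", nucleus = "Sp5i"
    ))
  )
  if (!is.null(n_units)) p$n_units <- n_units
  if (!is.null(zero_baseline_fraction))
    p$zero_baseline_fraction <- zero_baseline_fraction
  class(p) <- "generator_preset"
  validate_preset(p)
  p
}

validate_preset <- function(p) {
  if (is.null(p$n_units) || length(p$n_units) != 1 || is.na(p$n_units) ||
      p$n_units < 1)
    stop("invalid preset: n_units must be a positive count")
  if (is.null(p$trial_count) || p$trial_count < 1)
    stop("invalid preset: trial_count must be a positive count")
  for (f in c("double_peak_fraction", "zero_baseline_fraction",
              "whisking_fraction")) {
    v <- p[[f]]
    if (is.null(v) || v < 0 || v > 1)
      stop("invalid preset: ", f, " must lie in [0, 1]")
  }
  invisible(TRUE)
}
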