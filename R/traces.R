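#' Whisker position trace
#'
#' A regularly sampled record of linear whisker (or object) position at a
#' fixed point along the shaft -- the reading of a laser optical sensor --
#' in metres.
#'
#' @param samples numeric vector of positions (m); must be finite.
#' @param rate sampling rate (Hz), > 0.
#' @param t0 time of the first sample (s).
#' @return An object of class `whisker_trace` with fields `samples`, `rate`,
#'   `t0`.
#' @export
whisker_trace <- function(samples, rate, t0 = 0) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("whisker trace contains non-finite samples")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         t0 = as.numeric(t0)),
    class = "whisker_trace"
  )
}

#' Sample times of a trace
#' @param trace a `whisker_trace`
#' @return numeric vector of sample times (s)
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

trace_end <- function(trace) {
  trace$t0 + (length(trace$samples) - 1) / trace$rate
}

#' Extracellular voltage trace
#'
#' @param samples voltage samples (microvolts)
#' @param rate sampling rate (Hz); native recordings are 40 kHz
#' @param band band-pass limits (Hz) the trace has been filtered to
#' @param t0 time of first sample (s)
#' @return object of class `voltage_trace`
#' @export
voltage_trace <- function(samples, rate = 40000, band = c(200, 5000), t0 = 0) {
  if (any(!is.finite(samples))) stop("voltage trace contains non-finite samples")
  if (rate <= 0) stop("rate must be positive")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 band = as.numeric(band), t0 = as.numeric(t0)),
            class = "voltage_trace")
}

#' Single- or multi-unit spike record
#'
#' @param spike_times sorted spike timestamps (s), unique at 1 ms resolution
#' @param unit_id identifier
#' @param quality `"single"` or `"multi"`
#' @param receptive_field `"SW"` (single whisker) or `"MW"` (multi whisker)
#' @param nucleus `"Pr5"` or `"Sp5i"`
#' @return object of class `unit_record`
#' @export
unit_record <- function(spike_times, unit_id,
                        quality = c("single", "multi"),
                        receptive_field = c("SW", "MW"),
                        nucleus = c("Pr5", "Sp5i")) {
  quality <- match.arg(quality)
  receptive_field <- match.arg(receptive_field)
  nucleus <- match.arg(nucleus)
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = FALSE))
    stop("spike_times must be sorted for unit ", unit_id)
  if (anyDuplicated(floor(spike_times * 1000 + 1e-9)))
    stop("spike_times must be unique at 1 ms resolution for unit ", unit_id)
  structure(list(spike_times = spike_times, unit_id = unit_id,
                 quality = quality, receptive_field = receptive_field,
                 nucleus = nucleus),
            class = "unit_record")
}

#' Recording session container
#'
#' Binds the whisker trace, the optional object trace, contact and lick event
#' series, unit spike records and (optionally) the raw voltage trace, along
#' with group/nucleus metadata.
#'
#' @param trace `whisker_trace` of whisker position
#' @param contacts data.frame with column `time` (s) and logical `reward`
#' @param licks data.frame with column `time` (s)
#' @param units list of `unit_record`
#' @param object optional `whisker_trace` of the object trajectory
#' @param voltage optional `voltage_trace`
#' @param metadata list with `group` ("intact"/"lesioned"), `nucleus`
#'   ("Pr5"/"Sp5i"), `session_id`
#' @param validate run invariant checks (event ordering, time span)
#' @return object of class `whisk_session`
#' @export
whisk_session <- function(trace, contacts, licks, units, object = NULL,
                          voltage = NULL, metadata = list(), validate = TRUE) {
  if (is.null(contacts)) contacts <- data.frame(time = numeric(), reward = logical())
  if (is.null(licks)) licks <- data.frame(time = numeric())
  if (!"reward" %in% names(contacts)) contacts$reward <- rep(TRUE, nrow(contacts))
  s <- structure(list(trace = trace, object = object, contacts = contacts,
                      licks = licks, units = units, voltage = voltage,
                      metadata = metadata),
                 class = "whisk_session")
  if (validate) validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks that event timestamps lie within the trace time span and are
#' strictly increasing, and that spike trains are sorted. Violations are
#' reported with the offending record index.
#'
#' @param session a `whisk_session`
#' @return invisibly `TRUE`; stops with a descriptive error otherwise
#' @export
validate_session <- function(session) {
  tr <- session$trace
  if (!inherits(tr, "whisker_trace")) stop("session trace missing or invalid")
  span <- c(tr$t0, trace_end(tr))
  check_events <- function(times, what) {
    if (!length(times)) return(invisible(NULL))
    d <- diff(times)
    if (any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop(sprintf("%s series not strictly increasing at index %d", what, i + 1L))
    }
    bad <- which(times < span[1] | times > span[2])
    if (length(bad))
      stop(sprintf("%s at index %d (t = %.6f s) lies outside the trace span [%.6f, %.6f]",
                   what, bad[1], times[bad[1]], span[1], span[2]))
  }
  check_events(session$contacts$time, "contact")
  check_events(session$licks$time, "lick")
  for (u in session$units) {
    if (is.unsorted(u$spike_times))
      stop("spike times unsorted for unit ", u$unit_id)
  }
  invisible(TRUE)
}

#' @export
print.whisk_session <- function(x, ...) {
  cat(sprintf("<whisk_session %s: %.1f s at %g Hz, %d contacts, %d licks, %d units%s>\n",
              x$metadata$session_id %||% "?",
              length(x$trace$samples) / x$trace$rate, x$trace$rate,
              nrow(x$contacts), nrow(x$licks), length(x$units),
              if (is.null(x$voltage)) "" else ", voltage"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
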