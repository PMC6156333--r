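# On-disk session representation: a JSON manifest plus one TSV table per
# component. Plain text keeps desk-scale sessions diffable; times are stored
# in seconds and positions in metres at 1e-9 precision, which round-trips
# losslessly for the package's purposes.

SCHEMA_VERSION <- 1L

fmt9 <- function(x) sprintf("%.9f", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a session to a directory
#'
#' Writes `manifest.json` plus `trace.tsv` (time/position), `contacts.tsv`,
#' `licks.tsv`, `spikes.tsv` (one row per spike with unit_id), optional
#' `object.tsv` and `voltage.tsv`. Round-trips losslessly at 1e-9 s / 1e-9 m.
#'
#' @param session a `whisk_session`
#' @param path directory to create/write into
#' @return the manifest (invisibly), as written
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create session directory: ", path)
  tr <- session$trace
  write_tsv(data.frame(time = fmt9(trace_times(tr)),
                       position = fmt9(tr$samples)),
            file.path(path, "trace.tsv"))
  if (!is.null(session$object))
    write_tsv(data.frame(time = fmt9(trace_times(session$object)),
                         position = fmt9(session$object$samples)),
              file.path(path, "object.tsv"))
  write_tsv(data.frame(time = fmt9(session$contacts$time),
                       reward = session$contacts$reward),
            file.path(path, "contacts.tsv"))
  write_tsv(data.frame(time = fmt9(session$licks$time)),
            file.path(path, "licks.tsv"))
  spikes <- do.call(rbind, c(lapply(session$units, function(u)
    if (length(u$spike_times))
      data.frame(unit_id = u$unit_id, time = fmt9(u$spike_times)) else NULL),
    list(data.frame(unit_id = character(), time = character()))))
  write_tsv(spikes, file.path(path, "spikes.tsv"))
  if (!is.null(session$voltage))
    write_tsv(data.frame(time = fmt9(trace_times(session$voltage)),
                         voltage = sprintf("%.4f", session$voltage$samples)),
              file.path(path, "voltage.tsv"))
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    format = "whiskgate-session",
    metadata = session$metadata,
    trace = list(file = "trace.tsv", rate = tr$rate, t0 = tr$t0,
                 n = length(tr$samples)),
    object = if (is.null(session$object)) NULL else
      list(file = "object.tsv", rate = session$object$rate,
           t0 = session$object$t0, n = length(session$object$samples)),
    voltage = if (is.null(session$voltage)) NULL else
      list(file = "voltage.tsv", rate = session$voltage$rate,
           band = session$voltage$band, t0 = session$voltage$t0,
           n = length(session$voltage$samples)),
    units = lapply(session$units, function(u)
      list(unit_id = u$unit_id, quality = u$quality,
           receptive_field = u$receptive_field, nucleus = u$nucleus,
           n_spikes = length(u$spike_times)))
  )
  manifest <- Filter(Negate(is.null), manifest)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a session from a directory
#'
#' Validates the manifest schema version and every documented invariant
#' (event ordering, time span, spike sorting); violations are reported with
#' the offending record index. A missing licks table yields an empty lick
#' series.
#'
#' @param path session directory containing `manifest.json`
#' @return a validated `whisk_session`
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (is.null(mf$schema_version) || mf$schema_version != SCHEMA_VERSION)
    stop("schema-version mismatch: file has ",
         mf$schema_version %||% "none", ", reader expects ", SCHEMA_VERSION)
  read_tsv <- function(f) utils::read.delim(file.path(path, f),
                                            stringsAsFactors = FALSE)
  trd <- read_tsv(mf$trace$file)
  trace <- whisker_trace(trd$position, mf$trace$rate, mf$trace$t0)
  object <- NULL
  if (!is.null(mf$object$file)) {
    od <- read_tsv(mf$object$file)
    object <- whisker_trace(od$position, mf$object$rate, mf$object$t0)
  }
  contacts <- read_tsv("contacts.tsv")
  licks <- if (file.exists(file.path(path, "licks.tsv")))
    read_tsv("licks.tsv") else data.frame(time = numeric())
  spikes <- read_tsv("spikes.tsv")
  units <- lapply(mf$units, function(um) {
    st <- spikes$time[spikes$unit_id == um$unit_id]
    unit_record(st, unit_id = um$unit_id, quality = um$quality,
                receptive_field = um$receptive_field, nucleus = um$nucleus)
  })
  voltage <- NULL
  if (!is.null(mf$voltage$file)) {
    vd <- read_tsv(mf$voltage$file)
    voltage <- voltage_trace(vd$voltage, rate = mf$voltage$rate,
                             band = unlist(mf$voltage$band),
                             t0 = mf$voltage$t0)
  }
  md <- lapply(mf$metadata, identity)
  whisk_session(trace, contacts, licks, units, object = object,
                voltage = voltage, metadata = md, validate = TRUE)
}
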