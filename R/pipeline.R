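# Pipeline orchestration: simulate/ingest -> classify -> gating -> effect
# profiles -> onsets -> kinematics, with reproducible on-disk outputs and
# group comparison.

#' Pipeline configuration
#'
#' All stage parameters default to the analysis constants used throughout
#' the package (the "paper" profile): peri-contact window [-20, 50) ms at
#' 1 ms; baseline [-20, -10) ms; evoked [0, 10) ms; 2 sigma + 1 mm/s RMS
#' non-whisking criteria; [5, 95] percentile deceleration matching; 500 ms
#' onset windows with 75% overlap, 95th percentile ratio and 0.1 m/s rest
#' ceiling; alpha 0.05.
#'
#' @param preset generator preset name (for simulated input)
#' @param seed generator seed
#' @param input path to a stored session directory (alternative to
#'   `preset` + `seed`)
#' @param out_dir output directory (optional; no files written when NULL)
#' @param alpha per-bin significance level
#' @param matched_only compute gating on deceleration-matched trials
#' @param run_onsets,run_kinematics stage toggles
#' @return config list
#' @export
pipeline_config <- function(preset = NULL, seed = NULL, input = NULL,
                            out_dir = NULL, alpha = 0.05,
                            matched_only = TRUE, run_onsets = TRUE,
                            run_kinematics = TRUE) {
  if (is.null(input) && (is.null(preset) || is.null(seed)))
    stop("config needs either a session `input` path or `preset` + `seed`")
  list(preset = preset, seed = seed, input = input, out_dir = out_dir,
       alpha = alpha, matched_only = matched_only, run_onsets = run_onsets,
       run_kinematics = run_kinematics)
}

#' Run the full analysis pipeline on one session
#'
#' Simulates (or reads) a session, preprocesses the whisker trace, extracts
#' and classifies contact windows, applies deceleration matching, computes
#' per-unit gating summaries and peak pairs, the population bin-wise effect
#' profile and response width, whisking-onset responses, and the kinematics
#' table. When `out_dir` is set, writes every intermediate table (TSV), a
#' JSON report and a run log; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config list from [pipeline_config()]
#' @return report list: `gating` (per-unit table), `profile`,
#'   `response_width`, `onsets` summary, `kinematics`, `classification`,
#'   `meta`; attribute `"psth"` carries per-unit PSTHs
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$input) && !dir.exists(config$input))
    stop("missing session: ", config$input)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  log_lines <- c(sprintf("whiskgate pipeline, package %s",
                         as.character(utils::packageVersion("whiskgate"))),
                 sprintf("input: %s",
                         config$input %||% sprintf("simulate %s seed %s",
                                                   config$preset, config$seed)))
  if (is.null(config$input)) {
    gen <- stage("simulate",
                 generate_session(config$preset, config$seed))
    session <- gen$session
    truth <- gen$ground_truth
  } else {
    session <- stage("ingest", read_session(config$input))
    truth <- NULL
  }
  sid <- session$metadata$session_id %||% "session"
  trace1k <- stage("preprocess", preprocess_trace(session$trace))
  windows <- stage("windows", extract_contact_windows(session, trace1k))
  cls <- stage("classify", classify_contacts(windows))
  classification <- stage("match", match_decelerations(cls$classification))
  gating <- stage("gating",
                  analyze_gating(session, classification,
                                 config$matched_only))
  psths <- attr(gating, "psth")

  inc <- gating$included %in% TRUE
  profile <- NULL; width <- NA_integer_
  if (sum(inc) >= 2) {
    rates <- t(vapply(psths[gating$unit_id[inc]],
                      function(p) p$all$rate, numeric(70)))
    basel <- vapply(psths[gating$unit_id[inc]], function(p)
      mean(p$all$rate[psth_bins_in(p$all, BASE_MS)]), 0)
    profile <- stage("profile",
                     binwise_profile(rates, basel, alpha = config$alpha))
    width <- response_width(profile)
  }

  onset_tab <- NULL; onset_summary <- NULL
  if (isTRUE(config$run_onsets)) {
    onsets <- stage("onsets",
                    detect_whisking_onsets(trace1k, session$contacts,
                                           session$licks))
    onset_tab <- analyze_onsets(session, onsets)
    onset_summary <- list(
      session_valid = onsets$session_valid,
      n_windows = length(onsets$onset_times),
      n_eligible_units = nrow(onset_tab),
      median_increment = if (nrow(onset_tab))
        stats::median(onset_tab$increment) else NA_real_,
      median_effect_size = if (nrow(onset_tab))
        stats::median(onset_tab$effect_size) else NA_real_)
  }

  kin <- NULL
  if (isTRUE(config$run_kinematics))
    kin <- stage("kinematics",
                 kinematics_analysis(session$units, classification))

  report <- list(
    meta = list(session_id = sid, group = session$metadata$group,
                nucleus = session$metadata$nucleus,
                preset = if (is.character(config$preset)) config$preset
                         else config$preset$name,
                seed = config$seed,
                alpha = config$alpha,
                n_contacts = nrow(session$contacts),
                n_matched_whisking =
                  sum(classification$matched & classification$label == "whisking"),
                n_matched_non_whisking =
                  sum(classification$matched &
                        classification$label == "non_whisking")),
    gating = gating,
    profile = profile,
    response_width = width,
    onsets = onset_tab,
    onset_summary = onset_summary,
    classification = classification,
    ground_truth = truth
  )
  attr(report, "psth") <- psths
  report$kinematics <- kin

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(config$out_dir, f)
    write_tsv(classification, op("classification.tsv"))
    write_tsv(gating, op("gating.tsv"))
    if (!is.null(profile)) write_tsv(profile, op("profile.tsv"))
    if (!is.null(onset_tab)) write_tsv(onset_tab, op("onsets.tsv"))
    if (!is.null(kin$unit_correlations))
      write_tsv(kin$unit_correlations, op("kinematics.tsv"))
    jsonlite::write_json(
      list(meta = report$meta, response_width = width,
           onset_summary = onset_summary,
           gating_means = list(
             evoked_ratio = mean(gating$evoked_ratio[inc], na.rm = TRUE),
             baseline_ratio = mean(
               gating$baseline_ratio[inc & is.finite(gating$baseline_ratio)],
               na.rm = TRUE))),
      op("report.json"), auto_unbox = TRUE, pretty = TRUE, digits = 10)
    writeLines(c(log_lines,
                 sprintf("units: %d, contacts: %d", length(session$units),
                         nrow(session$contacts)),
                 sprintf("alpha: %g, matched_only: %s", config$alpha,
                         config$matched_only)),
               op("run.log"))
  }
  report
}

#' Compare two group reports
#'
#' Rank-sum tests and AUC effect sizes between the groups' evoked-ratio and
#' baseline-ratio distributions (infinite baseline ratios excluded), plus a
#' bin-wise group effect profile on the pooled all-trial PSTHs restricted to
#' units with non-zero baselines in both states.
#'
#' @param report_a,report_b reports from [run_pipeline()] (e.g. intact and
#'   lesioned)
#' @param alpha per-bin significance level
#' @return list with `evoked`, `baseline` (TestResults), `profile`
#'   (group-mode EffectProfile) and per-group `response_width`
#' @export
compare_groups <- function(report_a, report_b, alpha = 0.05) {
  ga <- report_a$gating; gb <- report_b$gating
  if (is.null(ga) || !nrow(ga) || is.null(gb) || !nrow(gb))
    stop("empty gating table")
  inc_a <- ga$included %in% TRUE; inc_b <- gb$included %in% TRUE
  ev <- rank_sum_test(ga$evoked_ratio[inc_a], gb$evoked_ratio[inc_b])
  ba <- rank_sum_test(ga$baseline_ratio[inc_a & is.finite(ga$baseline_ratio)],
                      gb$baseline_ratio[inc_b & is.finite(gb$baseline_ratio)])
  profile <- NULL
  pa <- attr(report_a, "psth"); pb <- attr(report_b, "psth")
  nz <- function(g) g$included %in% TRUE & g$mean_baseline_W > 0 &
    g$mean_baseline_NW > 0
  ia <- ga$unit_id[nz(ga)]; ib <- gb$unit_id[nz(gb)]
  ia <- intersect(ia, names(pa)); ib <- intersect(ib, names(pb))
  if (length(ia) >= 2 && length(ib) >= 2) {
    ra <- t(vapply(pa[ia], function(p) p$all$rate, numeric(70)))
    rb <- t(vapply(pb[ib], function(p) p$all$rate, numeric(70)))
    profile <- binwise_profile(ra, rb, mode = "groups", alpha = alpha)
  }
  list(evoked = ev, baseline = ba, profile = profile,
       response_width = c(a = report_a$response_width,
                          b = report_b$response_width))
}
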