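# Spike sorting: threshold trough detection, snippet extraction with
# deduplication and artifact rejection, PCA + k-means clustering, and
# single/multi unit grading.

SNIP_PRE <- 12L    # samples before trough (0.3 ms at 40 kHz)
SNIP_POST <- 32L   # samples after trough (0.8 ms at 40 kHz)

#' Detect and extract spike snippets
#'
#' Finds local minima (troughs) below a negative amplitude threshold, keeps
#' only the more negative of any two troughs within 1 ms of each other,
#' extracts 45-sample snippets (0.3 ms before the trough, 0.8 ms after, at
#' 40 kHz), and removes snippets with any sample exceeding 10 trace SDs as
#' artifacts.
#'
#' @param voltage a `voltage_trace`
#' @param threshold negative threshold in microvolts, or if `threshold_sd`
#'   is given, computed as `-threshold_sd` trace SDs
#' @param threshold_sd optional threshold as a (positive) multiple of the
#'   trace SD; default 5 when `threshold` is missing
#' @param artifact_sd artifact rejection limit in trace SDs
#' @return list (snippets): `waveforms` (n x 45 matrix, trough at column
#'   13), `trough_times` (s), `amplitudes` (trough voltage, uV), `rate`
#' @export
detect_snippets <- function(voltage, threshold = NULL, threshold_sd = NULL,
                            artifact_sd = 10) {
  v <- voltage$samples
  sdv <- stats::sd(v)
  if (is.null(threshold)) {
    if (is.null(threshold_sd)) threshold_sd <- 5
    threshold <- -abs(threshold_sd) * sdv
  }
  if (threshold >= 0) stop("threshold must be negative (trough detection)")
  nlen <- SNIP_PRE + SNIP_POST + 1L
  empty <- list(waveforms = matrix(numeric(), 0, nlen),
                trough_times = numeric(), amplitudes = numeric(),
                rate = voltage$rate)
  if (length(v) < nlen) return(empty)
  n <- length(v)
  i <- 2:(n - 1)
  tr <- i[v[i] < threshold & v[i] <= v[i - 1] & v[i] < v[i + 1]]
  # deduplicate troughs within 1 ms: keep the more negative
  min_gap <- round(0.001 * voltage$rate)
  while (length(tr) > 1) {
    d <- diff(tr)
    close <- which(d < min_gap)
    if (!length(close)) break
    k <- close[1]
    drop <- if (v[tr[k]] <= v[tr[k + 1]]) k + 1L else k
    tr <- tr[-drop]
  }
  tr <- tr[tr > SNIP_PRE & tr <= n - SNIP_POST]
  if (!length(tr)) return(empty)
  wf <- t(vapply(tr, function(j) v[(j - SNIP_PRE):(j + SNIP_POST)],
                 numeric(nlen)))
  keep <- apply(abs(wf), 1, max) <= artifact_sd * sdv
  list(waveforms = wf[keep, , drop = FALSE],
       trough_times = voltage$t0 + (tr[keep] - 1) / voltage$rate,
       amplitudes = v[tr[keep]],
       rate = voltage$rate)
}

#' PCA embedding and k-means clustering of snippets
#'
#' Principal components are computed on the mean-centred waveforms; k-means
#' (10 restarts) is run on the first three component scores under a fixed
#' seed, so results are deterministic given `(snippets, k, seed)`.
#'
#' @param snippets output of [detect_snippets()]
#' @param k number of clusters (user-supplied per recording)
#' @param seed RNG seed for the k-means restarts
#' @param nstart k-means restarts
#' @return list (ClusterModel): `features` (n x 3 PC scores), `assignments`,
#'   `centroids`, `k`
#' @export
embed_and_cluster <- function(snippets, k, seed = 1, nstart = 10) {
  n <- nrow(snippets$waveforms)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of snippets (", n, ")")
  pc <- stats::prcomp(snippets$waveforms, center = TRUE, scale. = FALSE)
  nc <- min(3L, ncol(pc$x))
  feat <- pc$x[, seq_len(nc), drop = FALSE]
  if (nc < 3) feat <- cbind(feat, matrix(0, n, 3 - nc))
  colnames(feat) <- paste0("PC", 1:3)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(feat, centers = k, nstart = nstart,
                                       iter.max = 100))
  list(features = feat, assignments = km$cluster, centroids = km$centers,
       k = k)
}

#' Grade clusters as single or multi units
#'
#' A cluster is graded `single` iff its fraction of sub-millisecond
#' inter-spike intervals is below 1% and its nearest-centroid separation is
#' at least 3 times the mean within-cluster feature SD; otherwise `multi`.
#' These operationalize the conservative single-unit criteria as testable
#' proxies.
#'
#' @param model ClusterModel from [embed_and_cluster()]
#' @param snippets the snippets that were clustered
#' @param isi_limit ISI-violation fraction allowed for single units
#' @param sep_limit required separation (multiples of within-cluster SD)
#' @return data.frame (UnitQuality): `unit_id`, `grade`,
#'   `isi_violation_fraction`, `separation_score`, `n_snippets`
#' @export
grade_units <- function(model, snippets, isi_limit = 0.01, sep_limit = 3) {
  ids <- sort(unique(model$assignments))
  wsd <- vapply(ids, function(c) {
    f <- model$features[model$assignments == c, , drop = FALSE]
    if (nrow(f) < 2) return(0)
    sqrt(mean(apply(f, 2, stats::var)))
  }, 0)
  mean_wsd <- mean(wsd[wsd > 0])
  if (!is.finite(mean_wsd) || mean_wsd == 0) mean_wsd <- NA_real_
  rows <- lapply(seq_along(ids), function(ci) {
    c <- ids[ci]
    tt <- sort(snippets$trough_times[model$assignments == c])
    if (!length(tt)) {
      warning("empty cluster ", c, " excluded from grading")
      return(NULL)
    }
    isi <- if (length(tt) > 1) mean(diff(tt) < 0.001 - 1e-9) else 0
    sep <- if (model$k == 1 || is.na(mean_wsd)) Inf else {
      d <- sqrt(colSums((t(model$centroids[-ci, , drop = FALSE]) -
                           model$centroids[ci, ])^2))
      min(d) / mean_wsd
    }
    data.frame(unit_id = c,
               grade = if (isi < isi_limit && sep >= sep_limit)
                 "single" else "multi",
               isi_violation_fraction = isi,
               separation_score = sep,
               n_snippets = length(tt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sort a voltage trace into unit records
#'
#' Convenience wrapper: [detect_snippets()], [embed_and_cluster()],
#' [grade_units()], returning `unit_record`s compatible with the session
#' container.
#'
#' @param voltage a `voltage_trace`
#' @param k number of clusters
#' @param threshold_sd detection threshold (trace SDs)
#' @param seed RNG seed
#' @param nucleus nucleus label for the resulting units
#' @return list with `units` (list of `unit_record`), `snippets`, `model`,
#'   `quality`
#' @export
sort_voltage <- function(voltage, k, threshold_sd = 5, seed = 1,
                         nucleus = "Pr5") {
  sn <- detect_snippets(voltage, threshold_sd = threshold_sd)
  model <- embed_and_cluster(sn, k, seed = seed)
  q <- grade_units(model, sn)
  units <- lapply(seq_len(nrow(q)), function(i) {
    tt <- sort(sn$trough_times[model$assignments == q$unit_id[i]])
    tt <- tt[!duplicated(floor(tt * 1000 + 1e-9))]
    unit_record(tt, unit_id = sprintf("sorted%02d", q$unit_id[i]),
                quality = q$grade[i], receptive_field = "SW",
                nucleus = nucleus)
  })
  list(units = units, snippets = sn, model = model, quality = q)
}
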