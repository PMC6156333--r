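# Nonparametric effect sizes (ROC AUC) and Wilcoxon tests; bin-wise effect
# profiles and response widths.

#' AUC effect size
#'
#' Probability that a random draw from `a` exceeds a random draw from `b`,
#' with ties receiving half credit:
#' AUC = (#\{a > b\} + 0.5 #\{a = b\}) / (|a| |b|).
#' Equals the area under the ROC curve of the two-sample classifier; 0.5
#' means no effect. Computed via midranks, so it equals the Mann-Whitney
#' U statistic divided by |a||b|.
#'
#' @param a,b numeric samples (non-empty)
#' @return AUC in [0, 1]
#' @export
auc_effect_size <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample: AUC undefined")
  r <- rank(c(a, b))
  na <- length(a)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * length(b))
}

# one-sample AUC of x against a constant reference
auc_vs_constant <- function(x, ref = 1) {
  (sum(x > ref) + 0.5 * sum(x == ref)) / length(x)
}

#' Wilcoxon signed-rank test (paired / one-sample)
#'
#' Two-sided test of symmetry of `x - mu` about zero. The exact null
#' distribution is used for n <= 25 when there are no ties or zeros;
#' otherwise the normal approximation with continuity and tie correction.
#' The reported effect size is the one-sample AUC of `x` against `mu`.
#'
#' @param x paired differences or ratios
#' @param mu null location (1 for ratio data, 0 for differences)
#' @return list (TestResult): `statistic`, `p_value`, `n`, `test`,
#'   `effect_size`
#' @export
signed_rank_test <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1) stop("empty sample")
  d <- x - mu
  if (all(d == 0)) {
    warning("all differences zero; p = 1")
    return(list(statistic = NA_real_, p_value = 1, n = n,
                test = "signed_rank", effect_size = 0.5))
  }
  exact <- n <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n,
       test = "signed_rank", effect_size = auc_vs_constant(x, mu))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample test. Exact null distribution when n1 + n2 <= 20 and
#' there are no ties; normal approximation with continuity and tie
#' correction otherwise. Effect size is [auc_effect_size()] of `a` vs `b`.
#'
#' @param a,b numeric samples
#' @return list (TestResult): `statistic` (U), `p_value`, `n1`, `n2`, `test`,
#'   `effect_size`
#' @export
rank_sum_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("empty sample")
  exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n1 = length(a), n2 = length(b), test = "rank_sum",
       effect_size = auc_effect_size(a, b))
}

#' Bin-wise effect profile
#'
#' In `"baseline"` mode, compares the units' firing rates in each PSTH bin
#' against the units' mean baseline rates (rank-sum + AUC per bin). In
#' `"groups"` mode, compares the two groups' rates bin by bin at
#' corresponding times. Raw per-bin p-values are marked significant at
#' `alpha` (no correction across bins, matching the per-bin significance
#' dots of the source analyses); set `fdr = TRUE` for an optional
#' Benjamini-Hochberg flag instead.
#'
#' @param rates units x bins rate matrix (Hz)
#' @param reference numeric vector of per-unit mean baseline rates
#'   (`"baseline"` mode) or a second units x bins matrix (`"groups"` mode)
#' @param bin_left left bin edges (ms); defaults to the standard
#'   [-20, 50) ms grid
#' @param mode `"baseline"` or `"groups"`
#' @param alpha significance level
#' @param fdr apply Benjamini-Hochberg correction across bins
#' @return data.frame (EffectProfile): `bin_left`, `auc`, `p`, `significant`
#' @export
binwise_profile <- function(rates, reference,
                            bin_left = seq(-20, 49),
                            mode = c("baseline", "groups"),
                            alpha = 0.05, fdr = FALSE) {
  mode <- match.arg(mode)
  if (ncol(rates) != length(bin_left))
    stop("rate matrix and bin grid have mismatched lengths")
  if (nrow(rates) < 2) stop("need at least 2 units per side")
  if (mode == "groups") {
    if (!is.matrix(reference) || ncol(reference) != ncol(rates))
      stop("mismatched bin grids between groups")
    if (nrow(reference) < 2) stop("need at least 2 units per side")
  } else {
    if (length(reference) != nrow(rates))
      stop("baseline reference must have one value per unit")
  }
  res <- lapply(seq_along(bin_left), function(j) {
    ref <- if (mode == "baseline") reference else reference[, j]
    t <- rank_sum_test(rates[, j], ref)
    c(auc = t$effect_size, p = t$p_value)
  })
  auc <- vapply(res, `[[`, 0, "auc")
  p <- vapply(res, `[[`, 0, "p")
  padj <- if (fdr) stats::p.adjust(p, "BH") else p
  data.frame(bin_left = bin_left, auc = auc, p = p,
             significant = padj < alpha)
}

#' Response width
#'
#' Number of post-contact bins whose rate is significantly above baseline
#' (significant flag set and AUC > 0.5) in a baseline-mode effect profile.
#'
#' @param profile data.frame from [binwise_profile()]
#' @return integer bin count
#' @export
response_width <- function(profile) {
  sum(profile$significant & profile$auc > 0.5 & profile$bin_left >= 0)
}
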