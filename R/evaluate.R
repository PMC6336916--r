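## Patient-level evaluation statistics: confusion metrics, Cohen's kappa
## with qualitative bands, Pearson chi-square, Fisher's exact test,
## Mann-Whitney U, and cluster-vs-resection concordance.

#' Patient-level confusion counts
#'
#' TP/FN count patients (lesion cluster concordant with the resection or
#' not); FP/TN count controls (any false cluster or none).
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class `fcd_confusion`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = unname(tp), fn = unname(fn), fp = unname(fp), tn = unname(tn))
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "fcd_confusion")
}

#' Sensitivity, specificity and accuracy
#'
#' `sensitivity = TP/(TP + FN)`, `specificity = TN/(TN + FP)`,
#' `accuracy = (TP + TN)/(TP + FP + FN + TN)`. A zero denominator yields
#' `NA` for that metric.
#'
#' @param counts an `fcd_confusion` object (or anything with fields
#'   `tp`, `fn`, `fp`, `tn`).
#' @return named numeric vector with the three metrics in `[0, 1]`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    accuracy = div(tp + tn, tp + fn + fp + tn))
}

#' Cohen's kappa with qualitative band
#'
#' Chance-corrected agreement `kappa = (Po - Pe)/(1 - Pe)` on a 2x2
#' agreement table, with the conventional qualitative bands: slight
#' (0.00-0.20), fair (0.21-0.40), moderate (0.41-0.60), substantial
#' (0.61-0.80) and almost perfect (0.81-1.00). Boundary values belong to
#' the lower band (0.40 is "fair"); negative kappa is reported as "poor".
#'
#' @param table 2x2 numeric matrix of agreement counts.
#' @return list with `kappa` and `band`; `kappa` is `NA` when the expected
#'   agreement is degenerate (Pe = 1).
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  n <- sum(table)
  if (n <= 0) stop("agreement table must have a positive total")
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < 1e-12)
    return(list(kappa = NA_real_, band = "undefined (degenerate marginals)"))
  k <- (po - pe) / (1 - pe)
  band <- if (k < 0) "poor" else
    c("slight", "fair", "moderate", "substantial", "almost perfect")[
      findInterval(k, c(0, 0.20, 0.40, 0.60, 0.80), left.open = TRUE) + (k == 0)]
  list(kappa = k, band = band)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The uncorrected statistic `sum((O - E)^2 / E)` with 1 degree of freedom
#' (no Yates continuity correction). A warning recommending Fisher's exact
#' test is emitted when any expected count falls below 5.
#'
#' @param table 2x2 contingency table of non-negative counts.
#' @return list with `statistic`, `df` and `p`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0), sum(table) > 0)
  e <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(e <= 0)) stop("all expected counts must be positive")
  if (any(e < 5))
    warning("expected count below 5; consider fisher_exact()")
  stat <- sum((table - e)^2 / e)
  list(statistic = stat, df = 1L, p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' @param table 2x2 contingency table.
#' @return two-sided hypergeometric exact p-value.
#' @export
fisher_exact <- function(table) {
  stats::fisher.test(as.matrix(table))$p.value
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test using the normal approximation with tie
#' correction. `U` is the number of (x, y) pairs with x ranked above y, so
#' fully separated samples with every x below every y give U = 0.
#'
#' @param x,y numeric samples.
#' @return list with `U` and the two-sided `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Cluster-resection concordance
#'
#' A detection is concordant when the major cluster - the cluster with the
#' highest peak probability - shares at least one vertex with the resection
#' label. Lower-ranked clusters do not count. The Dice coefficient of the
#' major cluster against the resection is returned as an auxiliary measure.
#'
#' @param clusters list of `fcd_cluster`, sorted by peak probability as
#'   returned by [threshold_and_cluster()].
#' @param resection an `fcd_label` of the resected vertices (non-empty).
#' @return list with `concordant` (logical) and `dice`.
#' @export
concordance <- function(clusters, resection) {
  stopifnot(inherits(resection, "fcd_label"))
  if (length(resection$vertices) == 0L) stop("resection label is empty")
  if (length(clusters) == 0L)
    return(list(concordant = FALSE, dice = 0))
  top <- clusters[[1L]]
  ov <- length(intersect(top$vertices, resection$vertices))
  list(concordant = ov >= 1L,
       dice = 2 * ov / (length(top$vertices) + length(resection$vertices)))
}
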