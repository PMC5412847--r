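#' Donor-equally-weighted Pearson correlation
#'
#' Multiple osteochondral samples per donor are pseudoreplicates; to remove
#' their influence each sample is weighted by `1 / (number of samples from its
#' donor)`, so every donor contributes equal total weight, and the weighted
#' Pearson correlation between a metric and the severity grade is computed.
#' The two-sided p-value uses a t statistic with `n_donors - 2` degrees of
#' freedom, matching the effective (donor-level) sample size. A `donor_mean`
#' variant first averages metric and grade within each donor; the default
#' weighted form preserves within-donor spread.
#'
#' @param table Data frame with columns `donor_id`, a grade column, and the
#'   metric column.
#' @param metric Name of the metric column.
#' @param grade_col Name of the severity-grade column (default `"grade"`).
#' @param donor_col Name of the donor column (default `"donor_id"`).
#' @param method `"weighted"` (default) or `"donor_mean"`.
#' @return List with `r`, `p`, `n_donors`, `n_samples`.
#' @export
donor_weighted_pearson <- function(table, metric, grade_col = "grade",
                                   donor_col = "donor_id",
                                   method = c("weighted", "donor_mean")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table),
            all(c(metric, grade_col, donor_col) %in% names(table)))
  x <- table[[metric]]
  g <- table[[grade_col]]
  donor <- as.character(table[[donor_col]])
  keep <- !is.na(x) & !is.na(g) & !is.na(donor) & nzchar(donor)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " sample(s) dropped for missing metric/grade/donor")
  x <- x[keep]; g <- g[keep]; donor <- donor[keep]
  nd <- length(unique(donor))
  if (nd < 3) stop("need at least 3 donors with nonmissing metric and grade")
  if (method == "donor_mean") {
    x <- tapply(x, donor, mean)
    g <- tapply(g, donor, mean)
    w <- rep(1, nd)
  } else {
    w <- 1 / table(donor)[donor]
    w <- as.numeric(w)
  }
  if (sd(x) == 0 || sd(g) == 0)
    stop("zero variance in metric or grade; correlation undefined")
  cw <- cov.wt(cbind(x = x, g = g), wt = w / sum(w), cor = TRUE)
  r <- max(-1, min(1, cw$cor["x", "g"]))
  tt <- if (abs(r) == 1) sign(r) * Inf else r * sqrt((nd - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = nd - 2)
  list(r = unname(r), p = unname(min(1, p)), n_donors = nd,
       n_samples = length(x))
}

#' Coefficient of variation (CV%)
#'
#' Precision of repeated measurements: `100 * sd / mean` over the repeats.
#'
#' @param repeats Numeric vector of at least 2 repeated measurements.
#' @return CV in percent.
#' @export
cv_percent <- function(repeats) {
  repeats <- repeats[!is.na(repeats)]
  if (length(repeats) < 2) stop("need at least 2 repeated values")
  m <- mean(repeats)
  if (m == 0) stop("mean of repeats is zero; CV% undefined")
  100 * sd(repeats) / m
}

#' Correlate every metric column against the grade
#'
#' @inheritParams donor_weighted_pearson
#' @param metrics Character vector of metric columns (default: all numeric
#'   columns other than the grade).
#' @return Data frame with columns `metric`, `r`, `p`, `n_donors`.
#' @export
correlate_metrics <- function(table, metrics = NULL, grade_col = "grade",
                              donor_col = "donor_id",
                              method = c("weighted", "donor_mean")) {
  method <- match.arg(method)
  if (is.null(metrics)) {
    num <- vapply(table, is.numeric, logical(1))
    metrics <- setdiff(names(table)[num], c(grade_col, donor_col))
  }
  rows <- lapply(metrics, function(mc) {
    res <- donor_weighted_pearson(table, mc, grade_col, donor_col, method)
    data.frame(metric = mc, r = res$r, p = res$p, n_donors = res$n_donors)
  })
  do.call(rbind, rows)
}
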