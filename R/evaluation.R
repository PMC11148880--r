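# Plan-comparison statistics: paired one-sided non-inferiority testing and
# per-metric comparison reports.

#' Paired non-inferiority test of plan scores
#'
#' One-sided paired t-test of the null hypothesis that the candidate
#' (arm A) is inferior to the reference (arm B) by more than the margin:
#' `H0: mean(A - B) <= -margin` against `H1: mean(A - B) > -margin`.
#' Non-inferiority is concluded when `p < alpha`. With margin 0 this
#' degenerates to a one-sided superiority test. The degenerate
#' zero-variance case is resolved by certainty: p = 0 when the shifted mean
#' difference is positive, 1 otherwise.
#'
#' @param scoreA numeric scores of the candidate arm.
#' @param scoreB numeric scores of the paired reference arm (same length).
#' @param margin non-inferiority margin (>= 0).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return List with `pValue`, `tStat`, `df`, `meanDiff`, `margin`,
#'   `alpha`, `nonInferior` (logical conclusion) and `n`.
#' @export
nonInferiorityTest <- function(scoreA, scoreB, margin = 0, alpha = 0.05) {
  if (length(scoreA) != length(scoreB))
    stop("nonInferiorityTest: paired arms must have equal length")
  n <- length(scoreA)
  if (n < 2) stop("nonInferiorityTest: need at least 2 pairs")
  stopifnot(margin >= 0, alpha > 0, alpha < 1,
            all(is.finite(scoreA)), all(is.finite(scoreB)))
  diff <- scoreA - scoreB
  shifted <- mean(diff) + margin
  if (stats::sd(diff) == 0) {
    p <- if (shifted > 0) 0 else 1
    t <- if (shifted > 0) Inf else -Inf
  } else {
    ht <- stats::t.test(diff, mu = -margin, alternative = "greater")
    p <- unname(ht$p.value)
    t <- unname(ht$statistic)
  }
  list(pValue = p, tStat = t, df = n - 1L, meanDiff = mean(diff),
       margin = margin, alpha = alpha, nonInferior = p < alpha, n = n)
}

#' Per-metric plan comparison report
#'
#' Summarizes paired per-metric scores of two arms (mean and sd per arm,
#' mean difference, one-sided non-inferiority p-value per metric) plus a
#' total-score row, and optionally writes the report as CSV and JSON.
#' No multiple-testing correction is applied across metrics; p-values are
#' reported per metric.
#'
#' @param caseIds case identifiers (length n).
#' @param metricsA,metricsB numeric matrices (cases x metrics) of
#'   per-metric scores for the two arms, with identical column names.
#' @param margin,alpha passed to [nonInferiorityTest()].
#' @param file optional path prefix; writes `<file>.csv` and `<file>.json`.
#' @return data.frame with one row per metric plus a `TOTAL` row.
#' @export
comparisonReport <- function(caseIds, metricsA, metricsB, margin = 0,
                             alpha = 0.05, file = NULL) {
  metricsA <- as.matrix(metricsA); metricsB <- as.matrix(metricsB)
  if (!identical(dim(metricsA), dim(metricsB)) ||
      !identical(colnames(metricsA), colnames(metricsB)))
    stop("comparisonReport: arms must share cases and metric columns")
  if (length(caseIds) != nrow(metricsA))
    stop("comparisonReport: caseIds do not match the score matrices")
  one <- function(a, b, name) {
    ht <- nonInferiorityTest(a, b, margin = margin, alpha = alpha)
    data.frame(metric = name, meanA = mean(a), sdA = stats::sd(a),
               meanB = mean(b), sdB = stats::sd(b),
               meanDiff = ht$meanDiff, pValue = ht$pValue,
               nonInferior = ht$nonInferior)
  }
  rows <- lapply(colnames(metricsA), function(m)
    one(metricsA[, m], metricsB[, m], m))
  rows[[length(rows) + 1L]] <-
    one(rowSums(metricsA), rowSums(metricsB), "TOTAL")
  rep <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(rep, paste0(file, ".csv"), row.names = FALSE)
    jsonlite::write_json(rep, paste0(file, ".json"), dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
  }
  rep
}
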