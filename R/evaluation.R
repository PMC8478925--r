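# Agreement between the pipeline's dTSR classes/scores and the
# pathologists' visual vTSR labels: 2x2 contingency, Cohen's kappa,
# rank-sum ROC/AUC, and a composition report.

normalizeTSRLabel <- function(x, what) {
  x <- tolower(as.character(x))
  x <- sub("^[dv]tsr-", "", x)
  if (!all(x %in% c("low", "high")))
    stop(what, " labels must be low/high", call. = FALSE)
  factor(x, levels = c("low", "high"))
}

#' Cross-tabulate vTSR against dTSR labels
#'
#' Rows are the visual classes (vTSR-low, vTSR-high), columns the
#' pipeline classes (dTSR-low, dTSR-high). Labels may be given as
#' `"low"`/`"high"` or with a `vTSR-`/`dTSR-` prefix.
#'
#' @param vtsrLabels,dtsrLabels equal-length label vectors.
#' @return a [ContingencyTable2x2-class].
#' @export
buildContingency <- function(vtsrLabels, dtsrLabels) {
  if (length(vtsrLabels) != length(dtsrLabels))
    stop("label vectors must have equal length", call. = FALSE)
  v <- normalizeTSRLabel(vtsrLabels, "vTSR")
  d <- normalizeTSRLabel(dtsrLabels, "dTSR")
  m <- matrix(as.integer(table(v, d)), 2L, 2L)
  dimnames(m) <- list(vTSR = c("vTSR-low", "vTSR-high"),
                      dTSR = c("dTSR-low", "dTSR-high"))
  new("ContingencyTable2x2", counts = m)
}

#' Cohen's kappa of a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = (a + d)/n` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. When `p_e = 1` (all
#' observations in one cell) kappa is undefined and `NA` is returned
#' with a warning.
#'
#' @param table a [ContingencyTable2x2-class] or plain 2x2 count matrix.
#' @return kappa in `[-1, 1]`, or `NA` if undefined.
#' @export
cohenKappa <- function(table) {
  m <- if (is(table, "ContingencyTable2x2")) tableCounts(table)
       else as.matrix(table)
  stopifnot(identical(dim(m), c(2L, 2L)), sum(m) >= 1)
  n <- sum(m)
  po <- (m[1, 1] + m[2, 2]) / n
  pe <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("kappa undefined: chance agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve and AUC of continuous dTSR scores against binary vTSR truth
#'
#' The positive class is vTSR-high (label 1). The AUC is the normalized
#' rank sum (Mann-Whitney statistic) with half credit for ties, which
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric dTSR percentages.
#' @param truth binary truth: 0/1, logical, or `"low"`/`"high"` labels.
#' @return list of class `ROCCurve`: `auc`, and a data.frame `curve`
#'   with columns `threshold`, `sensitivity`, `fpr`.
#' @export
rocAuc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth))
    truth <- as.integer(normalizeTSRLabel(truth, "truth")) - 1L
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length", call. = FALSE)
  if (!all(truth %in% c(0L, 1L)))
    stop("truth must be binary", call. = FALSE)
  nPos <- sum(truth == 1L); nNeg <- sum(truth == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[truth == 1L] >= t),
                         numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[truth == 0L] >= t),
                 numeric(1)))
  structure(list(auc = auc, curve = curve), class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROCCurve: AUC = %.4f over %d threshold(s)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' Composition and agreement report of a vTSR/dTSR table
#'
#' Emits the dTSR marginal percentages, the column-conditional
#' percentages (share of each vTSR label within each dTSR class), the
#' observed agreement and Cohen's kappa. Percentages are rounded half-up
#' to 2 decimals, the convention of published cross-tables.
#'
#' @param table a [ContingencyTable2x2-class].
#' @return named list: `n`, `counts`, `dtsr_marginal_pct`,
#'   `vtsr_marginal_pct`, `within_dtsr_pct` (2x2), `p_o`, `kappa`.
#' @export
agreementReport <- function(table) {
  stopifnot(is(table, "ContingencyTable2x2"))
  m <- tableCounts(table)
  n <- sum(m)
  colTot <- colSums(m)
  within <- m
  for (j in 1:2)
    within[, j] <- if (colTot[j] > 0) roundHalfUp(100 * m[, j] / colTot[j])
                   else c(0, 0)
  list(n = n,
       counts = m,
       dtsr_marginal_pct = setNames(roundHalfUp(100 * colTot / n),
                                    colnames(m)),
       vtsr_marginal_pct = setNames(roundHalfUp(100 * rowSums(m) / n),
                                    rownames(m)),
       within_dtsr_pct = within,
       p_o = (m[1, 1] + m[2, 2]) / n,
       kappa = cohenKappa(table))
}
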