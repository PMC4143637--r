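#' Confusion rates of gene-level calls against the truth set
#'
#' Scores the calls of one (trait, group) slice of a scan against the
#' designated functional genes: positives are genes with adjusted p value
#' strictly below the FDR level (default 0.05), negatives all others.
#' FPR = FP / (FP + TN) and FNR = FN / (FN + TP), reported in percent.
#' Functional genes that were never tested (e.g. monomorphic in the analyzed
#' individuals) are excluded from the denominators — they cannot be detected
#' in these data, and counting them as misses would bias the false-negative
#' rate.
#'
#' @param scan A `"gene_scan"` data frame.
#' @param truth_genes Character vector of functional gene ids (or a
#'   `"truth_set"`).
#' @param fdr FDR level for calling (default 0.05).
#' @param trait,group Which slice of the scan to score (defaults `"T1"`,
#'   `"rare"`).
#' @param adjusted Call on BH-adjusted p values (default `TRUE`); set
#'   `FALSE` to score calls at unadjusted p below `fdr`.
#' @return A one-row data frame with `trait`, `group`, `TP`, `FP`, `TN`,
#'   `FN`, `FPR`, `FNR` (rates in percent; a rate with an empty denominator
#'   is `NA`).
#' @examples
#' # 10 genes, 3 functional; calls = 2 functional + 1 not:
#' # FPR = 1/7, FNR = 1/3
#' @export
confusion_rates <- function(scan, truth_genes, fdr = 0.05,
                            trait = "T1", group = "rare", adjusted = TRUE) {
  if (inherits(truth_genes, "truth_set")) truth_genes <- truth_genes$functional_genes
  stopifnot(fdr > 0, fdr < 1)
  sub <- scan[scan$trait == trait & scan$group == group, ]
  if (nrow(sub) == 0L) stop("scan has no rows for trait ", trait, ", group ", group)
  pv <- if (adjusted) sub$p_adj else sub$p
  called <- !is.na(pv) & pv < fdr
  istruth <- sub$gene_id %in% truth_genes
  TP <- sum(called & istruth); FP <- sum(called & !istruth)
  FN <- sum(!called & istruth); TN <- sum(!called & !istruth)
  data.frame(trait = trait, group = group, TP = TP, FP = FP, TN = TN, FN = FN,
             FPR = if (FP + TN > 0) 100 * FP / (FP + TN) else NA_real_,
             FNR = if (FN + TP > 0) 100 * FN / (FN + TP) else NA_real_,
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC for gene prioritization
#'
#' Ranks genes by ascending unadjusted p value (BH adjustment is monotone,
#' so the AUC is identical either way) and sweeps the threshold over the
#' observed p values to produce (FPR, TPR) points; the AUC is the trapezoid
#' area, whose tie handling equals the Mann-Whitney pairwise-comparison
#' probability with half-credit for ties.
#'
#' @param scan A `"gene_scan"` data frame (or any data frame with `gene_id`
#'   and `p` columns for the chosen slice).
#' @param truth_genes Character vector of functional gene ids (or a
#'   `"truth_set"`).
#' @param trait,group Which slice of the scan to score.
#' @return A list of class `"roc_summary"`: `points` (data frame with
#'   `threshold`, `FPR`, `TPR`) and `auc`.
#' @export
roc_auc <- function(scan, truth_genes, trait = "T1", group = "rare") {
  if (inherits(truth_genes, "truth_set")) truth_genes <- truth_genes$functional_genes
  sub <- scan[scan$trait == trait & scan$group == group & !is.na(scan$p), ]
  istruth <- sub$gene_id %in% truth_genes
  n_pos <- sum(istruth); n_neg <- sum(!istruth)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined AUC: need both functional and non-functional genes among tested genes")
  thr <- c(-1, sort(unique(sub$p)))   # -1 anchors (0, 0); max p gives (1, 1)
  pts <- data.frame(threshold = thr)
  pts$TPR <- vapply(thr, function(t) mean(sub$p[istruth] <= t), 1)
  pts$FPR <- vapply(thr, function(t) mean(sub$p[!istruth] <= t), 1)
  pts <- pts[order(pts$FPR, pts$TPR), c("threshold", "FPR", "TPR")]
  auc <- sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) + utils::tail(pts$TPR, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds; AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_summary <- function(x, ...) {
  plot(x$points$FPR, x$points$TPR, type = "s",
       xlab = "False-positive rate", ylab = "True-positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
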