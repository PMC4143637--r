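#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment: with m non-missing p values
#' sorted ascending, p_adj(i) = min over j >= i of m * p(j) / j, capped at 1
#' and mapped back to the input order. Missing entries are excluded from m
#' and returned as missing.
#'
#' @param pvals Numeric vector of p values (`NA` allowed).
#' @return Adjusted p values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Scan all genes with the hierarchical grouped-effect model
#'
#' Fits [hier_glm()] once per gene and trait, collects the group-effect Wald
#' tests, and BH-adjusts the p values within each (trait, mode, group)
#' family — rare and common p values are never mixed in one adjustment
#' family. Genes with no polymorphic variants are skipped; genes whose fits
#' did not converge are retained with `converged = FALSE` (dropping them
#' would bias the family size of the FDR adjustment).
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param map Gene-variant map from [assign_variants_to_genes()].
#' @param traits Data frame of analysis traits (columns e.g. `T1`, `T2`,
#'   `T3`, `Q1`), one row per individual in genotype row order. SBP columns
#'   are expected to be treatment-adjusted already (see [prepare_traits()]);
#'   the null trait is never adjusted.
#' @param control A [hier_control()].
#' @param mode `"stratified"` (rare and common groups) or `"combined"` (all
#'   variants, one group).
#' @return A data frame of class `"gene_scan"`, ordered by (trait, gene_id),
#'   with columns `gene_id`, `trait`, `mode`, `group`, `estimate`, `se`,
#'   `z`, `p`, `p_adj`, `n_variants`, `converged`.
#' @export
scan_genes <- function(genotypes, map, traits,
                       control = hier_control(),
                       mode = c("stratified", "combined")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(traits), nrow(traits) == nrow(genotypes))
  if (length(map) == 0L) stop("empty scan: no genes in the gene-variant map")
  trait_names <- colnames(traits)

  rows <- list()
  skipped <- character()
  for (gene in names(map)) {
    design <- build_grouped_design(genotypes, map[[gene]], mode)
    if (is.null(design)) {
      skipped <- c(skipped, gene)
      next
    }
    for (tr in trait_names) {
      fit <- suppressWarnings(hier_glm(design, traits[[tr]], control))
      tab <- group_effect_test(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, trait = tr, mode = mode, group = tab$group,
        estimate = tab$estimate, se = tab$se, z = tab$z, p = tab$p,
        n_variants = design$J_k[tab$group], converged = fit$converged,
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    message("skipped ", length(skipped), " gene(s) with no polymorphic variants")
  if (length(rows) == 0L) stop("empty scan: no gene could be fitted")
  scan <- do.call(rbind, rows)
  scan <- scan[order(scan$trait, scan$gene_id, scan$group), ]
  rownames(scan) <- NULL

  scan$p_adj <- NA_real_
  for (fam in split(seq_len(nrow(scan)),
                    list(scan$trait, scan$mode, scan$group), drop = TRUE)) {
    scan$p_adj[fam] <- bh_adjust(scan$p[fam])
  }
  scan <- scan[, c("gene_id", "trait", "mode", "group", "estimate", "se",
                   "z", "p", "p_adj", "n_variants", "converged")]
  class(scan) <- c("gene_scan", "data.frame")
  scan
}

#' Call significant genes at an FDR level
#'
#' A gene is called for a (trait, group) pair when its BH-adjusted p value is
#' strictly smaller than the FDR level (default 0.05).
#'
#' @param scan A `"gene_scan"` data frame.
#' @param fdr FDR level (default 0.05).
#' @return A named list (one element per trait.group combination present)
#'   of called gene-id vectors.
#' @export
call_significant <- function(scan, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  hit <- !is.na(scan$p_adj) & scan$p_adj < fdr
  lapply(split(scan$gene_id[hit],
               droplevels(interaction(scan$trait[hit], scan$group[hit]))),
         unique)
}
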