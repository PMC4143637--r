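#' Filter a pathway database against the analyzed genes
#'
#' Intersects each pathway's membership with the genes actually present in
#' the data and keeps only pathways retaining at least `min_genes` members
#' (default 5): very small intersections make the rank test uninformative.
#'
#' @param db A `"pathway_db"` (named list of `list(description, genes)`), as
#'   read by [read_gmt()] or built by [simulate_pathways()].
#' @param genes_in_data Character vector of gene ids present in the analysis.
#' @param min_genes Minimum number of members present (default 5).
#' @return A filtered `"pathway_db"` whose member sets are the
#'   intersections.
#' @export
filter_pathways <- function(db, genes_in_data, min_genes = 5) {
  out <- lapply(db, function(pw) {
    keep <- intersect(pw$genes, genes_in_data)
    if (length(keep) < min_genes) NULL
    else list(description = pw$description, genes = keep)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  structure(out, class = "pathway_db")
}

#' Rank-based gene-set test
#'
#' Tests whether the genes of a set sit unusually high in the ranking of
#' gene-level statistics, by a two-sample (in-set vs out-of-set) rank-sum
#' comparison. For small universes (total genes <= `exact_max`) the p value
#' is computed by exhaustive enumeration of all equally likely rank
#' assignments; otherwise by the normal approximation with mid-ranks,
#' tie-corrected variance and continuity correction.
#'
#' The `"mixed"` alternative ranks absolute statistics (is the set enriched
#' for large effects of either sign? — the recommended default when effect
#' signs depend on arbitrary allele coding across genes); `"greater"` /
#' `"less"` / `"two.sided"` rank the signed statistics.
#'
#' @param gene_stats Named numeric vector of gene-level statistics (e.g. the
#'   rare-group Wald z from a scan).
#' @param members Character vector of in-set gene ids; must be a non-empty
#'   proper subset of `names(gene_stats)`.
#' @param alternative One of `"mixed"`, `"greater"`, `"less"`,
#'   `"two.sided"`.
#' @param exact_max Largest universe size for which enumeration is used
#'   (default 10).
#' @return The p value.
#' @examples
#' z <- c(A = 3, B = 2, C = 1, D = 0)
#' rank_set_test(z, c("A", "B"), alternative = "greater")  # 1/6
#' @export
rank_set_test <- function(gene_stats,
                          members,
                          alternative = c("mixed", "greater", "less", "two.sided"),
                          exact_max = 10) {
  alternative <- match.arg(alternative)
  if (is.null(names(gene_stats))) stop("'gene_stats' must be named by gene id")
  if (!all(members %in% names(gene_stats)))
    stop("members must be a subset of the statistic universe")
  m <- length(unique(members))
  nn <- length(gene_stats)
  if (m == 0L || m == nn)
    stop("degenerate set: members must be a non-empty proper subset")

  x <- if (alternative == "mixed") abs(gene_stats) else gene_stats
  r <- rank(x)                     # mid-ranks for ties
  inset <- names(gene_stats) %in% members
  W <- sum(r[inset])

  if (nn <= exact_max) {
    sums <- utils::combn(r, m, sum)
    p_greater <- mean(sums >= W - 1e-12)
    p_less <- mean(sums <= W + 1e-12)
  } else {
    mu <- m * (nn + 1) / 2
    tie <- table(r)
    sigma2 <- m * (nn - m) / 12 * ((nn + 1) - sum(tie^3 - tie) / (nn * (nn - 1)))
    if (sigma2 <= 0) return(1)    # complete ties: no evidence either way
    sd <- sqrt(sigma2)
    p_greater <- stats::pnorm((W - mu - 0.5) / sd, lower.tail = FALSE)
    p_less <- stats::pnorm((W - mu + 0.5) / sd)
  }
  switch(alternative,
         mixed = ,
         greater = p_greater,
         less = p_less,
         two.sided = min(1, 2 * min(p_greater, p_less)))
}

#' Pathway enrichment per trait from a gene scan
#'
#' Builds the gene-level ranking from the scan (by default the rare-group
#' Wald z of the stratified analysis for the requested trait), drops genes
#' without a statistic (e.g. no rare variants), filters the pathway database
#' to sets with at least `min_genes` members among the ranked genes, and
#' applies [rank_set_test()] to each pathway. Genes on no pathway stay in the
#' out-of-set background.
#'
#' @param scan A `"gene_scan"` data frame.
#' @param db A `"pathway_db"`.
#' @param trait Trait label to analyze (e.g. `"T1"`).
#' @param nominal Nominal enrichment level (default 0.05).
#' @param group Which group's z forms the ranking (default `"rare"`; use
#'   `"all"` with a combined-mode scan).
#' @param alternative Passed to [rank_set_test()] (default `"mixed"`).
#' @param min_genes Passed to [filter_pathways()] (default 5).
#' @return A data frame with columns `pathway_id`, `trait`,
#'   `n_members_in_data`, `p`, `enriched_at_nominal`.
#' @export
enrich_all <- function(scan, db, trait, nominal = 0.05, group = "rare",
                       alternative = "mixed", min_genes = 5) {
  stopifnot(nominal > 0, nominal < 1)
  sub <- scan[scan$trait == trait & scan$group == group & !is.na(scan$z), ]
  stats_v <- stats::setNames(sub$z, sub$gene_id)
  db <- filter_pathways(db, names(stats_v), min_genes)
  if (length(db) == 0L)
    return(data.frame(pathway_id = character(), trait = character(),
                      n_members_in_data = integer(), p = numeric(),
                      enriched_at_nominal = logical()))
  p <- vapply(db, function(pw) {
    if (length(pw$genes) >= length(stats_v)) return(NA_real_)
    rank_set_test(stats_v, pw$genes, alternative)
  }, numeric(1))
  out <- data.frame(pathway_id = names(db), trait = trait,
                    n_members_in_data = vapply(db, function(pw) length(pw$genes), 1L),
                    p = as.numeric(p),
                    enriched_at_nominal = !is.na(p) & p < nominal,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
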