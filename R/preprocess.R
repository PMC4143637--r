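#' Adjust observed blood pressure for antihypertensive treatment
#'
#' Adds a constant back to the observed systolic blood pressure of treated
#' person-exams (default 10 mm Hg), the standard correction for the downward
#' confounding of genotype-blood-pressure association by antihypertensive
#' medication. Untreated entries are returned unchanged. Apply once per exam;
#' applying it twice shifts treated entries by twice the constant.
#'
#' @param sbp Numeric vector of observed SBP (mm Hg).
#' @param treated Logical (or 0/1) vector of the same length.
#' @param constant Non-negative mm Hg constant to add (default 10).
#' @return Adjusted SBP vector.
#' @examples
#' adjust_treatment(c(120, 120), c(TRUE, FALSE))  # 130, 120
#' @export
adjust_treatment <- function(sbp, treated, constant = 10) {
  if (length(sbp) != length(treated))
    stop("'sbp' and 'treated' must have the same length")
  stopifnot(constant >= 0)
  sbp + constant * as.numeric(as.logical(treated))
}

#' Minor allele frequency of a dosage column
#'
#' Computes the allele frequency as (sum of dosages) / (2 x number of
#' non-missing individuals) and folds it onto the minor side:
#' MAF = min(f, 1 - f). Missing entries are excluded from both sums. The MAF
#' is always computed on the analyzed individuals, never taken from external
#' annotation.
#'
#' @param dosage Numeric vector of minor/alternate allele counts in \[0, 2\]
#'   (possibly fractional after imputation; `NA` allowed).
#' @return The minor allele frequency in \[0, 0.5\].
#' @examples
#' compute_maf(c(0, 1, 2, 0))  # 0.375
#' @export
compute_maf <- function(dosage) {
  ok <- !is.na(dosage)
  if (!any(ok)) return(NA_real_)
  f <- sum(dosage[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Stratify variants into rare and common by MAF
#'
#' Variants with MAF below the threshold are rare; at or above it, common
#' (the 1% boundary itself is common). Monomorphic variants (MAF = 0) carry
#' no association information and are excluded from both groups.
#'
#' @param mafs Named numeric vector of minor allele frequencies (names are
#'   variant ids).
#' @param threshold Rare/common MAF threshold (default 0.01).
#' @return A list with character vectors `rare` and `common`.
#' @export
stratify_variants <- function(mafs, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 0.5)
  ids <- names(mafs)
  if (is.null(ids) && length(mafs) > 0L)
    stop("'mafs' must be named by variant id")
  poly <- !is.na(mafs) & mafs > 0
  list(rare = ids[poly & mafs < threshold],
       common = ids[poly & mafs >= threshold])
}

#' Assign variants to genes with flanking windows
#'
#' A variant belongs to a gene if it lies on the same chromosome within the
#' gene body or within `flank` bp of either side (default 10 kb), with
#' 1-based inclusive coordinates on both ends. A variant may be assigned to
#' several overlapping gene windows and is then analyzed in each.
#'
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos` and a
#'   MAF column (`maf`, or `nominal_p` as fallback) used for rare/common
#'   stratification; alternatively supply `mafs` explicitly.
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param flank Flank size in bp (default 10000).
#' @param mafs Optional named numeric vector of MAFs overriding the column in
#'   `variants`.
#' @param maf_threshold Rare/common threshold passed to
#'   [stratify_variants()].
#' @return A named list (gene id -> list(rare, common) of variant ids), the
#'   gene-variant map consumed by [build_grouped_design()] and
#'   [scan_genes()].
#' @export
assign_variants_to_genes <- function(variants, genes, flank = 10000,
                                     mafs = NULL, maf_threshold = 0.01) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end))
    stop("invalid gene model: start > end for ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  if (is.null(mafs)) {
    mcol <- if ("maf" %in% names(variants)) "maf" else "nominal_p"
    if (!mcol %in% names(variants))
      stop("no MAF available: provide 'mafs' or a maf/nominal_p column")
    mafs <- stats::setNames(variants[[mcol]], variants$variant_id)
  }
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    hit <- variants$chrom == genes$chrom[i] &
      variants$pos >= genes$start[i] - flank &
      variants$pos <= genes$end[i] + flank
    ids <- variants$variant_id[hit]
    out[[i]] <- stratify_variants(mafs[ids], maf_threshold)
  }
  out
}

#' Treatment-adjusted analysis traits from a phenotype table
#'
#' Produces the four analysis traits: SBP at exams T1-T3 with the treatment
#' constant added back per exam, and the null trait Q1 (never adjusted).
#'
#' @param phenotypes Phenotype table with columns `sbp_t1..3`,
#'   `treated_t1..3`, `q1` (see [simulate_longitudinal_sbp()] /
#'   [read_phenotypes()]).
#' @param constant Treatment adjustment in mm Hg (default 10).
#' @return Data frame with columns `T1`, `T2`, `T3`, `Q1`.
#' @export
prepare_traits <- function(phenotypes, constant = 10) {
  need <- c(paste0("sbp_t", 1:3), paste0("treated_t", 1:3), "q1")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    T1 = adjust_treatment(phenotypes$sbp_t1, phenotypes$treated_t1, constant),
    T2 = adjust_treatment(phenotypes$sbp_t2, phenotypes$treated_t2, constant),
    T3 = adjust_treatment(phenotypes$sbp_t3, phenotypes$treated_t3, constant),
    Q1 = phenotypes$q1
  )
  rownames(out) <- phenotypes$iid
  out
}
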