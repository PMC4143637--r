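#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator that emulates the
#' statistical structure of a small whole-genome-sequencing follow-up study:
#' unrelated individuals typed on one chromosome, genes carrying a mix of
#' rare (MAF < 1%) and common variants, a designated set of functional genes
#' whose variants shift systolic blood pressure (SBP), SBP observed at three
#' exams under antihypertensive treatment of rising prevalence that masks the
#' true values, and an independent standard-normal null trait.
#'
#' @param n_individuals Number of unrelated individuals (default 142).
#' @param n_genes Number of genes on the simulated chromosome (default 200;
#'   a desk-scale stand-in for a gene-dense chromosome).
#' @param variants_per_gene Mean number of variants per gene; per-gene counts
#'   are Poisson with this mean, truncated at 1. Default 20.
#' @param rare_fraction Fraction of variants drawn from the rare MAF class
#'   (default 0.7, reflecting the rare-skewed site-frequency spectrum of
#'   sequencing data).
#' @param rare_maf_range,common_maf_range Population minor-allele-frequency
#'   ranges for the two classes (defaults \[0.002, 0.01) and \[0.01, 0.5\]).
#' @param n_functional_genes Number of genes designated functional for SBP
#'   (default 31).
#' @param variance_explained Fraction of total trait variance explained by
#'   each functional variant (default 0.00273).
#' @param treatment_prevalence Treated fraction at the three exams (defaults
#'   0.155, 0.359, 0.514).
#' @param treatment_mask mm Hg subtracted from true SBP when a person-exam is
#'   treated (default 10).
#' @param baseline_mean,baseline_sd Mean and total SD of SBP at exam 1 in
#'   mm Hg (defaults 120 and 15).
#' @param exam_drift Per-exam additive drift in mm Hg (default c(0, 4, 8):
#'   blood pressure rising with age).
#' @param within_correlation Correlation of repeated SBP measures within an
#'   individual, induced by an individual-level random intercept (default
#'   0.6).
#' @param ld_r Latent correlation of a Gaussian-copula factor shared by the
#'   variants of a gene; 0 (default) gives independent Hardy-Weinberg
#'   sampling, positive values induce within-gene linkage disequilibrium.
#' @param gene_length,gene_spacing Gene length and start-to-start spacing in
#'   bp (defaults 20,000 and 50,000, so 10-kb flanks of adjacent genes do not
#'   overlap).
#' @param monotone_prevalence If `TRUE` (default) require non-decreasing
#'   treatment prevalence across exams.
#' @param seed Integer seed; every generator operation derives its own
#'   stream from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 142,
                       n_genes = 200,
                       variants_per_gene = 20,
                       rare_fraction = 0.7,
                       rare_maf_range = c(0.002, 0.01),
                       common_maf_range = c(0.01, 0.5),
                       n_functional_genes = min(31L, n_genes),
                       variance_explained = 0.00273,
                       treatment_prevalence = c(0.155, 0.359, 0.514),
                       treatment_mask = 10,
                       baseline_mean = 120,
                       baseline_sd = 15,
                       exam_drift = c(0, 4, 8),
                       within_correlation = 0.6,
                       ld_r = 0,
                       gene_length = 20000L,
                       gene_spacing = 50000L,
                       monotone_prevalence = TRUE,
                       seed = 1L) {
  if (n_individuals < 1L || n_genes < 1L)
    stop("invalid config: need at least one individual and one gene")
  if (any(treatment_prevalence < 0) || any(treatment_prevalence > 1))
    stop("invalid config: treatment prevalence must lie in [0, 1]")
  if (isTRUE(monotone_prevalence) && is.unsorted(treatment_prevalence))
    stop("invalid config: treatment prevalence must be non-decreasing")
  if (variance_explained <= 0 || variance_explained >= 1)
    stop("invalid config: variance_explained must lie in (0, 1)")
  if (baseline_sd <= 0) stop("invalid config: baseline_sd must be > 0")
  if (within_correlation < 0 || within_correlation >= 1)
    stop("invalid config: within_correlation must lie in [0, 1)")
  if (n_functional_genes > n_genes)
    stop("invalid config: more functional genes than genes")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d individuals, %d genes (~%g variants each, %g%% rare), %d functional\n",
              x$n_individuals, x$n_genes, x$variants_per_gene,
              100 * x$rare_fraction, x$n_functional_genes))
  cat(sprintf("  variance explained per functional variant: %g\n", x$variance_explained))
  cat(sprintf("  treatment prevalence %s, mask %g mm Hg; seed %d\n",
              paste(x$treatment_prevalence, collapse = "/"), x$treatment_mask,
              x$seed))
  invisible(x)
}

## distinct, fixed offsets keep the operations on independent streams while
## remaining reproducible from the single configured seed
.sim_seed <- function(cfg, offset) set.seed((cfg$seed + offset) %% .Machine$integer.max)

#' Simulate genotypes, variant table and gene models
#'
#' Draws per-variant minor-allele counts for unrelated individuals under
#' Hardy-Weinberg equilibrium: dosage ~ Binomial(2, p) with p drawn from the
#' configured rare/common MAF spectrum. With `ld_r > 0`, the two allele draws
#' of each variant are thresholded latent Gaussians sharing a per-gene factor
#' (a Gaussian copula), which induces within-gene linkage disequilibrium
#' while preserving the marginal frequencies. Genes are laid out as
#' non-overlapping intervals along one synthetic chromosome and variant
#' positions fall inside their gene.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (n x m dosage matrix, rownames individual
#'   ids, colnames variant ids), `variants` (data frame: variant_id, chrom,
#'   pos, nominal_p), and `genes` (data frame: gene_id, chrom, start, end;
#'   1-based inclusive coordinates).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .sim_seed(cfg, 101L)
  n <- cfg$n_individuals
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    chrom = "chrS",
    start = (seq_len(cfg$n_genes) - 1L) * cfg$gene_spacing + 1L,
    end = (seq_len(cfg$n_genes) - 1L) * cfg$gene_spacing + cfg$gene_length,
    stringsAsFactors = FALSE
  )
  n_var <- pmax(1L, stats::rpois(cfg$n_genes, cfg$variants_per_gene))
  vlist <- vector("list", cfg$n_genes)
  glist <- vector("list", cfg$n_genes)
  for (gi in seq_len(cfg$n_genes)) {
    m <- n_var[gi]
    is_rare <- stats::runif(m) < cfg$rare_fraction
    p <- ifelse(is_rare,
                stats::runif(m, cfg$rare_maf_range[1], cfg$rare_maf_range[2]),
                stats::runif(m, cfg$common_maf_range[1], cfg$common_maf_range[2]))
    pos <- sort(sample.int(cfg$gene_length, m, replace = FALSE)) + genes$start[gi] - 1L
    if (cfg$ld_r > 0) {
      thr <- matrix(stats::qnorm(p), n, m, byrow = TRUE)
      Zg <- matrix(0L, n, m)
      for (copy in 1:2) {
        u <- stats::rnorm(n)
        lat <- sqrt(cfg$ld_r) * u + sqrt(1 - cfg$ld_r) * matrix(stats::rnorm(n * m), n, m)
        Zg <- Zg + (lat < thr)
      }
    } else {
      Zg <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    }
    colnames(Zg) <- sprintf("%s_v%02d", genes$gene_id[gi], seq_len(m))
    vlist[[gi]] <- data.frame(variant_id = colnames(Zg), chrom = "chrS",
                              pos = pos, nominal_p = p,
                              stringsAsFactors = FALSE)
    glist[[gi]] <- Zg
  }
  genotypes <- do.call(cbind, glist)
  rownames(genotypes) <- sprintf("ind%03d", seq_len(n))
  list(genotypes = genotypes,
       variants = do.call(rbind, vlist),
       genes = genes)
}

#' Per-allele effect size from variance explained
#'
#' Inverts the additive single-locus variance identity: a variant with minor
#' allele frequency `maf` and per-allele effect b explains
#' b^2 * 2 * maf * (1 - maf) of trait variance, so
#' \eqn{b = \sqrt{v \cdot \sigma^2_y / (2\,\mathrm{maf}(1-\mathrm{maf}))}}.
#'
#' @param v Fraction of trait variance explained, in (0, 1).
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param trait_var Total trait variance (trait units squared).
#' @return Per-allele effect size in trait units.
#' @examples
#' b <- effect_from_variance_explained(0.00273, 0.005, 1)
#' b^2 * 2 * 0.005 * 0.995  # recovers 0.00273
#' @export
effect_from_variance_explained <- function(v, maf, trait_var) {
  if (any(maf <= 0)) stop("undefined effect: maf must be > 0")
  stopifnot(all(v > 0), all(v < 1), all(maf <= 0.5), trait_var > 0)
  sqrt(v * trait_var / (2 * maf * (1 - maf)))
}

#' Designate functional genes and variants
#'
#' Picks the configured number of functional genes and, within each, one
#' functional variant (preferring rare variants that are polymorphic in the
#' sample, mirroring the rare functional loci of sequencing studies), with
#' per-allele effect size derived from the configured variance-explained
#' fraction via [effect_from_variance_explained()].
#'
#' @param sim Output of [simulate_genotypes()].
#' @param cfg A [sim_config()].
#' @return A list of class `"truth_set"`: `functional_genes` (character
#'   vector) and `functional_variants` (data frame: variant_id, gene_id,
#'   effect, variance_explained).
#' @export
designate_truth <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .sim_seed(cfg, 211L)
  genes <- sample(sim$genes$gene_id, cfg$n_functional_genes)
  trait_var <- cfg$baseline_sd^2
  rows <- lapply(genes, function(g) {
    vs <- sim$variants[startsWith(sim$variants$variant_id, paste0(g, "_")), ]
    counts <- colSums(sim$genotypes[, vs$variant_id, drop = FALSE])
    poly <- vs[counts > 0, ]
    if (nrow(poly) == 0L) poly <- vs        # monomorphic gene: keep nominal pick
    rare <- poly[poly$nominal_p < 0.01, ]
    pick <- if (nrow(rare) > 0L) rare[sample.int(nrow(rare), 1L), ]
            else poly[sample.int(nrow(poly), 1L), ]
    data.frame(variant_id = pick$variant_id, gene_id = g,
               effect = effect_from_variance_explained(cfg$variance_explained,
                                                       pick$nominal_p, trait_var),
               variance_explained = cfg$variance_explained,
               stringsAsFactors = FALSE)
  })
  structure(list(functional_genes = genes,
                 functional_variants = do.call(rbind, rows)),
            class = "truth_set")
}

#' Simulate longitudinal systolic blood pressure with treatment masking
#'
#' True SBP at exam t for individual i is
#' baseline + drift_t + a_i + sum over functional variants of dosage x effect
#' + e_it, with a_i an individual random intercept (variance rho * sd^2) and
#' e_it i.i.d. exam noise (variance (1 - rho) * sd^2), giving cross-exam
#' correlation rho. Antihypertensive treatment is assigned to the
#' highest-true-SBP individuals up to each exam's configured prevalence and
#' is sticky (once treated, always treated — treatment targets high blood
#' pressure and is rarely withdrawn). Observed SBP is true SBP minus the
#' treatment mask for treated person-exams.
#'
#' @param sim Output of [simulate_genotypes()].
#' @param truth A `"truth_set"` from [designate_truth()].
#' @param cfg A [sim_config()].
#' @return A data frame (the phenotype table) with columns `iid`,
#'   `sbp_t1..sbp_t3` (observed, mm Hg), `treated_t1..treated_t3` (0/1) and
#'   `q1` (independent standard normal null trait).
#' @export
simulate_longitudinal_sbp <- function(sim, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  .sim_seed(cfg, 307L)
  n <- cfg$n_individuals
  rho <- cfg$within_correlation
  a <- stats::rnorm(n, 0, cfg$baseline_sd * sqrt(rho))
  fv <- truth$functional_variants
  genetic <- if (nrow(fv) > 0L)
    as.numeric(sim$genotypes[, fv$variant_id, drop = FALSE] %*% fv$effect)
  else rep(0, n)
  true_sbp <- sapply(1:3, function(t)
    cfg$baseline_mean + cfg$exam_drift[t] + a + genetic +
      stats::rnorm(n, 0, cfg$baseline_sd * sqrt(1 - rho)))

  treated <- matrix(FALSE, n, 3)
  for (t in 1:3) {
    target <- round(cfg$treatment_prevalence[t] * n)
    carry <- if (t > 1L) treated[, t - 1L] else rep(FALSE, n)
    need <- max(0L, target - sum(carry))
    pool <- which(!carry)
    newly <- pool[order(true_sbp[pool, t], decreasing = TRUE)][seq_len(min(need, length(pool)))]
    treated[, t] <- carry
    treated[newly, t] <- TRUE
  }
  observed <- true_sbp - cfg$treatment_mask * treated

  out <- data.frame(iid = rownames(sim$genotypes),
                    sbp_t1 = observed[, 1], sbp_t2 = observed[, 2],
                    sbp_t3 = observed[, 3],
                    treated_t1 = as.integer(treated[, 1]),
                    treated_t2 = as.integer(treated[, 2]),
                    treated_t3 = as.integer(treated[, 3]),
                    q1 = simulate_null_trait(n, cfg$seed),
                    stringsAsFactors = FALSE)
  attr(out, "true_sbp") <- true_sbp
  out
}

#' Simulate the independent null trait
#'
#' Standard normal draws on a random stream of their own, so the trait is
#' independent of genotypes and of SBP by construction.
#'
#' @param n Number of individuals.
#' @param seed Integer seed (the generator offsets it onto a dedicated
#'   stream).
#' @return Numeric vector of length `n`.
#' @export
simulate_null_trait <- function(n, seed) {
  set.seed((seed + 104729L) %% .Machine$integer.max)
  stats::rnorm(n)
}

#' Simulate a pathway database over the simulated genes
#'
#' Draws random gene sets and forces a configurable number of them to contain
#' at least one functional gene, so that enrichment and crosstalk analyses
#' are exercisable on synthetic data.
#'
#' @param gene_ids Character vector of all gene ids.
#' @param n_pathways Number of pathways (default 50).
#' @param size_range Two-element integer range of pathway sizes (default
#'   c(5, 20)).
#' @param n_with_functional How many pathways must contain at least one
#'   functional gene (default 10; capped at `n_pathways`).
#' @param truth A `"truth_set"`, or `NULL` to skip the forcing rule.
#' @param seed Integer seed.
#' @return A named list of class `"pathway_db"`; each element is a list with
#'   `description` and `genes`.
#' @export
simulate_pathways <- function(gene_ids, n_pathways = 50, size_range = c(5, 20),
                              n_with_functional = 10, truth = NULL, seed = 1L) {
  set.seed((seed + 401L) %% .Machine$integer.max)
  stopifnot(size_range[1] >= 1, size_range[2] >= size_range[1],
            size_range[2] <= length(gene_ids))
  n_with_functional <- min(n_with_functional, n_pathways)
  db <- vector("list", n_pathways)
  names(db) <- sprintf("PW%03d", seq_len(n_pathways))
  for (i in seq_len(n_pathways)) {
    sizes <- seq.int(size_range[1], size_range[2])
    size <- sizes[sample.int(length(sizes), 1L)]
    members <- sample(gene_ids, size)
    if (!is.null(truth) && i <= n_with_functional &&
        !any(members %in% truth$functional_genes)) {
      members[sample.int(size, 1L)] <- sample(truth$functional_genes, 1L)
    }
    db[[i]] <- list(description = sprintf("synthetic pathway %d", i),
                    genes = unique(members))
  }
  structure(db, class = "pathway_db")
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running the whole generator: genotypes, gene models,
#' truth set, longitudinal phenotypes and pathways, all reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param n_pathways,n_with_functional,pathway_size_range Passed to
#'   [simulate_pathways()].
#' @return A list with `genotypes`, `variants`, `genes`, `truth`,
#'   `phenotypes`, `pathways`.
#' @export
simulate_study <- function(cfg = sim_config(), n_pathways = 50,
                           n_with_functional = 10,
                           pathway_size_range = c(5, 20)) {
  sim <- simulate_genotypes(cfg)
  truth <- designate_truth(sim, cfg)
  phenos <- simulate_longitudinal_sbp(sim, truth, cfg)
  pathways <- simulate_pathways(sim$genes$gene_id, n_pathways,
                                pmin(pathway_size_range, cfg$n_genes),
                                n_with_functional, truth, cfg$seed)
  list(genotypes = sim$genotypes, variants = sim$variants, genes = sim$genes,
       truth = truth, phenotypes = phenos, pathways = pathways)
}
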