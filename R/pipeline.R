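#' Pipeline configuration
#'
#' Assembles every threshold of the end-to-end workflow into one plain
#' object that round-trips losslessly through YAML, so each analysis
#' constant (10 mm Hg treatment adjustment, 10-kb gene flanks, 1% MAF
#' threshold, FDR 0.05, nominal enrichment 0.05, >= 5 pathway genes) is
#' visible and overridable.
#'
#' @param out_dir Output directory for all artifacts.
#' @param treatment_constant Treatment adjustment, mm Hg (default 10).
#' @param flank Gene window flank, bp (default 10000).
#' @param maf_threshold Rare/common MAF threshold (default 0.01).
#' @param fdr Gene-level FDR level (default 0.05).
#' @param nominal Nominal pathway-enrichment level (default 0.05).
#' @param min_pathway_genes Minimum pathway size in the data (default 5).
#' @param enrichment_alternative Rank-test alternative (default `"mixed"`).
#' @param enrichment_group Gene statistic used for the ranking (default
#'   `"rare"`).
#' @param modes Grouping modes to scan (default both).
#' @param time_pairs List of adjacent exam pairs for crosstalk (default
#'   T1-T2 and T2-T3).
#' @param tau_beta,tau_g,method Fitter settings, see [hier_control()].
#' @param sim A [sim_config()] for the `simulate` stage (default
#'   `sim_config(seed = seed)`).
#' @param seed Integer seed.
#' @param paths Optional named list of input file paths (`vcf`,
#'   `phenotypes`, `genes`, `gmt`, `truth`); filled in by the simulate stage
#'   when absent.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "dynpath_out",
                            treatment_constant = 10,
                            flank = 10000,
                            maf_threshold = 0.01,
                            fdr = 0.05,
                            nominal = 0.05,
                            min_pathway_genes = 5,
                            enrichment_alternative = "mixed",
                            enrichment_group = "rare",
                            modes = c("stratified", "combined"),
                            time_pairs = list(c("T1", "T2"), c("T2", "T3")),
                            tau_beta = 0.5, tau_g = 10,
                            method = "em",
                            sim = NULL,
                            seed = 1L,
                            paths = list()) {
  stopifnot(fdr > 0, fdr < 1, nominal > 0, nominal < 1,
            maf_threshold > 0, maf_threshold <= 0.5, flank >= 0,
            treatment_constant >= 0)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param cfg A `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  cfg <- do.call(pipeline_config, x)
  cfg$sim <- sim
  cfg
}

.cfg_path <- function(cfg, what, default) {
  p <- cfg$paths[[what]]
  if (is.null(p)) file.path(cfg$out_dir, default) else p
}

#' Run the dynamic pathway analysis pipeline
#'
#' Orchestrates the study workflow over file-based interfaces, so simulated
#' inputs can be replaced by real data files of the same formats:
#' \describe{
#'   \item{simulate}{generate a synthetic study and write VCF, phenotype
#'     TSV, gene models, GMT pathways and truth TSV;}
#'   \item{scan}{read those files, adjust SBP for treatment, stratify
#'     variants by MAF, assign them to 10-kb gene windows, and fit the
#'     hierarchical model per gene x trait x mode with BH correction
#'     (scan.tsv);}
#'   \item{enrich}{rank-based pathway enrichment per trait
#'     (enrichment.tsv);}
#'   \item{crosstalk}{crosstalk networks for each adjacent exam pair, in
#'     GraphML and SIF;}
#'   \item{evaluate}{confusion rates per trait x group and ROC/AUC against
#'     the truth set (confusion.tsv, roc_auc.tsv);}
#'   \item{all}{everything above in order.}
#' }
#'
#' @param cfg A `"pipeline_config"` (or path to its YAML).
#' @param stage One of `"simulate"`, `"scan"`, `"enrich"`, `"crosstalk"`,
#'   `"evaluate"`, `"all"`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(cfg, stage = c("all", "simulate", "scan", "enrich",
                                        "crosstalk", "evaluate")) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  stages <- if (stage == "all")
    c("simulate", "scan", "enrich", "crosstalk", "evaluate") else stage

  log_path <- file.path(cfg$out_dir, "run.log")
  logit <- function(...) cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")),
                             sprintf(...), "\n", sep = "", file = log_path,
                             append = TRUE)
  logit("dynpath %s; seed %d; stages: %s",
        as.character(utils::packageVersion("dynpath")), cfg$seed,
        paste(stages, collapse = ", "))
  write_config(cfg, file.path(cfg$out_dir, "config_used.yaml"))

  if ("simulate" %in% stages) {
    study <- simulate_study(cfg$sim)
    artifacts$vcf <- .cfg_path(cfg, "vcf", "genotypes.vcf")
    write_vcf(study$genotypes, study$variants, artifacts$vcf)
    artifacts$phenotypes <- .cfg_path(cfg, "phenotypes", "phenotypes.tsv")
    write_phenotypes(study$phenotypes, artifacts$phenotypes)
    artifacts$genes <- .cfg_path(cfg, "genes", "genes.tsv")
    write_gene_models(study$genes, artifacts$genes)
    artifacts$gmt <- .cfg_path(cfg, "gmt", "pathways.gmt")
    write_gmt(study$pathways, artifacts$gmt)
    artifacts$truth <- .cfg_path(cfg, "truth", "truth.tsv")
    write_truth(study$truth, artifacts$truth)
    logit("simulate: %d individuals, %d variants, %d genes",
          nrow(study$genotypes), ncol(study$genotypes), nrow(study$genes))
  }

  scan_path <- file.path(cfg$out_dir, "scan.tsv")
  if ("scan" %in% stages) {
    geno <- read_vcf(.cfg_path(cfg, "vcf", "genotypes.vcf"))
    phenos <- read_phenotypes(.cfg_path(cfg, "phenotypes", "phenotypes.tsv"))
    genes <- read_gene_models(.cfg_path(cfg, "genes", "genes.tsv"))
    stopifnot(identical(phenos$iid, rownames(geno$genotypes)))
    traits <- prepare_traits(phenos, cfg$treatment_constant)
    map <- assign_variants_to_genes(geno$variants, genes, cfg$flank,
                                    maf_threshold = cfg$maf_threshold)
    ctrl <- hier_control(tau_beta = cfg$tau_beta, tau_g = cfg$tau_g,
                         method = cfg$method)
    scans <- lapply(cfg$modes, function(m)
      scan_genes(geno$genotypes, map, traits, ctrl, mode = m))
    scan <- do.call(rbind, scans)
    .write_tsv(scan, scan_path)
    artifacts$scan <- scan_path
    conv <- tapply(scan$converged, scan$mode, mean)
    logit("scan: %d rows; convergence by mode: %s", nrow(scan),
          paste(sprintf("%s %.1f%%", names(conv), 100 * conv), collapse = ", "))
  }

  enrich_path <- file.path(cfg$out_dir, "enrichment.tsv")
  if ("enrich" %in% stages) {
    scan <- utils::read.table(scan_path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
    db <- read_gmt(.cfg_path(cfg, "gmt", "pathways.gmt"))
    enr <- do.call(rbind, lapply(c("T1", "T2", "T3", "Q1"), function(tr)
      enrich_all(scan, db, tr, cfg$nominal, cfg$enrichment_group,
                 cfg$enrichment_alternative, cfg$min_pathway_genes)))
    .write_tsv(enr, enrich_path)
    artifacts$enrichment <- enrich_path
    logit("enrich: %d pathway x trait tests, %d nominally enriched",
          nrow(enr), sum(enr$enriched_at_nominal))
  }

  if ("crosstalk" %in% stages) {
    enr <- utils::read.table(enrich_path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    db <- read_gmt(.cfg_path(cfg, "gmt", "pathways.gmt"))
    truth <- read_truth(.cfg_path(cfg, "truth", "truth.tsv"))
    for (tp in cfg$time_pairs) {
      net <- build_crosstalk(enr, db, truth$functional_genes, tp)
      tag <- paste(tp, collapse = "_")
      gml <- file.path(cfg$out_dir, sprintf("crosstalk_%s.graphml", tag))
      sif <- file.path(cfg$out_dir, sprintf("crosstalk_%s.sif", tag))
      export_network(net, gml, "graphml")
      export_network(net, sif, "sif")
      artifacts[[paste0("crosstalk_", tag)]] <- gml
      logit("crosstalk %s: %d nodes, %d edges", tag, nrow(net$nodes),
            nrow(net$edges))
    }
  }

  if ("evaluate" %in% stages) {
    truth_path <- .cfg_path(cfg, "truth", "truth.tsv")
    if (!file.exists(truth_path))
      stop("evaluate requires a truth file (designated functional genes); ",
           "none found at ", truth_path)
    truth <- read_truth(truth_path)
    scan <- utils::read.table(scan_path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
    combos <- unique(scan[, c("trait", "group")])
    conf <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
      confusion_rates(scan, truth, cfg$fdr, combos$trait[i], combos$group[i])))
    .write_tsv(conf, file.path(cfg$out_dir, "confusion.tsv"))
    aucs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      a <- tryCatch(roc_auc(scan, truth, combos$trait[i], combos$group[i])$auc,
                    error = function(e) NA_real_)
      data.frame(trait = combos$trait[i], group = combos$group[i], auc = a)
    }))
    .write_tsv(aucs, file.path(cfg$out_dir, "roc_auc.tsv"))
    artifacts$confusion <- file.path(cfg$out_dir, "confusion.tsv")
    artifacts$roc_auc <- file.path(cfg$out_dir, "roc_auc.tsv")
    logit("evaluate: %d trait x group combinations scored", nrow(combos))
  }

  invisible(artifacts)
}
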