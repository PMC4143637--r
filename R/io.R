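## File formats: VCF for genotypes, TSV tables for phenotypes / gene models /
## truth, GMT for pathways. All writers emit a "# dynpath <version>" comment
## header (plus a declared coordinate convention for gene models); all
## readers validate schemas and report offending line numbers.

.tool_header <- function() {
  sprintf("# dynpath %s", as.character(utils::packageVersion("dynpath")))
}

.write_tsv <- function(df, path, header = .tool_header()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, required, what) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write genotypes as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 file with biallelic records (REF A, ALT G,
#' placeholder alleles) and a GT field per individual encoding the dosage
#' (0/0, 0/1, 1/1). The ALT allele carries the minor-allele dosage as
#' generated.
#'
#' @param genotypes Dosage matrix (individuals x variants, values 0/1/2).
#' @param variants Variant table with `variant_id`, `chrom`, `pos` in the
#'   column order of `genotypes`.
#' @param path Output path.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            "A", "G", ".", "PASS", ".", "GT",
            gt_code[as.character(genotypes[, i])]), collapse = "\t")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=dynpath %s",
                       as.character(utils::packageVersion("dynpath"))),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)), collapse = "\t")),
             con)
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a (plain or gzipped) VCF with vcfR, rejects multi-allelic records
#' explicitly, converts GT to alternate-allele dosage, imputes missing
#' genotypes by the variant's mean dosage, and orients every variant to the
#' minor allele of the analyzed individuals (sites where the alternate
#' allele frequency exceeds 0.5 are flipped to count the reference allele).
#' Variants are returned in deterministic (chrom, pos) order.
#'
#' @param path VCF file path.
#' @return A list with `genotypes` (individuals x variants dosage matrix)
#'   and `variants` (data frame: `variant_id`, `chrom`, `pos`, `maf` —
#'   computed from the analyzed individuals).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record file
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0", "0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1", "1")] <- 2
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    message("imputing ", n_missing, " missing genotype(s) by variant mean dosage")
    for (i in which(rowSums(is.na(dos)) > 0)) {
      mu <- mean(dos[i, ], na.rm = TRUE)
      dos[i, is.na(dos[i, ])] <- if (is.nan(mu)) 0 else mu
    }
  }
  ## orient to the minor allele of the analyzed sample set
  af <- rowMeans(dos) / 2
  flip <- !is.na(af) & af > 0.5
  dos[flip, ] <- 2 - dos[flip, ]

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         maf = unname(apply(dos, 1, compute_maf)),
                         stringsAsFactors = FALSE)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, ]
  rownames(variants) <- NULL
  genotypes <- t(dos[o, , drop = FALSE])
  colnames(genotypes) <- variants$variant_id
  list(genotypes = genotypes, variants = variants)
}

#' Write / read gene models
#'
#' Tab-separated gene models (`gene_id`, `chrom`, `start`, `end`) with a
#' header comment declaring the coordinate convention: 1-based inclusive on
#' both ends (matching VCF positions), deliberately not 0-based BED.
#'
#' @param genes Gene model data frame.
#' @param path File path.
#' @return The path (writer) or the validated data frame (reader).
#' @export
write_gene_models <- function(genes, path) {
  .write_tsv(genes[, c("gene_id", "chrom", "start", "end")], path,
             c(.tool_header(), "# coordinates: 1-based, inclusive"))
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  df <- .read_tsv(path, c("gene_id", "chrom", "start", "end"), "gene model")
  if (any(df$start > df$end))
    stop("invalid gene model: start > end at line(s) ",
         paste(which(df$start > df$end), collapse = ", "))
  df
}

#' Write / read the phenotype table
#'
#' Tab-separated phenotypes: individual id, observed SBP and treatment
#' indicator at exams T1-T3, and the null trait Q1.
#'
#' @param phenotypes Phenotype data frame.
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  cols <- c("iid", paste0("sbp_t", 1:3), paste0("treated_t", 1:3), "q1")
  .write_tsv(phenotypes[, cols], path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  .read_tsv(path, c("iid", paste0("sbp_t", 1:3), paste0("treated_t", 1:3), "q1"),
            "phenotype")
}

#' Write / read the truth set
#'
#' Tab-separated designation of functional variants (variant, gene,
#' per-allele effect, variance explained); the functional gene set is the
#' set of distinct gene ids.
#'
#' @param truth A `"truth_set"`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  .write_tsv(truth$functional_variants, path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  fv <- .read_tsv(path, c("variant_id", "gene_id", "effect", "variance_explained"),
                  "truth")
  structure(list(functional_genes = unique(fv$gene_id), functional_variants = fv),
            class = "truth_set")
}

#' Read / write pathway databases in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated — id, description, then
#' member gene ids. Lines with fewer than three fields are rejected with
#' their line number.
#'
#' @param path GMT file path.
#' @param db A `"pathway_db"` (named list of `list(description, genes)`).
#' @return The `"pathway_db"` (reader) or the path (writer).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need id, description, >=1 gene): line ",
         paste(bad, collapse = ", "))
  db <- lapply(parts, function(x) list(description = x[2], genes = unique(x[-(1:2)])))
  names(db) <- vapply(parts, `[`, "", 1L)
  structure(db, class = "pathway_db")
}

#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(id)
    paste(c(id, db[[id]]$description, db[[id]]$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
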