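test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 10, n_functional_genes = 3, seed = 42)
  s1 <- simulate_study(cfg, n_pathways = 8)
  s2 <- simulate_study(cfg, n_pathways = 8)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pathways, s2$pathways)
  s3 <- simulate_study(sim_config(n_genes = 10, n_functional_genes = 3,
                                  seed = 43), n_pathways = 8)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("genotype sampling honors the nominal allele frequency", {
  # degenerate frequency: p = 0 gives an all-zero column
  cfg0 <- sim_config(n_individuals = 50, n_genes = 1, variants_per_gene = 1,
                     rare_fraction = 0, common_maf_range = c(0, 0), seed = 1)
  expect_true(all(simulate_genotypes(cfg0)$genotypes == 0))

  # binomial sampling oracle: at n = 10,000 and p = 0.3 the empirical allele
  # frequency lies within 3 binomial standard errors of 0.3
  cfg <- sim_config(n_individuals = 10000, n_genes = 1, variants_per_gene = 1,
                    rare_fraction = 0, common_maf_range = c(0.3, 0.3), seed = 2)
  sim <- simulate_genotypes(cfg)
  f <- sum(sim$genotypes) / (2 * 10000)
  se <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(f - 0.3), 3 * se)

  expect_error(sim_config(n_individuals = 0), "invalid config")
})

test_that("variant positions fall inside their gene and MAF classes match the spectrum", {
  cfg <- sim_config(n_genes = 30, seed = 3)
  sim <- simulate_genotypes(cfg)
  g <- sim$genes[match(sub("_v[0-9]+$", "", sim$variants$variant_id),
                       sim$genes$gene_id), ]
  expect_true(all(sim$variants$pos >= g$start & sim$variants$pos <= g$end))
  # configured 70% rare in expectation
  frac_rare <- mean(sim$variants$nominal_p < 0.01)
  expect_lt(abs(frac_rare - 0.7), 3 * sqrt(0.7 * 0.3 / nrow(sim$variants)))
})

test_that("effect size inverts the additive variance-explained identity", {
  b <- effect_from_variance_explained(0.00273, 0.005, 1)
  expect_equal(b^2 * 2 * 0.005 * (1 - 0.005), 0.00273, tolerance = 1e-12)
  # round trip at random parameter draws
  set.seed(4)
  for (i in 1:20) {
    v <- runif(1, 1e-4, 0.5); maf <- runif(1, 1e-3, 0.5); tv <- runif(1, 0.5, 400)
    b <- effect_from_variance_explained(v, maf, tv)
    expect_equal(b^2 * 2 * maf * (1 - maf) / tv, v, tolerance = 1e-12)
  }
  # zero-effect limit
  expect_lt(effect_from_variance_explained(1e-12, 0.2, 1), 1e-5)
  expect_error(effect_from_variance_explained(0.01, 0, 1), "maf")
})

test_that("treatment assignment hits the printed prevalences and is sticky", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_genotypes(cfg)
  truth <- designate_truth(sim, cfg)
  ph <- simulate_longitudinal_sbp(sim, truth, cfg)
  counts <- c(sum(ph$treated_t1), sum(ph$treated_t2), sum(ph$treated_t3))
  expect_identical(counts, c(22L, 51L, 73L))   # 15.5%, 35.9%, 51.4% of 142
  expect_true(all(abs(counts / 142 - c(0.155, 0.359, 0.514)) <= 1 / 142))
  # sticky: once treated, always treated
  expect_true(all(ph$treated_t2 >= ph$treated_t1))
  expect_true(all(ph$treated_t3 >= ph$treated_t2))
  # masking: observed = true - 10 for treated person-exams, untouched otherwise
  true_sbp <- attr(ph, "true_sbp")
  expect_equal(ph$sbp_t2, true_sbp[, 2] - 10 * ph$treated_t2)
  expect_error(sim_config(treatment_prevalence = c(0.2, 0.5, 1.2)),
               "invalid config")
})

test_that("regression on a functional variant recovers its effect size", {
  cfg <- sim_config(n_individuals = 8000, n_genes = 2, variants_per_gene = 3,
                    rare_fraction = 0, common_maf_range = c(0.2, 0.4),
                    n_functional_genes = 1, variance_explained = 0.02,
                    seed = 6)
  sim <- simulate_genotypes(cfg)
  truth <- designate_truth(sim, cfg)
  ph <- simulate_longitudinal_sbp(sim, truth, cfg)
  true_sbp <- attr(ph, "true_sbp")
  fv <- truth$functional_variants
  slope <- coef(lm(true_sbp[, 1] ~ sim$genotypes[, fv$variant_id]))[2]
  se <- summary(lm(true_sbp[, 1] ~ sim$genotypes[, fv$variant_id]))$coefficients[2, 2]
  expect_lt(abs(slope - fv$effect), 3.5 * se)
})

test_that("variance explained by a single functional variant converges to the target", {
  cfg <- sim_config(n_individuals = 20000, n_genes = 1, variants_per_gene = 1,
                    rare_fraction = 0, common_maf_range = c(0.3, 0.3),
                    n_functional_genes = 1, variance_explained = 0.02, seed = 7)
  sim <- simulate_genotypes(cfg)
  truth <- designate_truth(sim, cfg)
  z <- sim$genotypes[, truth$functional_variants$variant_id]
  v_hat <- var(z * truth$functional_variants$effect) / cfg$baseline_sd^2
  expect_equal(v_hat, 0.02, tolerance = 0.05)
})

test_that("the null trait is standard normal, reproducible and independent", {
  q <- simulate_null_trait(10000, 9)
  expect_lt(abs(mean(q)), 3 / sqrt(10000))
  expect_lt(abs(sd(q) - 1), 3 / sqrt(2 * 10000))
  expect_identical(q, simulate_null_trait(10000, 9))
  # independence by construction: same seed, correlation with genotypes small
  cfg <- sim_config(n_genes = 20, seed = 9)
  sim <- simulate_genotypes(cfg)
  q1 <- simulate_null_trait(142, 9)
  poly <- sim$genotypes[, apply(sim$genotypes, 2, var) > 0]
  r <- abs(cor(q1, poly))
  expect_lt(mean(r > 2 / sqrt(142)), 0.10)  # no systematic excess
})

test_that("simulated pathways respect size and functional-overlap rules and round-trip GMT", {
  cfg <- sim_config(n_genes = 40, n_functional_genes = 5, seed = 10)
  sim <- simulate_genotypes(cfg)
  truth <- designate_truth(sim, cfg)
  db <- simulate_pathways(sim$genes$gene_id, n_pathways = 12,
                          size_range = c(5, 5), n_with_functional = 6,
                          truth = truth, seed = 10)
  expect_true(all(vapply(db, function(p) length(p$genes), 1L) == 5L))
  for (i in 1:6)
    expect_gt(length(intersect(db[[i]]$genes, truth$functional_genes)), 0)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  db2 <- read_gmt(path)
  expect_equal(unclass(db2), unclass(db))
})
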