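test_that("grouped designs keep the rare/common bookkeeping straight", {
  Z <- make_geno(60, c(rep(0.005, 3), rep(0.3, 2)), seed = 1)
  entry <- list(rare = paste0("v", 1:3), common = paste0("v", 4:5))
  d <- build_grouped_design(Z, entry, "stratified")
  expect_identical(names(d$groups), c("rare", "common"))
  expect_identical(unname(d$J_k), c(3L, 2L))
  dc <- build_grouped_design(Z, entry, "combined")
  expect_identical(names(dc$groups), "all")
  expect_identical(dc$J, 5L)
  # degenerate group: only rare variants present -> single-group design
  dr <- build_grouped_design(Z, list(rare = paste0("v", 1:3), common = character()),
                             "stratified")
  expect_identical(names(dr$groups), "rare")
  expect_null(build_grouped_design(Z, list(rare = character(), common = character())))
})

test_that("with one variant and diffuse priors the fitted effect is the OLS slope", {
  set.seed(2)
  Z <- make_geno(200, 0.3)
  y <- 0.7 * Z[, 1] + rnorm(200)
  # diffuse priors validate the blockwise scheme itself (plug-in steps);
  # the marginal-EM variant is intentionally scale-pinned by proper priors
  ctrl <- hier_control(tau_beta = 1e4, tau_g = 1e4, tol = 1e-10,
                       max_iter = 1000, method = "plugin")
  fit <- suppressWarnings(hier_glm(Z, y, ctrl))
  ols <- unname(coef(lm(y ~ Z[, 1]))[2])
  expect_equal(unname(fit$g["all"] * fit$beta[1]), ols, tolerance = 1e-5)
})

test_that("in the diffuse-prior limit the fitted values approach the OLS fit", {
  set.seed(3)
  Z <- make_geno(80, c(0.4, 0.3, 0.2, 0.35, 0.25))
  y <- Z %*% c(0.5, -0.3, 0.2, 0, 0.4) + rnorm(80)
  ctrl <- hier_control(tau_beta = 1e4, tau_g = 1e4, tol = 1e-10,
                       max_iter = 2000, method = "plugin")
  d <- build_grouped_design(Z, list(rare = character(), common = colnames(Z)),
                            "stratified")
  fit <- suppressWarnings(hier_glm(d, y, ctrl))
  expect_equal(fit$eta, unname(fitted(lm(y ~ Z))), tolerance = 1e-3)
})

test_that("with frozen coefficients the model is a ridge burden regression", {
  set.seed(4)
  gg <- make_gene_geno(150, 6, 0, seed = 4)
  y <- rowSums(gg$Z) * 0.4 + rnorm(150)
  fit <- hier_glm(build_grouped_design(gg$Z, gg$groups), y,
                  hier_control(beta_update = FALSE, tol = 1e-10, max_iter = 500))
  expect_true(all(fit$beta == 1))
  counts <- rowSums(gg$Z[, gg$groups$rare, drop = FALSE])
  oracle <- burden_ridge_oracle(counts, y, tau_g = 10)
  expect_equal(unname(fit$g["rare"]), oracle$coef[2], tolerance = 1e-6)
  expect_equal(fit$theta, oracle$theta, tolerance = 1e-6)
})

test_that("the fitting objective is monotone over random instances, both methods", {
  set.seed(5)
  for (r in 1:30) {
    gg <- make_gene_geno(60, 4, 4)
    y <- rnorm(60, sd = runif(1, 0.5, 3))
    d <- build_grouped_design(gg$Z, gg$groups)
    expect_no_error(suppressWarnings(hier_glm(d, y, hier_control(debug = TRUE))))
    expect_no_error(suppressWarnings(
      hier_glm(d, y, hier_control(method = "plugin", debug = TRUE))))
  }
})

test_that("the optimum is stable across random initializations", {
  set.seed(6)
  gg <- make_gene_geno(142, 8, 6, seed = 6)
  y <- rowSums(gg$Z[, gg$groups$rare, drop = FALSE]) * 0.8 + rnorm(142)
  d <- build_grouped_design(gg$Z, gg$groups)
  ctrl <- hier_control(tol = 1e-8, max_iter = 1000)
  base <- hier_glm(d, y, ctrl)
  for (i in 1:5) {
    init <- list(beta0 = mean(y) + rnorm(1),
                 beta = rnorm(d$J, 1, 0.2), g = rnorm(2, 0, 0.5))
    fit <- suppressWarnings(hier_glm(d, y, ctrl, init = init))
    expect_lt(max(abs(fit$g - base$g)), 10 * ctrl$tol * 1e2)
  }
})

test_that("null traits yield approximately nominal (or conservative) Wald rejection", {
  # Monte-Carlo null oracle: n = 500, 20 variants, 500 replicates; the
  # |z| > 1.96 rate should be at most ~5% (shrinkage may push it below)
  set.seed(7)
  n <- 500; nrep <- 500
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    gg <- make_gene_geno(n, 12, 8)
    y <- rnorm(n)
    d <- build_grouped_design(gg$Z, gg$groups)
    fit <- suppressWarnings(hier_glm(d, y))
    rej[r] <- any(abs(fit$z) > 1.96, na.rm = TRUE)
  }
  # two groups tested per replicate -> bound 2 * 0.05 plus 3 MC standard errors
  expect_lt(mean(rej), 0.10 + 3 * sqrt(0.1 * 0.9 / nrep))
})

test_that("a shared positive rare-variant effect is recovered with the right sign", {
  set.seed(8)
  hits <- 0L
  for (r in 1:25) {
    gg <- make_gene_geno(1000, 10, 5)
    y <- rowSums(gg$Z[, gg$groups$rare, drop = FALSE]) + rnorm(1000)
    fit <- suppressWarnings(hier_glm(build_grouped_design(gg$Z, gg$groups), y))
    hits <- hits + (fit$g["rare"] > 0)
  }
  expect_gte(hits, 24L)
})

test_that("group-effect Wald tests behave as two-sided normal tests", {
  set.seed(9)
  gg <- make_gene_geno(120, 5, 5, seed = 9)
  y <- rnorm(120)
  fit <- suppressWarnings(hier_glm(build_grouped_design(gg$Z, gg$groups), y))
  tab <- group_effect_test(fit)
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)))
  # sign symmetry: flipping the trait flips the estimates, not the p values
  fit2 <- suppressWarnings(hier_glm(build_grouped_design(gg$Z, gg$groups), -y))
  expect_equal(fit2$g, -fit$g, tolerance = 1e-4)
  expect_equal(fit2$p, fit$p, tolerance = 1e-3)
})

test_that("fit methods expose the usual modelling surface", {
  set.seed(10)
  gg <- make_gene_geno(100, 4, 4, seed = 10)
  y <- rnorm(100, 120, 10)
  fit <- suppressWarnings(hier_glm(build_grouped_design(gg$Z, gg$groups), y))
  expect_s3_class(fit, "hier_glm")
  expect_output(print(fit), "Hierarchical grouped-effect")
  expect_output(print(summary(fit)), "Wald tests")
  expect_named(coef(fit)["(Intercept)"], "(Intercept)")
  expect_equal(residuals(fit), y - fit$eta)
  expect_equal(predict(fit), fit$eta)
  expect_equal(predict(fit, fit$design$Z), fit$eta)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(100L, 3L))
  expect_error(hier_glm(build_grouped_design(gg$Z, gg$groups), c(y, 1)), "finite")
})

test_that("non-convergence is a flagged result, not an error", {
  set.seed(11)
  gg <- make_gene_geno(80, 4, 4, seed = 11)
  y <- rowSums(gg$Z) + rnorm(80)
  expect_warning(
    fit <- hier_glm(build_grouped_design(gg$Z, gg$groups), y,
                    hier_control(tol = 1e-14, max_iter = 2)),
    "did not converge")
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$p)))
})
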