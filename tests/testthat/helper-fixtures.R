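# Small in-code fixtures and independently coded oracles shared by the suite.

# Hardy-Weinberg genotype matrix with named columns
make_geno <- function(n, p, seed = NULL, prefix = "v") {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rbinom(n * length(p), 2, rep(p, each = n)), n, length(p))
  colnames(Z) <- paste0(prefix, seq_along(p))
  rownames(Z) <- sprintf("ind%03d", seq_len(n))
  Z
}

# genotypes for one gene with both MAF classes present in-sample
make_gene_geno <- function(n, n_rare = 5, n_common = 5, seed = NULL) {
  Z <- make_geno(n, c(runif(n_rare, 0.002, 0.01), runif(n_common, 0.05, 0.5)),
                 seed = seed)
  maf <- apply(Z, 2, compute_maf)
  list(Z = Z, groups = stratify_variants(maf))
}

# brute-force BH step-up, written independently of bh_adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# pairwise Mann-Whitney AUC with half credit for ties (smaller p = better)
auc_oracle <- function(p_truth, p_null) {
  s <- 0
  for (a in p_truth) for (b in p_null)
    s <- s + (a < b) + 0.5 * (a == b)
  s / (length(p_truth) * length(p_null))
}

# one-group ridge-with-offset fixed point, independent of the fitter:
# burden regression of y on per-group counts with the g prior as penalty
burden_ridge_oracle <- function(counts, y, tau_g, n_iter = 500) {
  X <- cbind(1, counts)
  K <- ncol(X) - 1L
  theta <- var(y) * (length(y) - 1) / length(y)
  cf <- rep(0, K + 1L)
  for (i in seq_len(n_iter)) {
    A <- crossprod(X) + theta * diag(c(0, rep(1 / tau_g^2, K)), K + 1L)
    cf <- solve(A, crossprod(X, y))
    theta <- mean((y - X %*% cf)^2)
  }
  list(coef = as.numeric(cf), theta = theta)
}
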