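#' Control parameters for the hierarchical grouped-effect model
#'
#' Collects the prior scales and fitting controls for [hier_glm()]. The model
#' places a Normal(1, tau_beta^2) prior on the per-variant coefficients
#' (centered at 1 so that each group effect is interpretable as the
#' group-average per-allele effect) and a Normal(0, tau_g^2) prior on the
#' group effects; the test of association is a Wald test of g_k = 0.
#'
#' @param tau_beta Prior standard deviation of the variant-level coefficients
#'   around their center of 1. Smaller values pull the model toward a pure
#'   burden collapse (all coefficients equal); larger values let individual
#'   variants deviate. Default 0.5.
#' @param tau_g Prior standard deviation of the group effects around 0.
#'   Default 10 (weak on the mm Hg scale).
#' @param tol Convergence tolerance: maximum absolute change of any parameter
#'   between iterations. Default 1e-6.
#' @param max_iter Maximum number of blockwise iterations. Default 200.
#' @param method `"em"` (default) integrates over the uncertainty of the
#'   variant coefficients: their posterior covariance enters the group-effect
#'   normal equations, the dispersion update and the standard errors, giving
#'   calibrated-to-conservative null behavior. `"plugin"` treats the fitted
#'   variant coefficients as known when estimating and testing the group
#'   effects; because those coefficients are themselves adapted to the trait,
#'   plug-in Wald tests are anti-conservative for variant-rich genes, and
#'   increasingly so the more (and the more variable) the variants in a group
#'   — the mechanism behind the grossly inflated type I error of analyzing
#'   all variants of a gene as one group.
#' @param beta_update If `FALSE`, variant coefficients are frozen at 1 and the
#'   model reduces exactly to a ridge-penalized burden regression on per-group
#'   minor-allele counts. Default `TRUE`.
#' @param debug If `TRUE`, assert at every iteration that the fitting
#'   objective (the penalized marginal log-likelihood for `"em"`, the
#'   penalized joint log-likelihood for `"plugin"`) is non-decreasing;
#'   fitting aborts if it is not.
#' @return A list of class `"hier_control"`.
#' @export
hier_control <- function(tau_beta = 0.5, tau_g = 10, tol = 1e-6,
                         max_iter = 200, method = c("em", "plugin"),
                         beta_update = TRUE, debug = FALSE) {
  stopifnot(tau_beta > 0, tau_g > 0, tol > 0, max_iter >= 1)
  structure(list(tau_beta = tau_beta, tau_g = tau_g, tol = tol,
                 max_iter = max_iter, method = match.arg(method),
                 beta_update = isTRUE(beta_update), debug = isTRUE(debug)),
            class = "hier_control")
}

#' Build the grouped design for one gene
#'
#' Extracts the dosage columns of one gene from the genotype matrix and
#' partitions them into variant groups. In `"stratified"` mode the groups are
#' rare and common variants (an empty group is dropped, so a gene carrying
#' only rare variants yields a single-group design); in `"combined"` mode all
#' variants form one group irrespective of allele frequency.
#'
#' @param genotypes Numeric matrix of minor-allele dosages, individuals in
#'   rows, variants in columns (column names are variant ids).
#' @param gene_entry A list with character vectors `rare` and `common` of
#'   variant ids, as produced by [assign_variants_to_genes()].
#' @param mode `"stratified"` or `"combined"`.
#' @return A list of class `"grouped_design"` with elements `Z` (the n x J
#'   dosage matrix), `groups` (named list of column index vectors), and `J_k`
#'   (group sizes), or `NULL` if the gene has no polymorphic variants in the
#'   data (callers skip such genes).
#' @export
build_grouped_design <- function(genotypes, gene_entry,
                                 mode = c("stratified", "combined")) {
  mode <- match.arg(mode)
  rare <- intersect(gene_entry$rare, colnames(genotypes))
  common <- intersect(gene_entry$common, colnames(genotypes))
  ids <- c(rare, common)
  if (length(ids) == 0L) return(NULL)
  Z <- genotypes[, ids, drop = FALSE]
  if (mode == "combined") {
    groups <- list(all = seq_along(ids))
  } else {
    groups <- list(rare = seq_along(rare),
                   common = length(rare) + seq_along(common))
    groups <- groups[vapply(groups, length, 1L) > 0L]
  }
  structure(list(Z = Z, groups = groups,
                 J_k = vapply(groups, length, 1L), J = ncol(Z)),
            class = "grouped_design")
}

## map column index -> index of its group
.group_of <- function(groups, J) {
  k <- integer(J)
  for (i in seq_along(groups)) k[groups[[i]]] <- i
  k
}

## penalized joint log-likelihood at plug-in coefficient values
.obj_joint <- function(y, eta, beta, g, theta, ctrl) {
  n <- length(y)
  -n / 2 * log(2 * pi * theta) - sum((y - eta)^2) / (2 * theta) -
    sum((beta - 1)^2) / (2 * ctrl$tau_beta^2) -
    sum(g^2) / (2 * ctrl$tau_g^2)
}

## penalized marginal log-likelihood with the variant coefficients
## integrated out: y ~ N(beta0 + W 1, theta I + tau_beta^2 W W'),
## W = Z diag(g_k(j)); evaluated via the Woodbury identity (J-dim solve)
.obj_marginal <- function(y, beta0, g, theta, Z, kmap, ctrl) {
  n <- length(y)
  W <- Z * rep(g[kmap], each = n)
  r <- y - beta0 - rowSums(W)
  M <- crossprod(W) / theta + diag(1 / ctrl$tau_beta^2, ncol(Z))
  Minv_Wr <- solve(M, crossprod(W, r))
  quad <- (sum(r^2) - sum(crossprod(W, r) * Minv_Wr) / theta) / theta
  logdet <- determinant(M, logarithm = TRUE)$modulus +
    ncol(Z) * log(ctrl$tau_beta^2) + n * log(theta)
  -0.5 * (n * log(2 * pi) + as.numeric(logdet) + quad) -
    sum(g^2) / (2 * ctrl$tau_g^2)
}

#' Fit the hierarchical grouped-effect model for one gene
#'
#' Fits a Gaussian (identity link) regression in which the linear predictor
#' for individual i is
#' \deqn{\eta_i = \beta_0 + \sum_k g_k \sum_{j \in G_k} \beta_j z_{ij},}
#' where \eqn{z_{ij}} is the minor-allele dosage at variant j, the
#' \eqn{\beta_j} are variant-level coefficients shrunk toward 1, and the
#' \eqn{g_k} are multiplicative group effects (rare / common, or all
#' variants) shrunk toward 0. The gene-level association test is the Wald
#' test of \eqn{g_k = 0} for each group.
#'
#' Fitting is by a blockwise EM scheme built from iteratively reweighted
#' (penalized) least-squares steps: (i) given the variant coefficients,
#' regress the trait on the K collapsed scores
#' \eqn{s_{ik} = \sum_{j \in G_k} \beta_j z_{ij}} with the group prior acting
#' as a ridge penalty; (ii) given the group effects, update the variant
#' coefficients by ridge regression centered at 1 — algebraically this is
#' the posterior mean of the coefficients under their Normal(1, tau_beta^2)
#' prior; (iii) update the dispersion from the residuals. Under the default
#' `method = "em"` the coefficient posterior covariance from step (ii) also
#' enters steps (i) and (iii) and the standard errors, making the scheme the
#' exact EM algorithm for the marginal model in which the variant
#' coefficients are latent; the (penalized marginal) objective then increases
#' monotonically, and at the null the test reduces to a well-calibrated
#' burden regression. `method = "plugin"` drops the covariance terms and
#' conditions on the fitted coefficients throughout.
#'
#' @param design A `"grouped_design"` from [build_grouped_design()], or a
#'   bare dosage matrix (treated as one group).
#' @param y Numeric trait vector (one value per row of the design), e.g.
#'   treatment-adjusted systolic blood pressure at one exam.
#' @param control A [hier_control()] object.
#' @param init Optional named list overriding the default initialization
#'   (`beta0 = mean(y)`, `beta = 1`, `g = 0` — the burden special case).
#' @return An object of class `"hier_glm"`: a list with `beta0`, `beta`
#'   (posterior-mean variant coefficients), `g`, `se_g`, `z`, `p` (two-sided
#'   normal), `theta`, `eta`, `converged`, `n_iter`, `objective`, plus the
#'   design and control. Non-convergence is reported via `converged = FALSE`
#'   and a warning, never an error, so genome-wide scans do not abort.
#' @seealso [group_effect_test()], [scan_genes()]
#' @examples
#' set.seed(1)
#' Z <- matrix(rbinom(600, 2, 0.1), 100, 6,
#'             dimnames = list(NULL, paste0("v", 1:6)))
#' y <- rowSums(Z[, 1:3]) * 0.8 + rnorm(100)
#' d <- build_grouped_design(Z, list(rare = paste0("v", 1:3),
#'                                   common = paste0("v", 4:6)))
#' fit <- hier_glm(d, y)
#' summary(fit)
#' @export
hier_glm <- function(design, y, control = hier_control(), init = NULL) {
  if (is.matrix(design)) {
    design <- structure(list(Z = design,
                             groups = list(all = seq_len(ncol(design))),
                             J_k = ncol(design), J = ncol(design)),
                        class = "grouped_design")
  }
  stopifnot(inherits(design, "grouped_design"), inherits(control, "hier_control"))
  Z <- design$Z
  n <- nrow(Z); J <- ncol(Z); K <- length(design$groups)
  if (!is.numeric(y) || length(y) != n || any(!is.finite(y)))
    stop("'y' must be a finite numeric vector matching the design rows")
  if (J < 1L) stop("design has no variants")

  em <- control$method == "em" && control$beta_update
  beta0 <- if (!is.null(init$beta0)) init$beta0 else mean(y)
  beta <- if (!is.null(init$beta)) rep_len(as.numeric(init$beta), J) else rep(1, J)
  g <- if (!is.null(init$g)) rep_len(as.numeric(init$g), K) else rep(0, K)
  kmap <- .group_of(design$groups, J)
  theta <- max(mean((y - beta0)^2), 1e-12)

  lam_g <- 1 / control$tau_g^2
  lam_b <- 1 / control$tau_beta^2
  A_gram <- crossprod(Z)                 # cached Z'Z for the covariance traces
  Vpost <- NULL                          # posterior covariance of beta
  converged <- FALSE
  obj_prev <- -Inf
  it <- 0L

  g_step <- function(beta, Vpost, theta) {
    S <- vapply(design$groups,
                function(idx) as.numeric(Z[, idx, drop = FALSE] %*% beta[idx]),
                numeric(n))
    X <- cbind(1, S)
    A <- crossprod(X)
    pen <- diag(c(0, rep(theta * lam_g, K)), K + 1L)
    if (!is.null(Vpost)) {               # E[S'S] correction: C_kl = sum(V*Z'Z)
      C <- matrix(0, K, K)
      for (k in seq_len(K)) for (l in seq_len(K)) {
        ik <- design$groups[[k]]; il <- design$groups[[l]]
        C[k, l] <- sum(Vpost[ik, il] * A_gram[ik, il])
      }
      pen[-1L, -1L] <- pen[-1L, -1L] + C
    }
    cf <- solve(A + pen, crossprod(X, y))
    list(cf = cf, A = A, pen = pen, S = S)
  }

  for (it in seq_len(control$max_iter)) {
    old <- c(beta0, g, beta)

    ## (ii)/E-step: variant coefficients given g — ridge centered at 1,
    ## i.e. the posterior mean; posterior covariance kept when method="em"
    if (control$beta_update) {
      W <- Z * rep(g[kmap], each = n)
      M <- crossprod(W)
      diag(M) <- diag(M) + theta * lam_b
      Minv <- solve(M)
      beta <- as.numeric(Minv %*% (crossprod(W, y - beta0) + theta * lam_b))
      if (em) Vpost <- theta * Minv    # posterior covariance of beta
    }

    ## (i)/M-step: group effects by penalized regression on collapsed scores
    st <- g_step(beta, if (em) Vpost else NULL, theta)
    beta0 <- st$cf[1L]; g <- st$cf[-1L]

    ## (iii) dispersion
    eta <- as.numeric(beta0 + Z %*% (beta * g[kmap]))
    rss <- sum((y - eta)^2)
    if (em) {
      gk <- g[kmap]
      rss <- rss + sum(Vpost * (A_gram * tcrossprod(gk)))
    }
    theta <- max(rss / n, 1e-12)

    if (control$debug) {
      obj <- if (em)
        .obj_marginal(y, beta0, g, theta, Z, kmap, control)
      else
        .obj_joint(y, eta, beta, g, theta, control)
      if (obj < obj_prev - 1e-6)
        stop("fitting objective decreased at iteration ", it)
      obj_prev <- obj
    }
    if (max(abs(c(beta0, g, beta) - old)) < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("hier_glm did not converge in ", control$max_iter, " iterations")

  ## standard errors: for "em", from the observed information of the
  ## penalized marginal log-likelihood in (beta0, g, log theta) — the
  ## curvature at the mode accounts for coefficient uncertainty and for the
  ## dependence of the marginal covariance on g; for "plugin" (or frozen
  ## coefficients), from the information of the group-effect step at the
  ## fitted values
  se_g <- NULL
  if (em) {
    par <- c(beta0, g, log(theta))
    negll <- function(p) -.obj_marginal(y, p[1L], p[2:(K + 1L)],
                                        exp(p[K + 2L]), Z, kmap, control)
    se_g <- tryCatch({
      H <- stats::optimHess(par, negll)
      cv <- solve(H)
      sg <- sqrt(diag(cv)[2:(K + 1L)])
      if (all(is.finite(sg)) && all(sg > 0)) sg else NULL
    }, error = function(e) NULL)
  }
  if (is.null(se_g)) {
    st <- g_step(beta, if (em) Vpost else NULL, theta)
    cov_g <- theta * solve(st$A + st$pen)
    se_g <- sqrt(pmax(diag(cov_g)[-1L], 0))
  }
  z <- ifelse(se_g > 0, g / se_g, NA_real_)
  p <- ifelse(is.na(z), NA_real_, 2 * stats::pnorm(-abs(z)))
  eta <- as.numeric(beta0 + Z %*% (beta * g[kmap]))

  objective <- if (em)
    .obj_marginal(y, beta0, g, theta, Z, kmap, control)
  else
    .obj_joint(y, eta, beta, g, theta, control)

  structure(list(
    beta0 = unname(beta0),
    beta = stats::setNames(beta, colnames(Z)),
    g = stats::setNames(as.numeric(g), names(design$groups)),
    se_g = stats::setNames(se_g, names(design$groups)),
    z = stats::setNames(z, names(design$groups)),
    p = stats::setNames(p, names(design$groups)),
    theta = theta,
    eta = eta,
    residuals = y - eta,
    y = y,
    converged = converged,
    n_iter = it,
    objective = objective,
    design = design,
    control = control
  ), class = "hier_glm")
}

#' Wald tests of the group effects
#'
#' Returns, for each variant group of a fitted model, the Wald statistic
#' z = g / se and its two-sided normal p value for the null hypothesis that
#' the group effect is zero. A zero standard error yields a missing p value
#' with a warning.
#'
#' @param fit A fitted `"hier_glm"` object.
#' @return A data frame with columns `group`, `estimate`, `se`, `z`, `p`.
#' @export
group_effect_test <- function(fit) {
  stopifnot(inherits(fit, "hier_glm"))
  if (any(fit$se_g == 0, na.rm = TRUE))
    warning("zero standard error: p value undefined for some group(s)")
  data.frame(group = names(fit$g),
             estimate = as.numeric(fit$g),
             se = as.numeric(fit$se_g),
             z = as.numeric(fit$z),
             p = as.numeric(fit$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.hier_glm <- function(x, digits = 4, ...) {
  cat("Hierarchical grouped-effect model (gaussian, identity link)\n")
  cat(sprintf("  n = %d individuals, J = %d variants in %d group(s); method = %s\n",
              length(x$eta), length(x$beta), length(x$g), x$control$method))
  cat(sprintf("  dispersion theta = %.*g, %sconverged in %d iterations\n",
              digits, x$theta, if (x$converged) "" else "NOT ", x$n_iter))
  print(round(cbind(estimate = x$g, se = x$se_g, z = x$z, p = x$p), digits))
  invisible(x)
}

#' @export
summary.hier_glm <- function(object, ...) {
  out <- list(groups = group_effect_test(object),
              beta0 = object$beta0,
              beta = object$beta,
              theta = object$theta,
              converged = object$converged,
              n_iter = object$n_iter,
              objective = object$objective)
  class(out) <- "summary.hier_glm"
  out
}

#' @export
print.summary.hier_glm <- function(x, digits = 4, ...) {
  cat("Group effects (Wald tests of g_k = 0):\n")
  print(format(x$groups, digits = digits), row.names = FALSE)
  cat(sprintf("\nIntercept %.4g; dispersion %.4g; objective %.6g\n",
              x$beta0, x$theta, x$objective))
  cat(sprintf("Variant coefficients (prior center 1): min %.3g, median %.3g, max %.3g\n",
              min(x$beta), stats::median(x$beta), max(x$beta)))
  if (!x$converged) cat("Warning: fit did not converge\n")
  invisible(x)
}

#' @export
coef.hier_glm <- function(object, ...) {
  c(`(Intercept)` = object$beta0,
    stats::setNames(object$g, paste0("g.", names(object$g))),
    stats::setNames(object$beta, paste0("beta.", names(object$beta))))
}

#' @export
residuals.hier_glm <- function(object, ...) object$residuals

#' Predict from a fitted hierarchical grouped-effect model
#'
#' @param object A `"hier_glm"` fit.
#' @param newdata Optional dosage matrix with the same variant columns as the
#'   training design; the fitted linear predictor is returned when omitted.
#' @param ... Unused.
#' @export
predict.hier_glm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$eta)
  Z <- as.matrix(newdata)
  if (ncol(Z) != length(object$beta))
    stop("newdata must have ", length(object$beta), " variant columns")
  kmap <- .group_of(object$design$groups, ncol(Z))
  as.numeric(object$beta0 + Z %*% (object$beta * object$g[kmap]))
}

#' Simulate traits from a fitted model
#'
#' Draws Gaussian responses around the fitted linear predictor using the
#' estimated dispersion, in the style of [stats::simulate()].
#'
#' @param object A `"hier_glm"` fit.
#' @param nsim Number of simulated trait vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @export
simulate.hier_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$eta)
  out <- as.data.frame(replicate(nsim, object$eta + stats::rnorm(n, 0, sqrt(object$theta))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
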