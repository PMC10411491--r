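#' Phylogenetic variance-covariance matrix
#'
#' `V[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j; `V[i, i]` is the root-to-tip distance.
#' This is the Brownian-motion covariance structure (up to the rate).
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::vcv(tree)
}

align_tip_values <- function(x, tree) {
  n <- ape::Ntip(tree)
  if (!is.null(names(x))) {
    if (!all(tree$tip.label %in% names(x)))
      stop("tip values must be named by tree tip labels")
    x <- x[tree$tip.label]
  } else if (length(x) != n) {
    stop("need one value per tip")
  }
  as.numeric(x)
}

# Gaussian log-likelihood with mean mu*1 and covariance V, profiling the
# ML rate: V is a *shape* matrix, the fitted covariance is sigma2 * V.
gls_profile <- function(x, V) {
  n <- length(x)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  one <- rep(1, n)
  Vi_x <- backsolve(L, forwardsolve(t(L), x))
  Vi_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Vi_x) / sum(Vi_1)
  r <- x - mu
  Vi_r <- backsolve(L, forwardsolve(t(L), r))
  rss <- sum(r * Vi_r)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  logLik <- if (sigma2 <= 0) Inf else
    -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  list(mu = mu, sigma2 = sigma2, logLik = logLik, logdetV = logdetV, L = L)
}

new_trait_fit <- function(model, sigma2, z0, logLik, k, ou_alpha = NA_real_,
                          theta = NA_real_, converged = TRUE,
                          degenerate = FALSE) {
  structure(list(model = model, sigma2 = sigma2, ou_alpha = ou_alpha,
                 theta = theta, z0 = z0, logLik = logLik, k = k,
                 AICc = NA_real_, weight = NA_real_,
                 converged = converged, degenerate = degenerate),
            class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(x$model, "fit: sigma2 =", signif(x$sigma2, 5),
      if (x$model == "OU") paste("alpha =", signif(x$ou_alpha, 5),
                                 "theta =", signif(x$theta, 5)),
      " z0 =", signif(x$z0, 5), " logLik =", signif(x$logLik, 7), "\n")
  if (!is.na(x$AICc)) cat(" AICc =", signif(x$AICc, 7),
                          " weight =", signif(x$weight, 4), "\n")
  invisible(x)
}

#' Maximum-likelihood Brownian-motion fit for one trait on a tree
#'
#' The trait is multivariate normal with mean `z0 * 1` and covariance
#' `sigma2 * phylo_vcv(tree)` (optionally plus a known measurement-error
#' variance on the diagonal). With `error_var = 0` the estimates are the
#' closed-form GLS solutions (ML, denominator n). Parameter count k = 2.
#'
#' @param x tip values (named by tip label, or in tip order).
#' @param tree a `phylo` tree (>= 3 tips).
#' @param error_var known measurement-error variance added to the diagonal
#'   of the covariance (0 = error not modeled).
#' @return A `trait_model_fit`.
#' @export
fit_bm <- function(x, tree, error_var = 0) {
  x <- align_tip_values(x, tree)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  V <- phylo_vcv(tree)
  if (var(x) == 0)
    return(new_trait_fit("BM", 0, x[1], Inf, 2, degenerate = TRUE))
  if (error_var == 0) {
    g <- gls_profile(x, V)
    return(new_trait_fit("BM", g$sigma2, g$mu, g$logLik, 2))
  }
  # with a fixed error term sigma2 no longer profiles out: optimize it
  nll <- function(ls2) {
    W <- exp(ls2) * V + diag(error_var, n)
    g <- gls_profile(x, W)
    if (is.null(g)) return(1e10)
    # here W is the full covariance: likelihood with sigma2 fixed at 1
    r <- x - g$mu
    Vi_r <- backsolve(g$L, forwardsolve(t(g$L), r))
    0.5 * (n * log(2 * pi) + g$logdetV + sum(r * Vi_r))
  }
  g0 <- gls_profile(x, V)
  opt <- optimize(nll, log(g0$sigma2) + c(-8, 8))
  s2 <- exp(opt$minimum)
  W <- s2 * V + diag(error_var, n)
  g <- gls_profile(x, W)
  r <- x - g$mu
  Vi_r <- backsolve(g$L, forwardsolve(t(g$L), r))
  ll <- -0.5 * (n * log(2 * pi) + g$logdetV + sum(r * Vi_r))
  new_trait_fit("BM", s2, g$mu, ll, 2)
}

# OU covariance shape for unit sigma2, fixed root at theta:
# V[i,j] = exp(-a d_ij) * (1 - exp(-2 a t_ij)) / (2 a)
ou_shape <- function(a, Vbm, tipvar) {
  dij <- outer(tipvar, tipvar, "+") - 2 * Vbm  # patristic distances
  exp(-a * dij) * (-expm1(-2 * a * Vbm)) / (2 * a)
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit for one trait on a tree
#'
#' Fits the fixed-root OU model (root state equal to the optimum theta):
#' covariance `sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha
#' t_ij))` with `d_ij` the patristic distance and `t_ij` the shared time
#' from the root, mean `theta * 1`. The attraction strength alpha is
#' optimized on a log grid over `alpha * height` in `[1e-8, 50]` with local
#' refinement; theta and sigma2 are profiled in closed form at each alpha.
#' Ties are broken toward smaller alpha, and as `alpha -> 0` the likelihood
#' converges to the BM likelihood. Parameter count k = 3.
#'
#' @inheritParams fit_bm
#' @param alpha_fixed optionally fix alpha instead of optimizing.
#' @return A `trait_model_fit` with fields `ou_alpha`, `theta`.
#' @export
fit_ou <- function(x, tree, error_var = 0, alpha_fixed = NULL) {
  x <- align_tip_values(x, tree)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips")
  Vbm <- phylo_vcv(tree)
  tipvar <- diag(Vbm)
  H <- max(tipvar)
  if (var(x) == 0)
    return(new_trait_fit("OU", 0, x[1], Inf, 3, degenerate = TRUE))

  prof <- function(a) {
    if (error_var == 0) {
      g <- gls_profile(x, ou_shape(a, Vbm, tipvar))
      if (is.null(g)) return(list(logLik = -Inf))
      list(logLik = g$logLik, sigma2 = g$sigma2, theta = g$mu)
    } else {
      W0 <- ou_shape(a, Vbm, tipvar)
      nll <- function(ls2) {
        W <- exp(ls2) * W0 + diag(error_var, n)
        g <- gls_profile(x, W)
        if (is.null(g)) return(1e10)
        r <- x - g$mu
        Vi_r <- backsolve(g$L, forwardsolve(t(g$L), r))
        0.5 * (n * log(2 * pi) + g$logdetV + sum(r * Vi_r))
      }
      s2_start <- max(gls_profile(x, Vbm)$sigma2, 1e-12)
      opt <- optimize(nll, log(s2_start) + c(-10, 10))
      s2 <- exp(opt$minimum)
      W <- s2 * W0 + diag(error_var, n)
      g <- gls_profile(x, W)
      r <- x - g$mu
      Vi_r <- backsolve(g$L, forwardsolve(t(g$L), r))
      list(logLik = -0.5 * (n * log(2 * pi) + g$logdetV + sum(r * Vi_r)),
           sigma2 = s2, theta = g$mu)
    }
  }

  if (!is.null(alpha_fixed)) {
    p <- prof(alpha_fixed)
    return(new_trait_fit("OU", p$sigma2, p$theta, p$logLik, 3,
                         ou_alpha = alpha_fixed, theta = p$theta))
  }

  la_grid <- log(seq_grid <- exp(seq(log(1e-8 / H), log(50 / H), length.out = 40)))
  ll_grid <- vapply(seq_grid, function(a) prof(a)$logLik, 0)
  if (all(!is.finite(ll_grid)))
    return(new_trait_fit("OU", NA_real_, NA_real_, -Inf, 3, converged = FALSE))
  best <- which(ll_grid >= max(ll_grid, na.rm = TRUE) - 1e-10)[1]  # ties -> smaller alpha
  lo <- la_grid[max(1, best - 1)]
  hi <- la_grid[min(length(la_grid), best + 1)]
  opt <- optimize(function(la) -prof(exp(la))$logLik, c(lo, hi), tol = 1e-8)
  a_grid_best <- seq_grid[best]
  a_ref <- exp(opt$minimum)
  # keep whichever is better; prefer the smaller alpha on near-ties
  cand <- c(a_grid_best, a_ref)
  lls <- c(ll_grid[best], -opt$objective)
  pick <- if (abs(diff(lls)) < 1e-8) which.min(cand) else which.max(lls)
  a_hat <- cand[pick]
  p <- prof(a_hat)
  new_trait_fit("OU", p$sigma2, p$theta, p$logLik, 3,
                ou_alpha = a_hat, theta = p$theta,
                converged = is.finite(p$logLik))
}

#' AICc comparison of trait-model fits
#'
#' `AICc = -2 logLik + 2 k + 2 k (k + 1) / (n - k - 1)`; Akaike weights are
#' `exp(-dAICc/2)` normalized to sum to one across the comparison set.
#'
#' @param fits list of `trait_model_fit` objects fitted to the same data.
#' @param n number of tips (sample size).
#' @return The list of fits with `AICc` and `weight` filled in; the summary
#'   table is attached as attribute `"table"`.
#' @export
aicc_compare <- function(fits, n) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "trait_model_fit")))
  k <- vapply(fits, `[[`, 0, "k")
  if (any(n <= k + 1))
    stop("AICc undefined: n must exceed k + 1 for every model")
  ll <- vapply(fits, `[[`, 0, "logLik")
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) {
    fits[[i]]$AICc <- aicc[i]
    fits[[i]]$weight <- w[i]
  }
  attr(fits, "table") <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    sigma2 = vapply(fits, `[[`, 0, "sigma2"),
    ou_alpha = vapply(fits, `[[`, 0, "ou_alpha"),
    theta = vapply(fits, `[[`, 0, "theta"),
    logLik = ll, k = k, AICc = aicc, weight = w)
  fits
}

# GLS residuals whitened by the BM tree covariance: returns, for each
# trait, t(L)^-1 (x - mu_hat) with V = t(L) L, so cross products estimate
# the evolutionary rate (co)variances.
whitened_residuals <- function(x, y, tree) {
  V <- phylo_vcv(tree)
  L <- chol(V)
  one <- rep(1, length(x))
  w1 <- forwardsolve(t(L), one)
  gls_mean <- function(v) {
    wv <- forwardsolve(t(L), v)
    sum(w1 * wv) / sum(w1 * w1)
  }
  list(cx = forwardsolve(t(L), x - gls_mean(x)),
       cy = forwardsolve(t(L), y - gls_mean(y)))
}

#' Evolutionary correlation between two traits on a tree
#'
#' The correlation of the maximum-likelihood bivariate Brownian rate
#' matrix, computed by generalized least squares with the tree covariance
#' (equivalently, for binary trees, the correlation of phylogenetically
#' independent contrasts through the origin). On a star phylogeny this
#' reduces to the ordinary Pearson correlation of the tip values.
#'
#' @param x,y tip values (named by tip label, or in tip order).
#' @param tree a `phylo` tree (>= 3 tips).
#' @return The correlation, or `NA` (with a warning) for a zero-variance
#'   trait.
#' @export
evolutionary_correlation <- function(x, y, tree) {
  x <- align_tip_values(x, tree)
  y <- align_tip_values(y, tree)
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero-variance trait: evolutionary correlation undefined")
    return(NA_real_)
  }
  w <- whitened_residuals(x, y, tree)
  sum(w$cx * w$cy) / sqrt(sum(w$cx^2) * sum(w$cy^2))
}

#' Ordinary and phylogenetic regression of one trait on another across tips
#'
#' Reports both slope variants side by side: the ordinary least-squares
#' slope of y on x across tip values (which ignores the tips' shared
#' history) and the phylogenetic (GLS / independent-contrasts) regression
#' slope, together with the evolutionary correlation. On non-star trees
#' the two slopes differ because tip values are phylogenetically
#' correlated.
#'
#' @param x,y tip values (named by tip label, or in tip order).
#' @param tree a `phylo` tree (>= 3 tips).
#' @return List with `slope_ols`, `slope_phylo`, `r_evolutionary`, `n`.
#' @export
phylo_regression <- function(x, y, tree) {
  x <- align_tip_values(x, tree)
  y <- align_tip_values(y, tree)
  w <- whitened_residuals(x, y, tree)
  list(slope_ols = unname(coef(lm(y ~ x))[2]),
       slope_phylo = sum(w$cx * w$cy) / sum(w$cx^2),
       r_evolutionary = sum(w$cx * w$cy) / sqrt(sum(w$cx^2) * sum(w$cy^2)),
       n = length(x))
}

#' Pairwise divergence versus divergence time across replicate simulations
#'
#' For every pair of tips and every trait, the mean over replicate
#' simulations of the absolute phenotypic difference between the two tips,
#' keyed by the pair's divergence time (twice the time since their most
#' recent common ancestor).
#'
#' @param tip_tables list of `tree_tips` tables from repeated
#'   [evolve_along_tree()] runs on the same tree.
#' @param tree the tree the simulations ran on.
#' @param traits trait columns to summarize.
#' @param gene gene index to summarize.
#' @return A data.frame with columns `tip_i`, `tip_j`, `divergence_time`,
#'   `trait`, `mean_abs_divergence`.
#' @export
divergence_vs_time <- function(tip_tables, tree,
                               traits = c("ln_R", "ln_beta", "ln_P"),
                               gene = 1) {
  stopifnot(length(tip_tables) >= 1, inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  H <- tree_height(tree)
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  mats <- lapply(tip_tables, function(tt) {
    tt <- as.data.frame(tt)
    tt <- tt[tt$gene == gene, ]
    m <- as.matrix(tt[, traits, drop = FALSE])
    rownames(m) <- tt$tip
    m[tree$tip.label, , drop = FALSE]
  })
  pairs <- which(upper.tri(matrix(0, ntip, ntip)), arr.ind = TRUE)
  out <- lapply(traits, function(tr) {
    vals <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      mean(vapply(mats, function(m) abs(m[i, tr] - m[j, tr]), 0))
    }, 0)
    data.frame(tip_i = tree$tip.label[pairs[, 1]],
               tip_j = tree$tip.label[pairs[, 2]],
               divergence_time = 2 * (H - depth[mrca[cbind(pairs[, 1], pairs[, 2])]]),
               trait = tr, mean_abs_divergence = vals)
  })
  do.call(rbind, out)
}
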