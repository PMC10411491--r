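# Phylogenetic covariance, BM/OU likelihood fits, AICc weights,
# evolutionary correlations, and divergence tables.

# draw one multivariate-normal trait with covariance S and mean mu
rmvn <- function(S, mu = 0) mu + drop(crossprod(chol(S), rnorm(nrow(S))))

test_that("phylo_vcv reads off shared path lengths", {
  two <- ape::read.tree(text = "(a:3,b:3);")
  expect_equal(unname(phylo_vcv(two)), diag(c(3, 3)))
  V <- phylo_vcv(small_tree())  # ((a:1,b:1):1,c:2)
  expect_equal(V["a", "b"], 1)
  expect_equal(V["a", "c"], 0)
  expect_equal(V["a", "a"], 2)
  star <- pagel_lambda_transform(rescale_height(simulate_yule(8, seed = 1), 1),
                                 0)
  expect_true(all(phylo_vcv(star)[upper.tri(diag(8))] == 0))
})

test_that("BM fit on a star tree is the iid normal MLE", {
  star <- ape::stree(40, type = "star")
  star$edge.length <- rep(1, 40)
  set.seed(11)
  x <- rnorm(40)
  fit <- fit_bm(setNames(x, star$tip.label), star)
  expect_equal(fit$sigma2, mean((x - mean(x))^2), tolerance = 1e-8)
  expect_equal(fit$z0, mean(x), tolerance = 1e-8)
  expect_equal(fit$logLik,
               sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE)),
               tolerance = 1e-8)
})

test_that("BM fit is scale-equivariant", {
  tree <- rescale_height(simulate_yule(20, seed = 12), 1)
  set.seed(13)
  x <- rmvn(0.5 * phylo_vcv(tree), mu = 1)
  f1 <- fit_bm(setNames(x, tree$tip.label), tree)
  f2 <- fit_bm(setNames(2 * x, tree$tip.label), tree)
  expect_equal(f2$sigma2, 4 * f1$sigma2, tolerance = 1e-8)
  expect_equal(f2$logLik, f1$logLik - 20 * log(2), tolerance = 1e-8)
})

test_that("BM rate is recovered from simulated data on the fixture tree", {
  tree <- fixture_tree()
  V <- phylo_vcv(tree)
  set.seed(14)
  est <- vapply(1:200, function(i) {
    x <- rmvn(0.01 * V)
    fit_bm(setNames(x, tree$tip.label), tree)$sigma2
  }, 0)
  expect_lt(abs(mean(est) / 0.01 - 1), 0.1)
})

test_that("OU likelihood nests BM in the alpha -> 0 limit", {
  tree <- rescale_height(simulate_yule(15, seed = 15), 1)
  set.seed(16)
  x <- rmvn(0.3 * phylo_vcv(tree))
  x <- setNames(x, tree$tip.label)
  bm <- fit_bm(x, tree)
  ou0 <- fit_ou(x, tree, alpha_fixed = 1e-12)
  expect_equal(ou0$logLik, bm$logLik, tolerance = 1e-4)
})

test_that("OU attraction strength is recovered within a factor of two", {
  tree <- fixture_tree()
  H <- tree_height(tree)
  a_true <- 5 / H
  V <- phylo_vcv(tree)
  tipvar <- diag(V)
  dij <- outer(tipvar, tipvar, "+") - 2 * V
  Sou <- 0.01 / (2 * a_true) * exp(-a_true * dij) * (1 - exp(-2 * a_true * V))
  set.seed(17)
  a_hat <- vapply(1:100, function(i) {
    x <- rmvn(Sou)
    fit_ou(setNames(x, tree$tip.label), tree)$ou_alpha
  }, 0)
  expect_lt(abs(log(median(a_hat) / a_true)), log(2))
})

test_that("in the stationary limit the OU optimum tracks the sample mean", {
  tree <- fixture_tree()
  H <- tree_height(tree)
  a <- 20 / H  # alpha * height >> 1: tips are nearly iid N(theta, s2/2a)
  s2 <- 0.02 * a  # stationary variance s2/(2a) = 0.01
  V <- phylo_vcv(tree)
  dij <- outer(diag(V), diag(V), "+") - 2 * V
  Sou <- s2 / (2 * a) * exp(-a * dij) * (1 - exp(-2 * a * V))
  set.seed(18)
  x <- rmvn(Sou, mu = 3)
  fit <- fit_ou(setNames(x, tree$tip.label), tree)
  expect_equal(fit$theta, mean(x), tolerance = 0.02)
})

test_that("OU never fits worse than BM (nested model property)", {
  tree <- fixture_tree()
  set.seed(19)
  for (i in 1:10) {
    x <- rmvn(0.01 * phylo_vcv(tree))
    x <- setNames(x, tree$tip.label)
    expect_gte(fit_ou(x, tree)$logLik, fit_bm(x, tree)$logLik - 1e-4)
  }
})

test_that("AICc formula and weights match worked examples", {
  f <- function(ll, k) structure(
    list(model = "BM", sigma2 = 1, ou_alpha = NA_real_, theta = NA_real_,
         z0 = 0, logLik = ll, k = k, AICc = NA_real_, weight = NA_real_),
    class = "trait_model_fit")
  out <- aicc_compare(list(f(0, 1)), n = 10)
  expect_equal(out[[1]]$AICc, 2.5)  # 0 + 2 + 4/8

  out <- aicc_compare(list(f(-5, 2), f(-5, 2)), n = 20)
  expect_equal(vapply(out, `[[`, 0, "weight"), c(0.5, 0.5))

  # delta AICc of 2 (same k, logLik difference 1)
  out <- aicc_compare(list(f(-4, 2), f(-5, 2)), n = 20)
  expect_equal(vapply(out, `[[`, 0, "weight"),
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-6)

  # invariance to a constant shift in logLik
  out2 <- aicc_compare(list(f(96, 2), f(95, 2)), n = 20)
  expect_equal(vapply(out2, `[[`, 0, "weight"),
               vapply(out, `[[`, 0, "weight"))

  expect_error(aicc_compare(list(f(0, 3)), n = 4), "AICc undefined")
})

test_that("evolutionary correlation reduces to Pearson on a star tree", {
  star <- ape::stree(30, type = "star")
  star$edge.length <- rep(1, 30)
  set.seed(20)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  names(x) <- names(y) <- star$tip.label
  expect_equal(evolutionary_correlation(x, y, star), cor(x, y),
               tolerance = 1e-10)
  expect_equal(evolutionary_correlation(x, -x, star), -1, tolerance = 1e-10)
})

test_that("evolutionary correlation is affine-invariant up to sign", {
  tree <- rescale_height(simulate_yule(20, seed = 21), 1)
  set.seed(22)
  x <- setNames(rmvn(phylo_vcv(tree)), tree$tip.label)
  y <- setNames(rmvn(phylo_vcv(tree)) + 0.5 * x, tree$tip.label)
  r <- evolutionary_correlation(x, y, tree)
  expect_equal(evolutionary_correlation(3 * x + 7, y, tree), r)
  expect_equal(evolutionary_correlation(-2 * x, y, tree), -r)
  expect_warning(ans <- evolutionary_correlation(x * 0, y, tree),
                 "zero-variance")
  expect_true(is.na(ans))
})

test_that("phylogenetic and ordinary regression slopes are both reported", {
  tree <- rescale_height(simulate_yule(25, seed = 23), 1)
  set.seed(24)
  x <- setNames(rmvn(phylo_vcv(tree)), tree$tip.label)
  y <- setNames(-0.8 * x + 0.1 * rmvn(phylo_vcv(tree)), tree$tip.label)
  pr <- phylo_regression(x, y, tree)
  expect_equal(pr$slope_ols, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  px <- ape::pic(x, tree)
  py <- ape::pic(y, tree)
  expect_equal(pr$slope_phylo, sum(px * py) / sum(px^2), tolerance = 1e-10)
  expect_lt(abs(pr$slope_phylo + 0.8), 0.1)
})

test_that("divergence table keys pairs by twice the time to the MRCA", {
  tree <- small_tree()  # ((a:1,b:1):1,c:2)
  tt <- data.frame(tip = c("a", "b", "c"), gene = 1,
                   ln_alpha = c(0, 1, 3), ln_beta = 0,
                   ln_R = c(0, 1, 3), ln_P = c(0, 1, 3))
  dv <- divergence_vs_time(list(tt), tree, traits = "ln_R")
  ab <- dv[dv$tip_i == "a" & dv$tip_j == "b", ]
  ac <- dv[dv$tip_i == "a" & dv$tip_j == "c", ]
  expect_equal(ab$divergence_time, 2)
  expect_equal(ac$divergence_time, 4)
  expect_equal(ab$mean_abs_divergence, 1)
  expect_equal(ac$mean_abs_divergence, 3)
  # averaging across replicate tables
  tt2 <- tt
  tt2$ln_R <- c(0, 3, 3)
  dv2 <- divergence_vs_time(list(tt, tt2), tree, traits = "ln_R")
  expect_equal(dv2[dv2$tip_i == "a" & dv2$tip_j == "b",
                   "mean_abs_divergence"], 2)
})

test_that("neutral divergence grows like the half-normal mean of a walk", {
  # E|x_i - x_j| = sqrt(2 v t / pi) for a neutral walk with variance rate v
  tree <- ape::read.tree(text = "((a:1000,b:1000):1000,c:2000);")
  cfg <- default_cfg("neutral")
  reps <- lapply(1:150, function(i) evolve_along_tree(tree, cfg, seed = 9000 + i))
  dv <- divergence_vs_time(reps, tree, traits = "ln_alpha")
  v <- 5e-4 * 0.01  # U_alpha * sigma_alpha^2 per time step
  expected <- sqrt(2 * v * dv$divergence_time / pi)
  expect_equal(dv$mean_abs_divergence, expected, tolerance = 0.2)
})
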