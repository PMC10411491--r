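# Mutation process, fitness functions, fixation probability, and the
# sequential-fixation engine.

test_that("expected mutation count is 2 Ne sum(U)", {
  expect_equal(expected_mutation_count(1000, mutation_params()), 2)
  expect_equal(expected_mutation_count(500, mutation_params()), 1)
  expect_error(mutation_params(U_alpha = 0, U_beta = 0), "total mutation rate")
  expect_error(mutation_params(sigma_alpha = 0), "SD")
  expect_error(mutation_params(U_alpha = -1e-4), "non-negative")
})

test_that("mutation draws hit traits in proportion to their rates", {
  mut <- mutation_params(U_alpha = 1e-3, U_beta = 0.0)
  set.seed(1)
  d <- draw_mutation(mut, 1000)
  expect_true(all(d$trait == "transcription"))

  mut <- mutation_params()
  set.seed(2)
  d <- draw_mutation(mut, 1e5)
  frac <- mean(d$trait == "transcription")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
  # effect SD within 2% (chi-square bound at this n)
  expect_lt(abs(sd(d$effect) / 0.1 - 1), 0.02)
})

test_that("Gaussian fitness matches its closed form", {
  net1 <- regulatory_network(gene_params(ln_optimum = 0, sigma_omega = 1))
  at <- function(lnP, net) structure(list(ln_R = lnP, ln_P = lnP),
                                     class = "expression_state")
  expect_equal(gaussian_fitness(at(0, net1), net1), 1)
  expect_equal(gaussian_fitness(at(1, net1), net1), exp(-0.5),
               tolerance = 1e-6)
  # two selected genes each one sigma from optimum -> product of terms
  net2 <- regulatory_network(list(
    gene_params(ln_optimum = 0, sigma_omega = 1),
    gene_params(ln_optimum = 0, sigma_omega = 1)))
  st <- structure(list(ln_R = c(1, 1), ln_P = c(1, 1)),
                  class = "expression_state")
  expect_equal(gaussian_fitness(st, net2), exp(-1), tolerance = 1e-6)
  # unselected genes contribute nothing
  net3 <- regulatory_network(list(
    gene_params(ln_optimum = 0, sigma_omega = 1), gene_params()))
  expect_equal(gaussian_fitness(st, net3), exp(-0.5), tolerance = 1e-6)
})

test_that("equivalent-gene fitness acts on the summed protein level", {
  expect_equal(equivalent_fitness(log(2), log(3), log(5), 1), 1)
  expect_equal(equivalent_fitness(0, 0, log(2), 1), 1)
  expect_equal(equivalent_fitness(0, 0, 0, 1), exp(-log(2)^2 / 2),
               tolerance = 1e-6)
})

test_that("fixation probability has the neutral limit and stable tails", {
  expect_equal(fixation_probability(0, 1000), 5e-4)
  expect_equal(fixation_probability(1e-12, 1000), 5e-4, tolerance = 1e-6)
  expect_equal(fixation_probability(0.001, 1000),
               (1 - exp(-0.002)) / (1 - exp(-4)), tolerance = 1e-10)
  expect_equal(fixation_probability(-0.01, 1000), 8.6e-20,
               tolerance = 0.01)
  # no overflow for strongly deleterious mutations
  expect_identical(fixation_probability(-5, 1000), 0)
  expect_identical(fixation_probability(-1e6, 10), 0)
  # monotone increasing in s
  s <- seq(-0.05, 0.05, by = 0.001)
  expect_true(all(diff(fixation_probability(s, 1000)) >= 0))
  expect_true(all(fixation_probability(s, 1000) >= 0 &
                  fixation_probability(s, 1000) <= 1))
})

test_that("ensembles are deterministic given a base seed", {
  cfg <- default_cfg("stabilizing", T = 2000)
  e1 <- evolve_replicates(cfg, 2, base_seed = 5)
  e2 <- evolve_replicates(cfg, 2, base_seed = 5)
  expect_identical(e1$endpoints, e2$endpoints)
  expect_identical(e1$trajectories[[2]]$ln_alpha, e2$trajectories[[2]]$ln_alpha)
  e3 <- evolve_replicates(cfg, 2, base_seed = 6)
  expect_false(identical(e1$endpoints, e3$endpoints))
})

test_that("a one-step run records only the boundary states", {
  cfg <- default_cfg("stabilizing", T = 1)
  tr <- evolve_lineage(cfg, seed = 3)
  expect_equal(tr$times, c(0, 1))
  expect_true(tr$n_proposed >= 0)
  expect_true(sum(tr$n_fixed_alpha) + sum(tr$n_fixed_beta) <= tr$n_proposed)
})

test_that("recorded phenotypes equal the steady state of recorded genotypes", {
  C <- matrix(0, 2, 2)
  C[1, 2] <- 0.4
  C[2, 1] <- -0.3
  net <- regulatory_network(list(
    gene_params(ln_optimum = 0, sigma_omega = 1), gene_params()), C)
  cfg <- evolution_config(net, mutation_params(n_genes = 2), Ne = 1000,
                          T = 5000, regime = "stabilizing",
                          record_every = 500)
  tr <- evolve_lineage(cfg, seed = 8)
  for (k in seq_along(tr$times)) {
    net_k <- net
    for (g in 1:2) {
      net_k$genes[[g]]$ln_alpha <- tr$ln_alpha[k, g]
      net_k$genes[[g]]$ln_beta <- tr$ln_beta[k, g]
    }
    st <- steady_state(net_k)
    expect_equal(unname(tr$ln_R[k, ]), st$ln_R, tolerance = 1e-10)
    expect_equal(unname(tr$ln_P[k, ]), st$ln_P, tolerance = 1e-10)
  }
})

test_that("vanishing selection reduces the engine to the neutral engine", {
  # with an essentially flat fitness function every s ~ 0, so the selected
  # engine must reproduce the neutral run draw for draw (this also checks
  # that acceptance uses the continuously-updated ancestral fitness)
  cfg_n <- default_cfg("neutral", T = 2e4)
  cfg_s <- default_cfg("stabilizing", sigma_omega = 1e9, T = 2e4)
  tr_n <- evolve_lineage(cfg_n, seed = 99)
  tr_s <- evolve_lineage(cfg_s, seed = 99)
  expect_equal(tr_n$end$ln_alpha, tr_s$end$ln_alpha)
  expect_equal(tr_n$end$ln_beta, tr_s$end$ln_beta)
  expect_equal(tr_n$n_proposed, tr_s$n_proposed)
})

test_that("neutral fixation counts match the origin-fixation rate U*T", {
  # neutral substitution rate = mutation rate: expect ~ U*T = 50 per trait
  tr <- fixture("neutral_lineage", function()
    evolve_lineage(default_cfg("neutral"), seed = 17))
  bounds <- qpois(c(0.005, 0.995), 50)
  expect_gte(tr$n_fixed_alpha, bounds[1])
  expect_lte(tr$n_fixed_alpha, bounds[2])
  expect_gte(tr$n_fixed_beta, bounds[1])
  expect_lte(tr$n_fixed_beta, bounds[2])
})

test_that("equivalent-gene regime keeps the summed protein at its optimum", {
  net <- regulatory_network(list(gene_params(), gene_params()))
  cfg <- evolution_config(net, mutation_params(n_genes = 2), Ne = 1000,
                          T = 2e4, regime = "equivalent")
  # default optimum: summed protein of the all-zero start, ln 2
  expect_equal(cfg$equivalent_optimum, log(2))
  ens <- evolve_replicates(cfg, 30, base_seed = 31,
                           keep_trajectories = FALSE)
  wide <- reshape(ens$endpoints[, c("lineage", "gene", "ln_P")],
                  idvar = "lineage", timevar = "gene", direction = "wide")
  ln_sum <- log(exp(wide$ln_P.1) + exp(wide$ln_P.2))
  expect_lt(max(abs(ln_sum - log(2))), 0.5)
  expect_lt(var(ln_sum), var(wide$ln_P.1))
})

test_that("config validation catches inconsistent setups", {
  net_free <- regulatory_network(gene_params())  # no optimum
  expect_error(evolution_config(net_free, regime = "stabilizing"),
               "ln_optimum")
  expect_error(evolution_config(net_free, regime = "equivalent"),
               "two genes")
  net <- regulatory_network(gene_params(ln_optimum = 0, sigma_omega = 1))
  expect_error(evolution_config(net, Ne = 0), "Ne")
  expect_error(evolution_config(net, T = 0), "T")
  expect_error(
    evolution_config(net, mutation_params(n_genes = 2)), "genes")
})

test_that("ensemble TSV export is long-format and complete", {
  cfg <- default_cfg("stabilizing", T = 1000, record_every = 500)
  ens <- evolve_replicates(cfg, 3, base_seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_ensemble_tsv(ens, path)
  expect_true(file.exists(path))
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 3 * length(ens$times))
  expect_equal(names(back),
               c("lineage_id", "time", "gene", "ln_alpha", "ln_beta",
                 "ln_R", "ln_P"))
  expect_equal(back$ln_alpha, out$ln_alpha)
})
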