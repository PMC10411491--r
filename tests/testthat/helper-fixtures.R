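# Shared, lazily-built simulation fixtures. The heavier ensembles are the
# study conditions themselves (T = 1e5, Ne = 1000, U = 5e-4, sigma = 0.1,
# sigma_omega = 1) at reduced replicate counts; they are computed once per
# test run and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_cfg <- function(regime = "stabilizing", ln_optimum = 0, T = 1e5,
                        Ne = 1000, sigma_omega = 1, record_every = 1000) {
  net <- regulatory_network(gene_params(ln_optimum = ln_optimum,
                                        sigma_omega = sigma_omega))
  evolution_config(net, mutation_params(), Ne = Ne, T = T, regime = regime,
                   record_every = record_every)
}

stab_ensemble <- function() fixture("stab", function()
  evolve_replicates(default_cfg("stabilizing"), 150, base_seed = 101))

neutral_ensemble <- function() fixture("neutral", function()
  evolve_replicates(default_cfg("neutral"), 150, base_seed = 202))

directional_ensemble <- function() fixture("directional", function()
  evolve_replicates(default_cfg("directional", ln_optimum = 1), 200,
                    base_seed = 303, keep_trajectories = FALSE))

fixture_tree <- function() fixture("tree", function()
  rescale_height(simulate_yule(50, seed = 77), 1e5))

# a small tree with known structure for closed-form checks
small_tree <- function() ape::read.tree(text = "((a:1,b:1):1,c:2);")
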