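#' Mutation process parameters
#'
#' Per-gene rates and effect sizes of the mutational input. `U_alpha[i]` is
#' the per-haploid-genome, per-time-step rate of mutations hitting gene i's
#' transcription rate and `U_beta[i]` the rate for its translation rate; a
#' mutation perturbs exactly one of the two (no pleiotropy). Effects on the
#' log scale are drawn from centred normals with SDs `sigma_alpha[i]`,
#' `sigma_beta[i]`.
#'
#' @param U_alpha,U_beta non-negative per-gene mutation rates (recycled to
#'   the number of genes).
#' @param sigma_alpha,sigma_beta positive SDs of mutational effects.
#' @param n_genes number of genes; defaults to the longest argument.
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(U_alpha = 5e-4, U_beta = 5e-4,
                            sigma_alpha = 0.1, sigma_beta = 0.1,
                            n_genes = NULL) {
  if (is.null(n_genes))
    n_genes <- max(length(U_alpha), length(U_beta),
                   length(sigma_alpha), length(sigma_beta))
  U_alpha <- rep_len(U_alpha, n_genes)
  U_beta <- rep_len(U_beta, n_genes)
  sigma_alpha <- rep_len(sigma_alpha, n_genes)
  sigma_beta <- rep_len(sigma_beta, n_genes)
  if (any(U_alpha < 0) || any(U_beta < 0))
    stop("mutation rates must be non-negative")
  if (any(sigma_alpha <= 0) || any(sigma_beta <= 0))
    stop("mutational effect SDs must be positive")
  if (sum(U_alpha) + sum(U_beta) <= 0)
    stop("total mutation rate must be positive")
  structure(list(U_alpha = U_alpha, U_beta = U_beta,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 n_genes = n_genes),
            class = "mutation_params")
}

#' Expected number of mutations entering the population per time step
#'
#' In the origin-fixation regime, `2 Ne` haploid genomes each contribute
#' mutations at total rate `sum(U)`, so the Poisson mean of mutations
#' considered per time step is `2 * Ne * sum(U)`.
#'
#' @param Ne effective population size.
#' @param mut a [mutation_params()] object.
#' @return The expected count (numeric scalar).
#' @export
expected_mutation_count <- function(Ne, mut) {
  stopifnot(inherits(mut, "mutation_params"), Ne >= 1)
  2 * Ne * (sum(mut$U_alpha) + sum(mut$U_beta))
}

#' Draw random mutation events
#'
#' The target gene and trait are chosen with probability proportional to
#' their rates; the log-scale effect is normal with the chosen trait's SD.
#'
#' @param mut a [mutation_params()] object.
#' @param n number of events to draw.
#' @return A data.frame with columns `gene`, `trait` ("transcription" or
#'   "translation"), and `effect`.
#' @export
draw_mutation <- function(mut, n = 1) {
  stopifnot(inherits(mut, "mutation_params"))
  rates <- c(mut$U_alpha, mut$U_beta)
  ch <- sample.int(2 * mut$n_genes, n, replace = TRUE, prob = rates)
  is_alpha <- ch <= mut$n_genes
  gene <- ifelse(is_alpha, ch, ch - mut$n_genes)
  sds <- ifelse(is_alpha, mut$sigma_alpha[gene], mut$sigma_beta[gene])
  data.frame(gene = gene,
             trait = ifelse(is_alpha, "transcription", "translation"),
             effect = rnorm(n, 0, sds))
}

#' Gaussian fitness of an expression state
#'
#' Fitness is the product over directly selected genes of Gaussian terms in
#' the deviation of each log protein level from its optimum:
#' `exp(-sum_i (ln P_i - ln O_i)^2 / (2 sigma_omega_i^2))`. A
#' no-equilibrium condition (see [steady_state()]) is assigned fitness 0.
#'
#' @param state an `expression_state`, or a condition of class
#'   `mpcoevo_no_equilibrium`.
#' @param net the [regulatory_network()] carrying optima and fitness widths.
#' @return Fitness in `[0, 1]`.
#' @export
gaussian_fitness <- function(state, net) {
  if (inherits(state, "mpcoevo_no_equilibrium")) return(0)
  stopifnot(inherits(state, "expression_state"),
            inherits(net, "regulatory_network"))
  v <- net_vectors(net)
  sel <- v$has_optimum
  if (!any(sel)) return(1)
  d <- state$ln_P[sel] - v$ln_optimum[sel]
  exp(-sum(d^2 / (2 * v$sigma_omega[sel]^2)))
}

#' Fitness of a functionally equivalent gene pair
#'
#' For duplicate genes whose proteins are interchangeable, selection acts
#' on the summed protein level:
#' `exp(-(ln(P1 + P2) - ln_optimum)^2 / (2 sigma_omega^2))`.
#'
#' @param ln_P1,ln_P2 log protein levels of the two genes.
#' @param ln_optimum optimal log total protein level.
#' @param sigma_omega SD of the Gaussian fitness function.
#' @return Fitness in `[0, 1]`.
#' @export
equivalent_fitness <- function(ln_P1, ln_P2, ln_optimum, sigma_omega) {
  stopifnot(sigma_omega > 0)
  d <- log(exp(ln_P1) + exp(ln_P2)) - ln_optimum
  exp(-d^2 / (2 * sigma_omega^2))
}

#' Kimura fixation probability
#'
#' `pf = (1 - exp(-2 s)) / (1 - exp(-4 Ne s))`, continuous at `s = 0` with
#' the neutral limit `1 / (2 Ne)`, clamped to `[0, 1]`, and computed with
#' `expm1` so strongly deleterious mutations underflow to 0 rather than
#' overflowing.
#'
#' @param s selection coefficient(s).
#' @param Ne effective population size.
#' @return Fixation probability, vectorized over `s`.
#' @export
fixation_probability <- function(s, Ne) {
  stopifnot(Ne >= 1)
  vapply(s, fixation_probability_cpp, 0, Ne = Ne)
}

regime_codes <- c(neutral = 0L, stabilizing = 1L, directional = 1L,
                  equivalent = 2L)

#' Configuration of one evolutionary simulation
#'
#' Collects everything [evolve_lineage()] needs: the regulatory network
#' (with optima), mutation process, population size `Ne`, number of time
#' steps `T`, the selection regime, and the trajectory recording interval.
#' Regimes: `"neutral"` (every proposal fixes with probability `1/(2 Ne)`;
#' fitness is ignored), `"stabilizing"` / `"directional"` (Gaussian fitness
#' on each selected gene's protein level; the two differ only in whether
#' the starting phenotype sits at or away from the optimum), and
#' `"equivalent"` (two genes, selection on their summed protein level).
#' For `"equivalent"`, `equivalent_optimum` defaults to the log of the
#' summed starting protein level, i.e. the pair starts at its optimum
#' (log 2 for the all-zero start).
#'
#' @param network a [regulatory_network()].
#' @param mutation a [mutation_params()] (defaults match the network size).
#' @param Ne effective population size (>= 1).
#' @param T number of time steps (>= 1).
#' @param regime one of `"neutral"`, `"stabilizing"`, `"directional"`,
#'   `"equivalent"`.
#' @param equivalent_optimum optimal log summed protein level (regime
#'   `"equivalent"` only).
#' @param equivalent_sigma_omega fitness width for the summed protein.
#' @param record_every trajectory sampling interval in time steps; the end
#'   point at `T` is always recorded.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(network, mutation = NULL, Ne = 1000, T = 1e5,
                             regime = c("stabilizing", "neutral",
                                        "directional", "equivalent"),
                             equivalent_optimum = NULL,
                             equivalent_sigma_omega = 1,
                             record_every = 1000) {
  regime <- match.arg(regime)
  stopifnot(inherits(network, "regulatory_network"))
  if (is.null(mutation)) mutation <- mutation_params(n_genes = network$n)
  stopifnot(inherits(mutation, "mutation_params"))
  if (mutation$n_genes != network$n)
    stop("mutation_params cover ", mutation$n_genes,
         " genes but the network has ", network$n)
  if (!is.numeric(Ne) || length(Ne) != 1 || Ne < 1)
    stop("Ne must be a single value >= 1")
  if (!is.numeric(T) || length(T) != 1 || T < 1)
    stop("T must be a single value >= 1")
  if (!is.numeric(record_every) || record_every < 1)
    stop("record_every must be >= 1")
  v <- net_vectors(network)
  if (regime %in% c("stabilizing", "directional") && !any(v$has_optimum))
    stop("regime '", regime, "' requires at least one gene with ln_optimum")
  if (regime == "equivalent") {
    if (network$n != 2)
      stop("regime 'equivalent' requires exactly two genes")
    if (is.null(equivalent_optimum)) {
      st <- steady_state(network)
      equivalent_optimum <- log(sum(exp(st$ln_P)))
    }
    if (equivalent_sigma_omega <= 0)
      stop("equivalent_sigma_omega must be > 0")
  } else equivalent_optimum <- NA_real_
  structure(list(network = network, mutation = mutation,
                 Ne = as.numeric(Ne), T = as.integer(T), regime = regime,
                 equivalent_optimum = as.numeric(equivalent_optimum),
                 equivalent_sigma_omega = as.numeric(equivalent_sigma_omega),
                 record_every = as.integer(record_every)),
            class = "evolution_config")
}

#' Evolve a single lineage by sequential fixation
#'
#' Runs the origin-fixation model for `T` time steps. Each step draws a
#' Poisson number of mutations (mean [expected_mutation_count()]); each
#' mutation in turn perturbs one genotypic value, the steady-state
#' phenotype and fitness are recomputed, the selection coefficient is
#' `s = w / w_A - 1` against the current (post-previous-fixation)
#' resident fitness, and the mutation fixes with [fixation_probability()].
#' Under the neutral regime every proposal fixes with probability
#' `1/(2 Ne)`, giving selected and neutral runs identical mutational input.
#'
#' @param config an [evolution_config()].
#' @param seed optional integer seed (set before the run).
#' @param init optional list with numeric vectors `ln_alpha`, `ln_beta`
#'   overriding the network's starting genotype.
#' @return A `lineage_trajectory`: list with `times`, matrices
#'   `ln_alpha`, `ln_beta`, `ln_R`, `ln_P` (one row per record, one column
#'   per gene), counts `n_proposed`, `n_fixed_alpha`, `n_fixed_beta`, and
#'   `end` (the final genotype and phenotype).
#' @export
evolve_lineage <- function(config, seed = NULL, init = NULL) {
  stopifnot(inherits(config, "evolution_config"))
  if (!is.null(seed)) set.seed(seed)
  v <- net_vectors(config$network)
  la0 <- if (is.null(init)) v$ln_alpha else rep_len(init$ln_alpha, config$network$n)
  lb0 <- if (is.null(init)) v$ln_beta else rep_len(init$ln_beta, config$network$n)
  m <- config$mutation
  res <- evolve_lineage_cpp(
    config$T, config$Ne, m$U_alpha, m$U_beta, m$sigma_alpha, m$sigma_beta,
    config$network$C, v$ln_gamma_R, v$ln_gamma_P,
    v$has_optimum, ifelse(v$has_optimum, v$ln_optimum, 0),
    ifelse(v$has_optimum, v$sigma_omega, 1),
    regime_codes[[config$regime]],
    ifelse(is.na(config$equivalent_optimum), 0, config$equivalent_optimum),
    config$equivalent_sigma_omega,
    la0, lb0, config$record_every)
  last <- length(res$times)
  res$end <- list(ln_alpha = res$ln_alpha[last, ], ln_beta = res$ln_beta[last, ],
                  ln_R = res$ln_R[last, ], ln_P = res$ln_P[last, ])
  res$config <- config
  class(res) <- "lineage_trajectory"
  res
}

#' Evolve an ensemble of independent replicate lineages
#'
#' All lineages start from the same initial genotype and evolve
#' independently; each lineage gets its own RNG seed drawn once from the
#' root seed, so ensembles are reproducible and a lineage's result does not
#' depend on how many others were run.
#'
#' @param config an [evolution_config()].
#' @param n_lineages number of replicate lineages.
#' @param base_seed root seed for the ensemble.
#' @param keep_trajectories keep the full per-lineage trajectories (set
#'   `FALSE` to retain end points only).
#' @return A `lineage_ensemble`: list with `endpoints` (data.frame with
#'   columns `lineage`, `gene`, `ln_alpha`, `ln_beta`, `ln_R`, `ln_P`),
#'   `trajectories` (list or NULL), `times`, `config`, `seeds`.
#' @export
evolve_replicates <- function(config, n_lineages, base_seed = 1,
                              keep_trajectories = TRUE) {
  stopifnot(inherits(config, "evolution_config"), n_lineages >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_lineages)
  trajs <- vector("list", n_lineages)
  n <- config$network$n
  ep <- vector("list", n_lineages)
  for (i in seq_len(n_lineages)) {
    tr <- evolve_lineage(config, seed = seeds[i])
    ep[[i]] <- data.frame(lineage = i, gene = seq_len(n),
                          ln_alpha = tr$end$ln_alpha, ln_beta = tr$end$ln_beta,
                          ln_R = tr$end$ln_R, ln_P = tr$end$ln_P)
    if (keep_trajectories) trajs[[i]] <- tr
  }
  structure(list(endpoints = do.call(rbind, ep),
                 trajectories = if (keep_trajectories) trajs else NULL,
                 times = if (keep_trajectories) trajs[[1]]$times else NULL,
                 config = config, seeds = seeds),
            class = "lineage_ensemble")
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  cat("lineage trajectory:", x$config$T, "time steps,",
      x$config$network$n, "gene(s), regime", x$config$regime, "\n")
  cat(" proposed mutations:", x$n_proposed,
      " fixed:", sum(x$n_fixed_alpha) + sum(x$n_fixed_beta), "\n")
  invisible(x)
}

#' @export
print.lineage_ensemble <- function(x, ...) {
  cat("ensemble of", length(x$seeds), "lineages, regime",
      x$config$regime, "\n")
  invisible(x)
}

#' Write ensemble trajectories or end points as TSV
#'
#' Long format: one row per (lineage, recorded time, gene) with the
#' genotypic values and derived phenotypes.
#'
#' @param ensemble a `lineage_ensemble`.
#' @param path output file; `""` returns the data.frame invisibly written
#'   nowhere.
#' @param endpoints_only write only the final states.
#' @return The long data.frame, invisibly.
#' @export
write_ensemble_tsv <- function(ensemble, path, endpoints_only = FALSE) {
  stopifnot(inherits(ensemble, "lineage_ensemble"))
  if (endpoints_only || is.null(ensemble$trajectories)) {
    out <- cbind(lineage_id = ensemble$endpoints$lineage,
                 time = ensemble$config$T,
                 ensemble$endpoints[, c("gene", "ln_alpha", "ln_beta",
                                        "ln_R", "ln_P")])
  } else {
    n <- ensemble$config$network$n
    out <- do.call(rbind, lapply(seq_along(ensemble$trajectories), function(i) {
      tr <- ensemble$trajectories[[i]]
      do.call(rbind, lapply(seq_len(n), function(g)
        data.frame(lineage_id = i, time = tr$times, gene = g,
                   ln_alpha = tr$ln_alpha[, g], ln_beta = tr$ln_beta[, g],
                   ln_R = tr$ln_R[, g], ln_P = tr$ln_P[, g])))
    }))
  }
  if (nzchar(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
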