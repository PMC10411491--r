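#' Add measurement error to ensemble end points
#'
#' Independent normal errors with SD `sigma_eps` are added to the log mRNA
#' and log protein levels of every row; the "measured" translation rate is
#' the ratio of measured protein to measured mRNA, so its error is
#' anticorrelated with the mRNA error by construction:
#' `ln_beta_hat = ln_P_hat - ln_R_hat`.
#'
#' @param endpoints a data.frame with columns `ln_R`, `ln_P` (e.g.
#'   `ensemble$endpoints` or a `tree_tips` table).
#' @param sigma_eps error SD (>= 0; 0 reproduces the input exactly).
#' @param seed optional integer seed.
#' @return The data.frame with added columns `ln_R_hat`, `ln_P_hat`,
#'   `ln_beta_hat`.
#' @export
add_measurement_error <- function(endpoints, sigma_eps, seed = NULL) {
  stopifnot(is.data.frame(endpoints), sigma_eps >= 0,
            all(c("ln_R", "ln_P") %in% names(endpoints)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(endpoints)
  eps_R <- if (sigma_eps > 0) rnorm(n, 0, sigma_eps) else numeric(n)
  eps_P <- if (sigma_eps > 0) rnorm(n, 0, sigma_eps) else numeric(n)
  endpoints$ln_R_hat <- endpoints$ln_R + eps_R
  endpoints$ln_P_hat <- endpoints$ln_P + eps_P
  endpoints$ln_beta_hat <- endpoints$ln_P_hat - endpoints$ln_R_hat
  endpoints
}

#' Correlation, regression slope, and variances of ensemble end points
#'
#' Standard Pearson correlation and ordinary least-squares slope of trait y
#' on trait x across lineage end points, plus each trait's across-lineage
#' variance.
#'
#' @param endpoints a `lineage_ensemble` or its `endpoints` data.frame.
#' @param x,y column names of the two traits.
#' @param gene gene index to subset on.
#' @return List with `r`, `slope`, `intercept`, `n`, and `variances` (named
#'   by trait). `slope` is `NA` (flagged via `zero_var_x`) when x has zero
#'   variance.
#' @export
endpoint_stats <- function(endpoints, x = "ln_R", y = "ln_beta", gene = 1) {
  if (inherits(endpoints, "lineage_ensemble")) endpoints <- endpoints$endpoints
  ep <- endpoints[endpoints$gene == gene, , drop = FALSE]
  if (nrow(ep) < 3) stop("need at least 3 lineages")
  xv <- ep[[x]]
  yv <- ep[[y]]
  vx <- var(xv)
  vy <- var(yv)
  if (vx == 0) {
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = nrow(ep), zero_var_x = TRUE,
                variances = setNames(c(vx, vy), c(x, y))))
  }
  cf <- coef(lm(yv ~ xv))
  list(r = if (vy == 0) NA_real_ else cor(xv, yv),
       slope = unname(cf[2]), intercept = unname(cf[1]), n = nrow(ep),
       zero_var_x = FALSE, variances = setNames(c(vx, vy), c(x, y)))
}

#' Across-lineage variance of each trait through time
#'
#' @param ensemble a `lineage_ensemble` with stored trajectories.
#' @param traits trait matrices to summarize.
#' @return A data.frame with columns `time`, `gene`, `trait`, `variance`.
#' @export
variance_trajectory <- function(ensemble,
                                traits = c("ln_alpha", "ln_beta",
                                           "ln_R", "ln_P")) {
  stopifnot(inherits(ensemble, "lineage_ensemble"))
  if (is.null(ensemble$trajectories))
    stop("ensemble was run with keep_trajectories = FALSE")
  times <- ensemble$times
  ngene <- ensemble$config$network$n
  out <- list()
  for (tr in traits) {
    for (g in seq_len(ngene)) {
      m <- vapply(ensemble$trajectories, function(z) z[[tr]][, g],
                  numeric(length(times)))
      out[[paste(tr, g)]] <- data.frame(
        time = times, gene = g, trait = tr,
        variance = apply(m, 1, var))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

single_gene_config <- function(Ne = 1000, T = 1e5, ln_optimum = 0,
                               sigma_omega = 1, mutation = mutation_params(),
                               regime = "stabilizing", record_every = 1000) {
  net <- regulatory_network(gene_params(ln_optimum = ln_optimum,
                                        sigma_omega = sigma_omega))
  evolution_config(net, mutation, Ne = Ne, T = T, regime = regime,
                   record_every = record_every)
}

#' Grid of end-point correlations over selection strengths
#'
#' For each combination of effective population size and fitness-function
#' width, evolves a replicate ensemble under stabilizing selection and
#' records the end-point transcription-translation and mRNA-protein
#' correlations. Selection is stronger for larger `Ne` and smaller
#' `sigma_omega`.
#'
#' @param ne_values vector of `Ne` values.
#' @param sigma_omega_values vector of fitness-width values.
#' @param config base [evolution_config()] (single gene); each cell
#'   overrides its `Ne` and the gene's `sigma_omega`.
#' @param n_lineages lineages per cell.
#' @param base_seed root seed; each cell gets a derived seed.
#' @return Tidy data.frame: `Ne`, `sigma_omega`, `stat`, `value`,
#'   `n_lineages`, `seed`.
#' @export
selection_grid <- function(ne_values, sigma_omega_values,
                           config = single_gene_config(),
                           n_lineages = 100, base_seed = 1) {
  stopifnot(length(ne_values) >= 1, length(sigma_omega_values) >= 1)
  cells <- expand.grid(Ne = ne_values, sigma_omega = sigma_omega_values)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  out <- lapply(seq_len(nrow(cells)), function(k) {
    cfg <- config
    cfg$Ne <- cells$Ne[k]
    cfg$network$genes[[1]]$sigma_omega <- cells$sigma_omega[k]
    ens <- evolve_replicates(cfg, n_lineages, base_seed = seeds[k],
                             keep_trajectories = FALSE)
    data.frame(Ne = cells$Ne[k], sigma_omega = cells$sigma_omega[k],
               stat = c("cor_lnR_lnbeta", "cor_lnR_lnP"),
               value = c(endpoint_stats(ens, "ln_R", "ln_beta")$r,
                         endpoint_stats(ens, "ln_R", "ln_P")$r),
               n_lineages = n_lineages, seed = seeds[k])
  })
  do.call(rbind, out)
}

two_gene_network <- function(c12, c21, scenario = c("target", "both"),
                             ln_optimum = 0, sigma_omega = 1) {
  scenario <- match.arg(scenario)
  g1 <- gene_params(ln_optimum = ln_optimum, sigma_omega = sigma_omega)
  g2 <- if (scenario == "both")
    gene_params(ln_optimum = ln_optimum, sigma_omega = sigma_omega)
  else gene_params()
  C <- matrix(0, 2, 2)
  C[1, 2] <- c12  # effect of gene 1's protein on gene 2's transcription
  C[2, 1] <- c21
  regulatory_network(list(g1, g2), C)
}

#' Grid of correlations for two interacting genes
#'
#' For each combination of the interaction parameters `C[1,2]` and
#' `C[2,1]`, evolves two-gene ensembles and records, per gene, the
#' transcription-translation correlation (on genotypic values `ln_alpha`,
#' `ln_beta`, as well as on realized `ln_R`) and the mRNA-protein
#' correlation. In the `"target"` scenario gene 1 is under direct
#' stabilizing selection and gene 2 is an unselected regulator; in
#' `"both"`, both genes carry an optimum. Cells whose starting steady
#' state has no equilibrium are reported as missing with a reason.
#'
#' @param c12_values,c21_values interaction parameter grids (|C| < 1).
#' @param scenario `"target"` or `"both"`.
#' @param n_lineages lineages per cell.
#' @param Ne,T,sigma_omega,mutation engine parameters.
#' @param base_seed root seed.
#' @return Tidy data.frame: `c12`, `c21`, `gene`, `stat`, `value`,
#'   `n_lineages`, `seed`, `missing_reason`.
#' @export
interaction_grid <- function(c12_values, c21_values,
                             scenario = c("target", "both"),
                             n_lineages = 100, Ne = 1000, T = 1e5,
                             sigma_omega = 1,
                             mutation = mutation_params(n_genes = 2),
                             base_seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(all(abs(c12_values) < 1), all(abs(c21_values) < 1))
  cells <- expand.grid(c12 = c12_values, c21 = c21_values)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  stats_one <- function(ens, g) {
    data.frame(stat = c("cor_lnalpha_lnbeta", "cor_lnR_lnbeta",
                        "cor_lnR_lnP"),
               value = c(endpoint_stats(ens, "ln_alpha", "ln_beta", gene = g)$r,
                         endpoint_stats(ens, "ln_R", "ln_beta", gene = g)$r,
                         endpoint_stats(ens, "ln_R", "ln_P", gene = g)$r))
  }
  out <- lapply(seq_len(nrow(cells)), function(k) {
    net <- two_gene_network(cells$c12[k], cells$c21[k], scenario,
                            sigma_omega = sigma_omega)
    res <- tryCatch({
      steady_state(net)  # probe the starting equilibrium
      cfg <- evolution_config(net, mutation, Ne = Ne, T = T,
                              regime = "stabilizing")
      ens <- evolve_replicates(cfg, n_lineages, base_seed = seeds[k],
                               keep_trajectories = FALSE)
      do.call(rbind, lapply(1:2, function(g)
        cbind(gene = g, stats_one(ens, g), missing_reason = NA_character_)))
    }, mpcoevo_no_equilibrium = function(e) {
      data.frame(gene = NA_integer_, stat = NA_character_, value = NA_real_,
                 missing_reason = "no equilibrium at starting genotype")
    })
    cbind(c12 = cells$c12[k], c21 = cells$c21[k], res,
          n_lineages = n_lineages, seed = seeds[k])
  })
  do.call(rbind, out)
}

#' Multi-optimum experiment: within-gene versus across-gene correlations
#'
#' Draws `n_genes` optimal log protein levels from a centred normal,
#' evolves each gene independently (separate single-gene runs sharing a
#' seed schedule) from the common ancestral state `ln_alpha = ln_beta = 0`,
#' and contrasts the within-gene (across-lineage) correlations with the
#' pooled across-gene correlations - the Simpson's-paradox pattern. Also
#' reports, across genes, the correlation between each trait's
#' among-lineage variance and the distance `|ln_optimum - ancestral ln P|`.
#'
#' @param n_genes number of genes (>= 2).
#' @param optimum_sd SD of the optimum distribution (default `sqrt(2)`,
#'   i.e. variance 2).
#' @param n_lineages lineages per gene.
#' @param Ne,T,sigma_omega,mutation engine parameters.
#' @param base_seed root seed (drives both the optima draw and the runs).
#' @return List with `optima`, `per_gene` (data.frame of within-gene r and
#'   variances), `pooled` (across-gene r values), and `variance_vs_distance`
#'   (correlation of among-lineage variance with `|ln_optimum|`, per trait).
#' @export
multi_optima_experiment <- function(n_genes = 20, optimum_sd = sqrt(2),
                                    n_lineages = 500, Ne = 1000, T = 1e5,
                                    sigma_omega = 1,
                                    mutation = mutation_params(),
                                    base_seed = 1) {
  stopifnot(n_genes >= 2)
  set.seed(base_seed)
  optima <- rnorm(n_genes, 0, optimum_sd)
  seeds <- sample.int(.Machine$integer.max - 1L, n_genes)
  per_gene <- vector("list", n_genes)
  pools <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    cfg <- single_gene_config(Ne = Ne, T = T, ln_optimum = optima[g],
                              sigma_omega = sigma_omega, mutation = mutation,
                              regime = "directional")
    ens <- evolve_replicates(cfg, n_lineages, base_seed = seeds[g],
                             keep_trajectories = FALSE)
    ep <- ens$endpoints
    per_gene[[g]] <- data.frame(
      gene = g, ln_optimum = optima[g],
      r_lnR_lnbeta = cor(ep$ln_R, ep$ln_beta),
      r_lnR_lnP = cor(ep$ln_R, ep$ln_P),
      var_lnR = var(ep$ln_R), var_lnbeta = var(ep$ln_beta),
      var_lnP = var(ep$ln_P))
    pools[[g]] <- ep
  }
  per_gene <- do.call(rbind, per_gene)
  pool <- do.call(rbind, pools)
  list(optima = optima,
       per_gene = per_gene,
       pooled = list(r_lnR_lnbeta = cor(pool$ln_R, pool$ln_beta),
                     r_lnR_lnP = cor(pool$ln_R, pool$ln_P)),
       variance_vs_distance = c(
         ln_R = cor(per_gene$var_lnR, abs(per_gene$ln_optimum)),
         ln_beta = cor(per_gene$var_lnbeta, abs(per_gene$ln_optimum))),
       endpoints = pool)
}

#' Scan over relative mutational target sizes
#'
#' Keeps the total mutation rate fixed and varies the fraction of
#' mutations that hit transcription: `U_alpha = f * total`,
#' `U_beta = (1 - f) * total` for each fraction `f`.
#'
#' @param fractions transcription-mutation fractions in (0, 1).
#' @param total_rate total mutation rate `U_alpha + U_beta`.
#' @param n_lineages lineages per fraction.
#' @param Ne,T,sigma_omega,sigma_alpha,sigma_beta engine parameters.
#' @param regime selection regime.
#' @param base_seed root seed.
#' @return Tidy data.frame: `fraction`, `stat`, `value`, `n_lineages`,
#'   `seed`.
#' @export
mutational_target_scan <- function(fractions = seq(0.1, 0.9, by = 0.1),
                                   total_rate = 1e-3, n_lineages = 100,
                                   Ne = 1000, T = 1e5, sigma_omega = 1,
                                   sigma_alpha = 0.1, sigma_beta = 0.1,
                                   regime = "stabilizing", base_seed = 1) {
  stopifnot(all(fractions > 0 & fractions < 1), total_rate > 0)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(fractions))
  out <- lapply(seq_along(fractions), function(k) {
    f <- fractions[k]
    mut <- mutation_params(U_alpha = f * total_rate,
                           U_beta = (1 - f) * total_rate,
                           sigma_alpha = sigma_alpha, sigma_beta = sigma_beta)
    cfg <- single_gene_config(Ne = Ne, T = T, sigma_omega = sigma_omega,
                              mutation = mut, regime = regime)
    ens <- evolve_replicates(cfg, n_lineages, base_seed = seeds[k],
                             keep_trajectories = FALSE)
    data.frame(fraction = f,
               stat = c("cor_lnR_lnbeta", "cor_lnR_lnP"),
               value = c(endpoint_stats(ens, "ln_R", "ln_beta")$r,
                         endpoint_stats(ens, "ln_R", "ln_P")$r),
               n_lineages = n_lineages, seed = seeds[k])
  })
  do.call(rbind, out)
}
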