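#' Default model parameters of the study conditions
#'
#' The parameter set used by every preset unless overridden: `T = 1e5` time
#' steps, `Ne = 1000`, per-trait mutation rates `U_alpha = U_beta = 5e-4`
#' (so one mutation per trait enters the population per time step,
#' `2 Ne U = 1`), mutational effect SDs `sigma_alpha = sigma_beta = 0.1`,
#' optimum `ln_optimum = 0` (1 for the directional preset), fitness width
#' `sigma_omega = 1`, 500 replicate lineages, and the all-zero starting
#' genotype.
#'
#' @return A named list of defaults.
#' @export
default_parameters <- function() {
  list(T = 1e5, Ne = 1000, U_alpha = 5e-4, U_beta = 5e-4,
       sigma_alpha = 0.1, sigma_beta = 0.1, ln_optimum = 0,
       sigma_omega = 1, n_lineages = 500, record_every = 1000)
}

experiment_presets <- function() {
  c("fig1", "fig1-grid", "fig2", "fig3-grid", "fig4", "multi-optima",
    "mut-scan", "error-scan")
}

#' Read an experiment configuration from a YAML file
#'
#' Fields mirror [default_parameters()] plus `preset`, `regime`,
#' `n_lineages`, and `lambda` / `n_tips` for tree presets; unknown fields
#' are rejected so typos surface immediately.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  known <- c(names(default_parameters()),
             "preset", "regime", "lambda", "n_tips", "birth_rate",
             "sigma_eps", "scale", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg
}

validate_params <- function(p) {
  if (p$Ne < 1) stop("invalid parameter Ne: must be >= 1 (got ", p$Ne, ")")
  if (p$T < 1) stop("invalid parameter T: must be >= 1 (got ", p$T, ")")
  if (p$n_lineages < 1)
    stop("invalid parameter n_lineages: must be >= 1 (got ", p$n_lineages, ")")
  if (p$sigma_omega <= 0)
    stop("invalid parameter sigma_omega: must be > 0 (got ", p$sigma_omega, ")")
  if (p$U_alpha < 0 || p$U_beta < 0)
    stop("invalid parameter U_alpha/U_beta: rates must be >= 0")
  invisible(p)
}

out_header <- function(spec_tag, seed) {
  paste0("# mpcoevo experiment ", spec_tag, " seed=", seed)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run a named preset experiment
#'
#' Orchestrates the package's modules into the study's preset experiment
#' designs and writes all outputs (TSV tables, newick trees, a resolved
#' configuration) into `out_dir`. Presets: `fig1` (single-gene stabilizing
#' + neutral ensembles, end-point stats, variance trajectories),
#' `fig1-grid` (Ne x sigma_omega selection grid), `fig2` (Yule-tree
#' simulation, BM/OU comparison, divergence-vs-time table), `fig3-grid`
#' (two-gene interaction grid), `fig4` (directional selection ensemble),
#' `multi-optima`, `mut-scan`, and `error-scan` (measurement error SDs
#' 0.01-0.05). The `scale` factor multiplies `n_lineages` (and grid sizes
#' are reduced) for desk-scale runs; results are deterministic given
#' `(preset, parameters, seed)`.
#'
#' @param preset preset name, one of `experiment_presets()`.
#' @param out_dir output directory (created if missing).
#' @param seed root seed.
#' @param scale factor in (0, 1] multiplying `n_lineages`.
#' @param params parameter overrides (see [default_parameters()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of the computed result objects.
#' @export
run_experiment <- function(preset, out_dir = ".", seed = 1, scale = 1,
                           params = list(), quiet = FALSE) {
  if (!preset %in% experiment_presets())
    stop("unknown preset '", preset, "'; available: ",
         paste(experiment_presets(), collapse = ", "))
  p <- utils::modifyList(default_parameters(), params)
  validate_params(p)
  nl <- max(3L, as.integer(round(p$n_lineages * scale)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- out_header(preset, seed)
  say <- function(...) if (!quiet) message(...)
  mut <- mutation_params(p$U_alpha, p$U_beta, p$sigma_alpha, p$sigma_beta)
  results <- list()

  base_cfg <- function(regime, ln_opt = p$ln_optimum)
    single_gene_config(Ne = p$Ne, T = p$T, ln_optimum = ln_opt,
                       sigma_omega = p$sigma_omega, mutation = mut,
                       regime = regime, record_every = p$record_every)

  if (preset %in% c("fig1", "fig4", "error-scan")) {
    regime <- if (preset == "fig4") "directional" else "stabilizing"
    ln_opt <- if (preset == "fig4") 1 else p$ln_optimum
    say("evolving ", nl, " lineages (", regime, ") ...")
    ens <- evolve_replicates(base_cfg(regime, ln_opt), nl, base_seed = seed)
    results$ensemble <- ens
    write_tsv_with_header(write_ensemble_tsv(ens, "", endpoints_only = TRUE),
                          file.path(out_dir, "endpoints.tsv"), hdr)
    st <- endpoint_stats(ens, "ln_R", "ln_beta")
    say(sprintf("end-point corr(lnR, lnbeta) = %.3f, slope = %.3f",
                st$r, st$slope))
    results$stats <- st
    vt <- variance_trajectory(ens)
    write_tsv_with_header(vt, file.path(out_dir, "variance_trajectory.tsv"),
                          hdr)
    if (preset == "fig1") {
      say("neutral control ...")
      ens0 <- evolve_replicates(base_cfg("neutral"), nl,
                                base_seed = seed + 1)
      results$neutral <- ens0
      write_tsv_with_header(
        write_ensemble_tsv(ens0, "", endpoints_only = TRUE),
        file.path(out_dir, "endpoints_neutral.tsv"), hdr)
    }
    if (preset == "error-scan") {
      rows <- lapply(c(0.01, 0.02, 0.03, 0.04, 0.05), function(se) {
        noisy <- add_measurement_error(ens$endpoints, se, seed = seed + 100)
        data.frame(sigma_eps = se,
                   stat = c("cor_lnRhat_lnbetahat", "cor_lnRhat_lnPhat"),
                   value = c(cor(noisy$ln_R_hat, noisy$ln_beta_hat),
                             cor(noisy$ln_R_hat, noisy$ln_P_hat)))
      })
      results$error_scan <- do.call(rbind, rows)
      write_tsv_with_header(results$error_scan,
                            file.path(out_dir, "error_scan.tsv"), hdr)
    }
  } else if (preset == "fig1-grid") {
    ne_vals <- if (scale < 1) c(100, 1000) else c(100, 300, 1000, 3000)
    sw_vals <- if (scale < 1) c(0.5, 2) else c(0.5, 1, 2, 4)
    grid <- selection_grid(ne_vals, sw_vals, base_cfg("stabilizing"),
                           n_lineages = nl, base_seed = seed)
    results$grid <- grid
    write_tsv_with_header(grid, file.path(out_dir, "selection_grid.tsv"), hdr)
  } else if (preset == "fig2") {
    n_tips <- if (!is.null(params$n_tips)) params$n_tips else 50
    tree <- rescale_height(simulate_yule(n_tips, seed = seed), p$T)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    say("evolving along a ", n_tips, "-tip tree ...")
    tips <- evolve_along_tree(tree, base_cfg("stabilizing"), seed = seed + 1)
    results$tips <- tips
    write_tsv_with_header(as.data.frame(tips),
                          file.path(out_dir, "tips.tsv"), hdr)
    by_trait <- lapply(c("ln_R", "ln_beta", "ln_P"), function(tr) {
      v <- setNames(tips[[tr]], tips$tip)
      fits <- aicc_compare(list(fit_bm(v, tree), fit_ou(v, tree)),
                           n = ape::Ntip(tree))
      cbind(trait = tr, attr(fits, "table"))
    })
    results$model_comparison <- do.call(rbind, by_trait)
    write_tsv_with_header(results$model_comparison,
                          file.path(out_dir, "model_comparison.tsv"), hdr)
    results$evolutionary_correlation <- evolutionary_correlation(
      setNames(tips$ln_R, tips$tip), setNames(tips$ln_beta, tips$tip), tree)
    dv <- divergence_vs_time(list(tips), tree)
    write_tsv_with_header(dv, file.path(out_dir, "divergence_vs_time.tsv"),
                          hdr)
    results$divergence <- dv
  } else if (preset == "fig3-grid") {
    vals <- if (scale < 1) c(-0.6, 0, 0.6) else seq(-0.8, 0.8, by = 0.2)
    grid <- interaction_grid(vals, vals, scenario = "target",
                             n_lineages = nl, Ne = p$Ne, T = p$T,
                             sigma_omega = p$sigma_omega,
                             mutation = mutation_params(
                               p$U_alpha, p$U_beta, p$sigma_alpha,
                               p$sigma_beta, n_genes = 2),
                             base_seed = seed)
    results$grid <- grid
    write_tsv_with_header(grid, file.path(out_dir, "interaction_grid.tsv"),
                          hdr)
  } else if (preset == "multi-optima") {
    res <- multi_optima_experiment(n_genes = 20, n_lineages = nl,
                                   Ne = p$Ne, T = p$T,
                                   sigma_omega = p$sigma_omega,
                                   mutation = mut, base_seed = seed)
    results$multi_optima <- res
    write_tsv_with_header(res$per_gene,
                          file.path(out_dir, "multi_optima_per_gene.tsv"),
                          hdr)
  } else if (preset == "mut-scan") {
    scan <- mutational_target_scan(n_lineages = nl, Ne = p$Ne, T = p$T,
                                   sigma_omega = p$sigma_omega,
                                   base_seed = seed)
    results$scan <- scan
    write_tsv_with_header(scan, file.path(out_dir, "mutational_scan.tsv"),
                          hdr)
  }

  resolved <- c(list(preset = preset, seed = seed, scale = scale,
                     n_lineages = nl), p[setdiff(names(p), "n_lineages")])
  writeLines(c(hdr, paste0(names(resolved), ": ",
                           vapply(resolved, format, ""))),
             file.path(out_dir, "resolved_config.txt"))
  say("outputs written to ", normalizePath(out_dir))
  invisible(results)
}
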