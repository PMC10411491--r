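#' Parameters of a single gene
#'
#' Bundles the genotypic values and constants that determine one gene's
#' steady-state expression: the log transcription rate `ln_alpha`, the log
#' per-transcript translation rate `ln_beta`, the log degradation rates of
#' mRNA and protein (constants, never touched by evolutionary operators),
#' and - when the gene's protein level is directly under selection - the
#' optimal log protein level `ln_optimum` together with the width
#' `sigma_omega` of the Gaussian fitness function.
#'
#' @param ln_alpha log genotypic transcription rate.
#' @param ln_beta log genotypic per-transcript translation rate.
#' @param ln_gamma_R log mRNA degradation rate (constant through evolution).
#' @param ln_gamma_P log protein degradation rate (constant).
#' @param ln_optimum optimal log protein level, or `NA` when the gene is not
#'   directly selected.
#' @param sigma_omega SD of the Gaussian fitness function; must be positive
#'   whenever `ln_optimum` is set.
#' @return An object of class `gene_params`.
#' @examples
#' g <- gene_params(ln_alpha = 0, ln_beta = 0, ln_optimum = 0, sigma_omega = 1)
#' steady_state_single(g)
#' @export
gene_params <- function(ln_alpha = 0, ln_beta = 0,
                        ln_gamma_R = 0, ln_gamma_P = 0,
                        ln_optimum = NA_real_, sigma_omega = NA_real_) {
  stopifnot(is.numeric(ln_alpha), length(ln_alpha) == 1,
            is.numeric(ln_beta), length(ln_beta) == 1)
  if (!is.na(ln_optimum)) {
    if (is.na(sigma_omega) || sigma_omega <= 0)
      stop("sigma_omega must be > 0 when ln_optimum is set")
  }
  structure(list(ln_alpha = as.numeric(ln_alpha),
                 ln_beta = as.numeric(ln_beta),
                 ln_gamma_R = as.numeric(ln_gamma_R),
                 ln_gamma_P = as.numeric(ln_gamma_P),
                 ln_optimum = as.numeric(ln_optimum),
                 sigma_omega = as.numeric(sigma_omega)),
            class = "gene_params")
}

#' A regulatory network of interacting genes
#'
#' Holds `n` genes and the interaction matrix `C`, where `C[i, j]` is the
#' power-law exponent with which gene i's protein acts on gene j's
#' transcription (negative values repress, positive values activate). The
#' diagonal is zero (no self-loops) and absolute values above one are
#' rejected: the power-law approximation to activation is only reasonable
#' below that bound. Values of exactly one are admitted so that the
#' positive-feedback boundary (where the equilibrium system is singular)
#' can be exercised; [steady_state()] then raises a no-equilibrium error.
#'
#' @param genes a `gene_params` object or a list of them.
#' @param C `n x n` interaction matrix; defaults to no interaction.
#' @return An object of class `regulatory_network` with fields `n`, `C`,
#'   `genes`.
#' @export
regulatory_network <- function(genes, C = NULL) {
  if (inherits(genes, "gene_params")) genes <- list(genes)
  if (!length(genes) || !all(vapply(genes, inherits, TRUE, "gene_params")))
    stop("genes must be gene_params objects")
  n <- length(genes)
  if (is.null(C)) C <- matrix(0, n, n)
  C <- as.matrix(C)
  if (!all(dim(C) == c(n, n)))
    stop("C must be an n x n matrix")
  if (any(diag(C) != 0))
    stop("C must have a zero diagonal (no self-loops)")
  if (any(abs(C) > 1))
    stop("interaction parameters with |C| > 1 are not supported")
  structure(list(n = n, C = C, genes = genes), class = "regulatory_network")
}

# flatten per-gene parameters into vectors for the solver / engine
net_vectors <- function(net) {
  g <- net$genes
  list(ln_alpha = vapply(g, `[[`, 0, "ln_alpha"),
       ln_beta = vapply(g, `[[`, 0, "ln_beta"),
       ln_gamma_R = vapply(g, `[[`, 0, "ln_gamma_R"),
       ln_gamma_P = vapply(g, `[[`, 0, "ln_gamma_P"),
       ln_optimum = vapply(g, `[[`, 0, "ln_optimum"),
       sigma_omega = vapply(g, `[[`, 0, "sigma_omega"),
       has_optimum = !vapply(g, function(x) is.na(x$ln_optimum), TRUE))
}

no_equilibrium_error <- function(rcond = NA_real_) {
  stop(errorCondition(
    paste0("no equilibrium: the log-linear steady-state system is singular",
           " (reciprocal condition number ", format(rcond), ")"),
    class = c("mpcoevo_no_equilibrium", "mpcoevo_error")))
}

#' Steady-state expression of a single gene
#'
#' At equilibrium of the mRNA/protein birth-death dynamics, the log mRNA
#' level is `ln_alpha - ln_gamma_R` and the log protein level is
#' `ln_alpha + ln_beta - ln_gamma_R - ln_gamma_P`.
#'
#' @param g a [gene_params()] object.
#' @return An `expression_state`: list with `ln_R` and `ln_P` (length 1).
#' @export
steady_state_single <- function(g) {
  stopifnot(inherits(g, "gene_params"))
  structure(list(ln_R = g$ln_alpha - g$ln_gamma_R,
                 ln_P = g$ln_alpha + g$ln_beta - g$ln_gamma_R - g$ln_gamma_P),
            class = "expression_state")
}

#' Steady-state expression of a regulatory network
#'
#' Solves the log-linear equilibrium system of the coupled mRNA/protein
#' dynamics: for each gene i, `ln R_i = ln alpha_i + sum_j C[j,i] ln P_j -
#' ln gamma_R` and `ln P_i = ln R_i + ln beta_i - ln gamma_P`. With no
#' interactions the result equals [steady_state_single()] applied gene by
#' gene. When the coefficient matrix is singular (positive feedback, e.g.
#' reciprocal activation exponents whose product is one) there is no
#' equilibrium: an error of class `mpcoevo_no_equilibrium` is raised, which
#' the fitness layer maps to fitness zero.
#'
#' @param net a [regulatory_network()].
#' @return An `expression_state`: list with numeric vectors `ln_R`, `ln_P`.
#' @export
steady_state <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  v <- net_vectors(net)
  res <- solve_network_cpp(v$ln_alpha, v$ln_beta, v$ln_gamma_R, v$ln_gamma_P,
                           net$C)
  if (isTRUE(res$singular)) no_equilibrium_error(res$rcond)
  structure(list(ln_R = res$ln_R, ln_P = res$ln_P),
            class = "expression_state")
}

#' Is the protein level expected to be more conserved than the mRNA level?
#'
#' Because `ln P = ln alpha + ln beta` (up to degradation constants),
#' the across-lineage variance of the log protein level is
#' `Var(ln alpha) + Var(ln beta) + 2 rho sqrt(Var(ln alpha) Var(ln beta))`,
#' while the variance of the log mRNA level equals `Var(ln alpha)`.
#' This function evaluates that inequality directly: it returns `TRUE` when
#' the protein variance is strictly below the mRNA variance, i.e. when the
#' transcription-translation correlation `rho` is negative enough to
#' compensate.
#'
#' @param var_ln_alpha across-lineage variance of the log transcription rate.
#' @param var_ln_beta across-lineage variance of the log translation rate.
#' @param rho correlation between the two, in `[-1, 1]`.
#' @return `TRUE` if `Var(ln P) < Var(ln R)`.
#' @export
protein_more_conserved <- function(var_ln_alpha, var_ln_beta, rho) {
  if (var_ln_alpha < 0 || var_ln_beta < 0)
    stop("variances must be non-negative")
  if (rho < -1 || rho > 1)
    stop("rho must lie in [-1, 1]")
  var_ln_p <- var_ln_alpha + var_ln_beta +
    2 * rho * sqrt(var_ln_alpha * var_ln_beta)
  var_ln_p < var_ln_alpha
}

#' @export
print.expression_state <- function(x, ...) {
  cat("steady-state expression (natural-log units)\n")
  print(data.frame(gene = seq_along(x$ln_R), ln_R = x$ln_R, ln_P = x$ln_P),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory network of", x$n, "gene(s)\n")
  if (any(x$C != 0)) {
    cat("interaction matrix C (C[i,j] = effect of gene i's protein on gene j):\n")
    print(x$C)
  } else cat("no interactions (C = 0)\n")
  invisible(x)
}

#' Write a regulatory network to a plain-text file
#'
#' Format: a first line with the number of genes `n`, then the `n x n`
#' whitespace-delimited interaction matrix, then one line per gene with
#' `ln_alpha ln_beta ln_optimum sigma_omega` (`NA` when the gene is not
#' directly selected).
#'
#' @param net a [regulatory_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(net$n), con)
  write.table(net$C, con, row.names = FALSE, col.names = FALSE)
  v <- net_vectors(net)
  write.table(data.frame(v$ln_alpha, v$ln_beta, v$ln_optimum, v$sigma_omega),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a regulatory network written by [write_network()]
#'
#' @param path file path.
#' @return A [regulatory_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || n < 1) stop("malformed network file: bad gene count")
  C <- as.matrix(read.table(text = lines[2:(1 + n)]))
  dimnames(C) <- NULL
  gtab <- read.table(text = lines[(2 + n):(1 + 2 * n)])
  genes <- lapply(seq_len(n), function(i)
    gene_params(ln_alpha = gtab[i, 1], ln_beta = gtab[i, 2],
                ln_optimum = gtab[i, 3], sigma_omega = gtab[i, 4]))
  regulatory_network(genes, C)
}
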