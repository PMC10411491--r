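#' Height of an ultrametric tree
#'
#' @param tree an `ape::phylo` tree.
#' @return Maximum root-to-tip distance.
#' @export
tree_height <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Simulate a Yule (pure-birth) tree
#'
#' Pure-birth tree conditioned on the number of extant tips; no extinction.
#' Only relative node depths matter once the tree is rescaled to a target
#' height, so the birth rate defaults to 1. Tips are labelled `s1..sN`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed optional integer seed.
#' @return An ultrametric `phylo` tree.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("s", seq_len(n_tips))
  tree
}

#' Rescale a tree to a target height
#'
#' Multiplies every branch length by `H / height(tree)` so that all
#' root-to-tip distances equal `H` (in simulation time steps).
#'
#' @param tree a `phylo` tree with positive height.
#' @param H target height.
#' @return The rescaled tree.
#' @export
rescale_height <- function(tree, H) {
  stopifnot(inherits(tree, "phylo"), H > 0)
  h <- tree_height(tree)
  if (h <= 0) stop("tree height must be positive")
  tree$edge.length <- tree$edge.length * (H / h)
  tree
}

#' Pagel's lambda transformation of an ultrametric tree
#'
#' Multiplies all shared (internal) path lengths by `lambda` while keeping
#' every root-to-tip distance unchanged, i.e. scales the off-diagonal
#' entries of the phylogenetic covariance matrix by `lambda` and leaves the
#' diagonal alone. `lambda = 1` is the identity; `lambda = 0` yields a star
#' phylogeny. Terminal branches are extended to compensate for the
#' shortened internal ones.
#'
#' @param tree an ultrametric `phylo` tree.
#' @param lambda value in `[0, 1]`.
#' @return The transformed tree (same topology and height).
#' @export
pagel_lambda_transform <- function(tree, lambda) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  H <- max(depth[seq_len(ntip)])
  if (any(abs(depth[seq_len(ntip)] - H) > 1e-8 * max(H, 1)))
    stop("tree must be ultrametric")
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  is_tip <- child <= ntip
  new_len <- tree$edge.length
  new_len[!is_tip] <- lambda * tree$edge.length[!is_tip]
  new_len[is_tip] <- H - lambda * depth[parent[is_tip]]
  tree$edge.length <- new_len
  tree
}

#' Evolve expression traits along a phylogenetic tree
#'
#' Runs the sequential-fixation engine along every branch of the tree in
#' pre-order: the root starts at the configured initial genotype, each
#' branch evolves for `floor(branch length)` time steps, and each child
#' node inherits its parent's end state. Branch RNG seeds are drawn once
#' per node from the root seed, so results are reproducible and
#' traversal-order independent. No evolution occurs on a root edge.
#'
#' @param tree a `phylo` tree; branch lengths in simulation time steps.
#' @param config an [evolution_config()] (its `T` is ignored; branch
#'   lengths set the step counts).
#' @param seed root seed.
#' @return A `tree_tips` data.frame with one row per (tip, gene) and
#'   columns `tip`, `gene`, `ln_alpha`, `ln_beta`, `ln_R`, `ln_P`; the tree
#'   is attached as attribute `"tree"`.
#' @export
evolve_along_tree <- function(tree, config, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "evolution_config"))
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ngene <- config$network$n
  set.seed(seed)
  node_seeds <- sample.int(.Machine$integer.max - 1L, ntip + nnode)

  v <- net_vectors(config$network)
  la <- matrix(NA_real_, ntip + nnode, ngene)
  lb <- matrix(NA_real_, ntip + nnode, ngene)
  root <- ntip + 1L
  la[root, ] <- v$ln_alpha
  lb[root, ] <- v$ln_beta

  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    steps <- floor(tr$edge.length[e])
    if (steps < 1) {
      la[ch, ] <- la[p, ]
      lb[ch, ] <- lb[p, ]
      next
    }
    branch_cfg <- config
    branch_cfg$T <- as.integer(steps)
    res <- evolve_lineage(branch_cfg, seed = node_seeds[ch],
                          init = list(ln_alpha = la[p, ], ln_beta = lb[p, ]))
    la[ch, ] <- res$end$ln_alpha
    lb[ch, ] <- res$end$ln_beta
  }

  out <- do.call(rbind, lapply(seq_len(ntip), function(i) {
    gtmp <- config$network
    for (g in seq_len(ngene)) {
      gtmp$genes[[g]]$ln_alpha <- la[i, g]
      gtmp$genes[[g]]$ln_beta <- lb[i, g]
    }
    st <- steady_state(gtmp)
    data.frame(tip = tree$tip.label[i], gene = seq_len(ngene),
               ln_alpha = la[i, ], ln_beta = lb[i, ],
               ln_R = st$ln_R, ln_P = st$ln_P)
  }))
  attr(out, "tree") <- tree
  class(out) <- c("tree_tips", class(out))
  out
}

#' Write tip phenotypes as TSV
#'
#' @param tips a `tree_tips` data.frame from [evolve_along_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tips_tsv <- function(tips, path) {
  write.table(as.data.frame(tips), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
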