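---
title: "Models and methods: simulating mRNA-protein coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating mRNA-protein coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpcoevo)
```

## The scientific question

Comparative studies routinely measure gene expression as mRNA abundance
and treat it as a proxy for protein abundance, yet across species the two
are only moderately correlated and protein levels tend to be the more
conserved. One biological explanation is compensatory evolution: changes
in transcription offset by changes in translation, keeping the protein
level near an optimum while the mRNA level drifts. `mpcoevo` implements a
quantitative-genetic simulation framework in which that hypothesis can be
made precise: mutations hit a gene's transcription rate or its
per-transcript translation rate, selection sees only the steady-state
protein level, and we ask what correlation structure this induces among
replicate lineages or across the tips of a phylogeny.

## Expression model

For a single gene with transcription rate $\alpha$, per-transcript
translation rate $\beta$, and first-order degradation of mRNA
($\gamma_R$) and protein ($\gamma_P$), copy-number dynamics are
$dR/dt = \alpha - \gamma_R R$ and $dP/dt = \beta R - \gamma_P P$. Only
the equilibrium is used, which in log units is linear:

$$\ln R = \ln\alpha - \ln\gamma_R, \qquad
  \ln P = \ln\alpha + \ln\beta - \ln\gamma_R - \ln\gamma_P.$$

Degradation rates are held constant through evolution and no numerical
values for them are part of the study conditions; since they only shift
the log phenotypes by constants, the package sets
$\ln\gamma_R = \ln\gamma_P = 0$ everywhere by default, so that
$\ln R = \ln\alpha$ and $\ln P = \ln\alpha + \ln\beta$ for a single gene.
Expression noise and mutations to degradation rates are out of scope:
genotype maps to phenotype deterministically.

Because $\ln P = \ln\alpha + \ln\beta$, the across-lineage variances obey
$\mathrm{Var}(\ln P) = \mathrm{Var}(\ln\alpha) + \mathrm{Var}(\ln\beta)
+ 2\rho\sqrt{\mathrm{Var}(\ln\alpha)\mathrm{Var}(\ln\beta)}$, and the
protein level is more conserved than the mRNA level exactly when the last
two terms are negative enough. `protein_more_conserved()` evaluates this
inequality directly rather than any rearranged closed form: the direct
algebraic rearrangement gives
$\rho < -\tfrac{1}{2}\sqrt{\mathrm{Var}(\ln\beta)/\mathrm{Var}(\ln\alpha)}$,
which is attainable ($\rho \ge -1$) only while
$\mathrm{Var}(\ln\beta) < 4\,\mathrm{Var}(\ln\alpha)$, whereas a commonly
quoted version of the condition uses a factor 2. Evaluating the raw
inequality sidesteps the discrepancy; the package takes no position on
which rearrangement is intended.

### Interacting genes

For $n$ genes, gene $j$'s protein multiplies gene $i$'s realized
transcription rate by $P_j^{C_{j,i}}$ (power-law activation for
$C_{j,i} > 0$, repression for negative values). In log space the
equilibrium is a linear system in $(\ln R_i, \ln P_i)$ whose coefficient
matrix depends only on $C$; `steady_state()` solves it densely. The
power-law form does not saturate, which is a deliberate approximation:
with $|C| \le 1$ and regulator expression kept moderate by selection the
region where real activation would plateau is never visited, and the
constructor rejects $|C| > 1$. Positive-feedback parameterizations can
make the system singular (e.g. reciprocal activation with
$C_{1,2}C_{2,1} = 1$): there is then no equilibrium, `steady_state()`
raises a condition of class `mpcoevo_no_equilibrium` (detected by a
reciprocal-condition-number threshold of $10^{-12}$), and the fitness
layer maps that condition to fitness zero, so such mutations can never
fix. Because mutations only move $\ln\alpha$ and $\ln\beta$, the
coefficient matrix is constant along a lineage and is factorized once per
run.

## Evolutionary model

Evolution follows an origin-fixation (sequential-fixation) model: the
population is monomorphic, mutations are considered one at a time, and
each either fixes or is lost before the next appears. Per time step the
number of proposed mutations is Poisson with mean $2 N_e \sum U$; each
mutation hits one gene's transcription or translation with probability
proportional to its rate and perturbs the log genotypic value by a
$N(0, \sigma)$ draw. Fitness is Gaussian in the log protein level,
$\omega = \exp(-\sum_i (\ln P_i - \ln O_i)^2 / 2\sigma_{\omega,i}^2)$
over directly selected genes, the selection coefficient is
$s = \omega/\omega_A - 1$ against the current resident fitness
$\omega_A$ (updated after every fixation), and fixation probability is
Kimura's $p_f = (1 - e^{-2s})/(1 - e^{-4N_e s})$. The implementation uses
`expm1` throughout and switches to the exact neutral limit $1/(2N_e)$
when $|4 N_e s| < 10^{-8}$, so $p_f$ is continuous at $s = 0$, underflows
to zero for strongly deleterious mutations instead of overflowing, and is
clamped to $[0, 1]$.

Four regimes share this machinery. *Stabilizing* and *directional*
selection differ only in where the optimum sits relative to the start
(the directional preset uses $\ln O = 1$ with the ancestral state at 0).
The *neutral* control accepts every proposal with probability $1/(2N_e)$
— Kimura's formula at $s = 0$ — so neutral and selected runs have
identical mutational input; with an essentially flat fitness function
($\sigma_\omega \to \infty$) the selected engine reproduces the neutral
run draw for draw, which the test suite checks. For *functionally
equivalent* duplicates, fitness acts on the summed protein,
$\omega = \exp(-(\ln(P_1 + P_2) - \ln O)^2/2\sigma_\omega^2)$; the
optimum for this regime is not pinned down by the study conditions, so
the package defaults to the log of the summed ancestral protein level
($\ln 2$ for the all-zero start), i.e. the pair starts at its optimum.
This default is a documented choice, overridable via
`equivalent_optimum`.

Within a time step the Poisson-many mutations are evaluated strictly
sequentially in draw order; trajectory recording happens on step
boundaries (every `record_every = 1000` steps by default, and always at
$T$), so recording never interleaves with the within-step mutation
sequence.

### Default parameters

The defaults are the study conditions themselves: $T = 10^5$ time steps,
$N_e = 1000$, $U_\alpha = U_\beta = 5\times10^{-4}$ per gene (so
$2N_eU = 1$ mutation per trait per step and two proposals per step in
total), $\sigma_\alpha = \sigma_\beta = 0.1$ log-units,
$\sigma_\omega = 1$, $\ln O = 0$ (stabilizing) or $1$ (directional), 500
replicate lineages, and the ancestral genotype
$\ln\alpha = \ln\beta = 0$. Under these values the origin-fixation
neutral expectation is $U T = 50$ substitutions per trait and an
across-lineage variance of $U\sigma^2 t = 5\times10^{-6}\,t$, both of
which the tests verify.

### Reproducibility

Every randomized operation takes an explicit seed. Ensembles draw one
sub-seed per lineage up front from the root seed, and tree simulations
draw one sub-seed per node, so per-lineage and per-subtree results do not
depend on how many siblings were simulated or on traversal order. The
engine consumes R's own RNG stream (via the C-level API), so `set.seed()`
governs everything.

## Phylogenetic simulation

Trees are pure-birth (Yule) trees conditioned on the tip count
(`ape::rphylo` with zero extinction), rescaled so every root-to-tip
distance equals the target height ($10^5$ steps to match $T$); only
relative node depths survive the rescaling, so the birth rate is
immaterial and defaults to 1. Evolution runs along each branch for
$\lfloor\text{branch length}\rfloor$ steps, children inheriting the
parent's end state; branches shorter than one step copy the parent
exactly, and no evolution occurs on a root edge. One fixed 50-tip tree
(seed 77) ships as a plain-newick fixture for regression tests, while all
analyses accept arbitrary user trees.

Pagel's $\lambda$ transform is implemented on the tree: internal branch
lengths are multiplied by $\lambda$ and each terminal branch extended so
root-to-tip distances are unchanged, which scales the off-diagonal
entries of the phylogenetic covariance matrix by exactly $\lambda$
(verified against `ape::vcv` in the tests). When the transform is used to
probe tree-shape effects, evolution is re-simulated on the transformed
tree rather than transforming simulated data post hoc; the $\lambda$ grid
is a user choice, not a fixed constant.

## Comparative inference

`fit_bm()` and `fit_ou()` are maximum-likelihood fits of the two standard
trait models. BM has the closed-form GLS solution with covariance
$\sigma^2 V$, $V$ the shared-path-length matrix, and $k = 2$ parameters.
OU uses the fixed-root-at-$\theta$ convention — the common
`fitContinuous`-style parameterization, stated explicitly here because
the root treatment is a genuine free choice — with covariance
$\frac{\sigma^2}{2\alpha}e^{-\alpha d_{ij}}(1 - e^{-2\alpha t_{ij}})$,
$d_{ij}$ the patristic distance and $t_{ij}$ the shared time; $\theta$
and $\sigma^2$ profile out in closed form at fixed $\alpha$, and $\alpha$
is optimized on a 40-point log grid over $\alpha H \in [10^{-8}, 50]$
with local refinement, ties broken toward smaller $\alpha$. As
$\alpha \to 0$ the OU likelihood converges to BM's, so the fitted OU
log-likelihood is never meaningfully below BM's; the suite enforces this
to an optimizer tolerance of $10^{-4}$. AICc is
$-2\ell + 2k + 2k(k+1)/(n-k-1)$ with Akaike weights normalized within a
comparison set.

Measurement error is deliberately *not* part of the default likelihood —
reproducing the practice whose consequences are under study — but both
fitters accept a known `error_var` added to the covariance diagonal so
the error-aware contrast can be run. Injected measurement error adds
independent $N(0, \sigma_\epsilon)$ noise to $\ln R$ and $\ln P$ and
defines the "measured" translation rate as their ratio, so its error is
anticorrelated with the mRNA error by construction — the statistical
artifact that can mimic compensatory evolution.

The evolutionary correlation between two traits is computed from
phylogenetically independent contrasts (correlation through the origin),
which for bivariate BM on a common tree coincides with the ML rate-matrix
correlation and reduces to the ordinary Pearson correlation on a star
tree — chosen for its closed-form testability over an equivalent
numerical GLS fit. Two regression slopes exist on a tree and they differ
substantially here: the ordinary tip-level OLS slope of $\ln\beta$ on
$\ln R$ stays near the replicate-lineage value ($\approx -0.97$) because
it ignores shared history, while the phylogenetic
(contrasts-based) slope is noticeably weaker ($\approx -0.79$), the
tree's shared history shrinking the effective sample. `phylo_regression()`
returns both, labeled. Pairwise divergence time in the
divergence-versus-time table is $2(H - \text{depth of the MRCA})$ — twice
the time since the common ancestor, stated explicitly since the factor of
two is a convention.

## What the generator does and does not emulate

The simulator generates monomorphic-lineage trajectories under the exact
study conditions: Poisson mutational input, no pleiotropy (a mutation
hits transcription or translation of one gene, never both), no linkage,
no standing variation, no expression noise, constant degradation rates,
and a deterministic genotype-phenotype map. Passing tests therefore
demonstrate the *evolutionary* mechanism — compensation induced purely by
selection on protein level — and the *statistical* artifacts of
ratio-based translation estimates and unmodeled error. They do not speak
to concurrent polymorphism (the sequential-fixation approximation needs
$2N_eU$ small), saturating regulatory kinetics, resource ceilings on
expression, or gene-specific parameter heterogeneity in real data.

## Numerical and design choices

- **Problem sizes.** The packaged analyses scale replicate counts to desk
  runtimes: 150-500 lineages where the full study used 500, 20 replicate
  tree simulations, and 20 genes x 300-400 lineages for the
  multi-optimum experiment. The multi-optimum variance-versus-distance
  correlation needs the larger per-gene counts: with only ~100 lineages
  the per-gene variance estimates carry ~14% sampling error, which alone
  caps the attainable correlation near 0.975.
- **Optimum distribution.** The 20 optima are drawn from a centred
  normal whose scale is read as variance 2 (SD $\sqrt2$); the notation is
  ambiguous between SD and variance conventions, so `optimum_sd` is an
  explicit argument and either reading is one call away.
- **Singularity handling.** Grid scans never abort on a singular cell:
  the cell is reported as missing with a reason. In practice the engine
  cannot enter the singular region because such proposals have fitness
  zero.
- **Degenerate inputs.** Zero-variance traits give flagged `NA`
  correlations and zero-rate BM fits rather than errors; zero-length
  branches copy states exactly; a tree of zero height cannot be rescaled.
- **Ties and tolerances.** Steady-state residuals are checked to
  $10^{-10}$ in the tests; OU/BM nesting to $10^{-4}$; the OU $\alpha$
  grid tie-break prefers the simpler (smaller-$\alpha$, more BM-like)
  explanation.

## Known limitations

Sequential fixation is an approximation valid at low mutation supply;
raising $U$ or $N_e$ far beyond the defaults would demand a
polymorphism-aware engine. The OU fitter deliberately mirrors standard
practice (fixed root, no error term by default) rather than implementing
every variant in the literature; only BM and single-optimum OU are
compared. The power-law interaction model is linear in log space and so
cannot represent saturating or combinatorial regulation, and interaction
parameters are restricted to $|C| \le 1$.
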