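---
title: "Models and methods behind archevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind archevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`archevol` studies how branching architecture evolves in a clade of
rainforest treelets: it quantifies the gradient from monocaulous
(single-stemmed) to well-branched species, asks whether that gradient and
other functional traits carry phylogenetic signal, whether traits covary
with architecture once phylogeny and measurement error are accounted for,
what the ancestral architecture was, and whether architecture changed
diversification. This vignette documents the models, their assumptions,
the tunable parameters, and the numerical and design choices — in enough
detail that every default can be judged and overridden.

## Branching indexes and architectural classes

Photosynthetic function is approximated by leaf area and exploration by
stem length, so the two raw indexes are branch shares of those totals:

- photosynthetic index = branch-borne leaf area / total leaf area,
- exploration index = branch cumulated length / total stem length.

Both are unit-free ratios in `[0, 1]` (0 for a monocaulous plant), and
invariant under a common rescaling of all lengths or areas. When only
representative branches are measured, per-branch means are extrapolated
to the branch census (`mean x count`), matching how whole-plant totals
are tabulated from partial measurements. The degenerate case of branches
with a zero-length trunk returns an exploration index of 1 with a
warning; a plant with no leaves at all has no defined photosynthetic
index and errors.

The *integrative* index is PC1 of the two species-mean indexes after
z-scoring (a correlation-matrix PCA of a 2-column table). The PC1 sign is
fixed so both loadings are positive — higher score always means more
branched — with the tie broken toward a positive photosynthetic loading.
The Spearman correlation of the two raw indexes is reported alongside,
because the index is only a useful one-dimensional summary when the two
functions covary strongly. Species-mean PCA defines the axis; individual
measurements are projected onto that fixed axis
(`scoreIndividuals()`) for the class segregation, so classes are decided
on individual-level evidence while the axis itself is stable.

**Segregation.** Species are ranked by mean score; every species pair is
compared by a two-sample Wilcoxon rank-sum test. The test is two-sample
(not the signed-rank variant) because per-species samples of distinct
species share no pairing structure; `stats::wilcox.test` supplies the
exact null for small untied samples and the tie-corrected normal
approximation otherwise. Significant pairs at `alpha` (default 0.1)
enter a compact letter display built by the insert-and-absorb algorithm.
A *break* is an adjacent ranked pair sharing no letter; classes are the
`k` contiguous runs delimited by the `k - 1` strongest breaks, where
strength is the pair's p-value with ties broken by the larger score gap.
The gap tie-break matters in practice: with five individuals per species
the exact Wilcoxon p floors at `2/choose(10, 5)`, so several breaks can
tie at the floor, and the score gap then separates between-class
boundaries from within-class jumps. If fewer than `k - 1` significant
breaks exist the best available partition is returned with a warning.
Class labels (Monocaulous / Intermediate / Branched) are attached only
when exactly three classes are recovered; otherwise neutral ordinal
labels are used.

**Derived traits.** `deriveTraits()` computes the 14-trait functional
set (slenderness ratio, wood/stem specific densities, internode
dimensions, tissue proportions, Huber value, leaf traits, total leaf
area, leaf number, fruit volume) from raw primitives, with one reading
choice worth flagging: the internode-diameter entry is tabulated as
"min diameter x max diameter", which has area units; it is read here as
the geometric mean `sqrt(min x max)`, the natural diameter-unit summary.
Fruit volume is `length x width^2`, the standard prolate approximation.
A zero denominator yields `NA` for that trait alone, with a message —
never a global failure. Tissue areas must close to within 1% of the
whole section.

## Phylogenetic signal with intraspecific variation

Species means carry sampling error `s_i^2 / n_i`, so both statistics use
the observation model `x ~ N(a 1, sigma2 * C_lambda + D)` where `C` is
the Brownian covariance (shared root-to-MRCA path lengths), `C_lambda`
multiplies its off-diagonals by Pagel's lambda, and
`D = diag(s_i^2 / n_i)`.

**Pagel's lambda** is fitted by ML, profiling `sigma2` at each lambda
(closed form when `D = 0`, one-dimensional optimization otherwise) and
maximizing over `lambda` in `[0, 1]`. The search is bounded at 1 by
default for interpretability; `unbounded = TRUE` extends to the
matrix-feasible maximum for users who want the unconstrained ML value
(estimates slightly above 1 are commonplace in small-tree empirical
tables). The p-value is a likelihood-ratio test against `lambda = 0`
referred to a 50:50 mixture of chi-squared with 0 and 1 degrees of
freedom, the standard correction for a null on the parameter boundary.

**Blomberg's K** is the observed ratio `MSE0 / MSE` over its Brownian
expectation, with `MSE0` from deviations around the phylogenetic (GLS)
mean, `MSE` from covariance-whitened deviations, and expectation
`(tr(V) - n / (1' V^-1 1)) / (n - 1)`. With intraspecific variation the
working covariance is the error-adjusted `V = C + D / sigma2_hat`,
`sigma2_hat` being the ML Brownian rate — a documented interpretation of
"K considering intraspecific variation", validated by simulation (the
no-error case agrees with the established `phytools` implementation to
machine precision, which the tests assert). Significance is a tip-label
permutation test, permuting the trait together with its sampling
variance, p inclusive: `(1 + #{MSE_perm <= MSE_obs}) / (1 + nperm)` with
999 permutations by default (at least 99 enforced); `sigma2_hat` is held
fixed across permutations. Under Brownian motion K is centred near 1,
with a noticeable downward finite-sample spread on small or imbalanced
trees — which is why complementary use of lambda and K is sensible on
clades of a few dozen species.

## Bivariate phylogenetic regression

Trait–architecture correlations are fitted as a bivariate Brownian model
in which both variables carry intraspecific variation: stacking x and y,
the covariance is `[[sx2 C + Dx, r sx sy C], [r sx sy C, sy2 C + Dy]]`
and the evolutionary slope is `beta = r * sy / sx`. The fit is direct ML
on the `2n`-dimensional normal — no EM — because with at most a few
hundred species the dense Cholesky solve is fast, transparent and easy
to test. The two means are profiled out by GLS at every parameter value;
free parameters are the two log rates and `atanh(r)`, optimized by
multi-start L-BFGS-B (5 restarts by default), one start being the
constrained `r = 0` solution so the full fit can never fall below the
nested model. The constrained model factorizes into two univariate BM
fits and is solved that way. Significance is the likelihood-ratio test
against the slope-zero fit on one degree of freedom, negative statistics
clipped to zero with a warning. `correlationTable()` assembles one fit
and test per trait, dropping missing species per trait (and saying so);
no multiplicity correction is applied by default because raw per-trait
p-values are the primary output, with a Holm option available. The
covariance kernel is pure Brownian (`lambda = 1`); profiling lambda
inside the regression is deliberately out of scope.

## Mk models and ancestral states

The three-state architectural character evolves under a continuous-time
Markov model with generator `Q` constrained as ER (one rate), SYM (three
symmetric rates) or ARD (six rates). The likelihood is Felsenstein
pruning with per-edge `exp(Q t)` (eigendecomposition computed once per
`Q`, scaling-and-squaring fallback for near-defective generators),
per-node rescaling against underflow, polytomies handled natively by the
product over children, and a root prior that defaults to uniform —
matching the convention of the ML ancestral-state tools this analysis
follows — with a stationary-distribution option. Unknown tip states
enter as uniform partial likelihoods.

Rates are fitted in log space under box constraints `[1e-8, 1e3]`. A
coarse profile over a common rate magnitude chooses the starting scale
before L-BFGS-B runs: the likelihood is flat in the saturated high-rate
regime, and a box-constrained quasi-Newton started in the wrong basin
can otherwise terminate on the boundary plateau. A single observed state
yields a flat likelihood; the fit then returns boundary rates with a
warning rather than failing.

Marginal ancestral probabilities combine the downward pruning pass with
an upward pass (equivalent to rerooting at every node); each node's
vector is normalized to sum to one, and the root vector equals the
prior-weighted root conditional of the likelihood pass. Model choice is
by AICc with `n =` number of tips — the natural sample unit for a single
character, stated explicitly because AICc's `n` is genuinely ambiguous
for phylogenetic data — and exact ties break toward fewer parameters.

## State-dependent diversification (MuSSE)

The joint likelihood of tree and tip states integrates, per branch, the
coupled ODEs for `E_i(t)` (probability a lineage in state `i` at time
`t` before the present leaves no sampled descendants) and `D_i(t)` (the
density of the observed subtree):

```
dE_i/dt = mu_i - (lam_i + mu_i + sum_j q_ij) E_i + lam_i E_i^2 + sum_j q_ij E_j
dD_i/dt = -(lam_i + mu_i + sum_j q_ij) D_i + 2 lam_i E_i D_i + sum_j q_ij D_j
```

Integration is an adaptive Dormand–Prince 5(4) stepper in compiled code
(relative tolerance 1e-8, absolute 1e-10 per branch), with a
`deSolve::lsoda` fallback if step-size control fails — the MuSSE system
is rarely stiff at biologically plausible rates, but the fallback makes
the likelihood total. At internal nodes
`D_i <- lam_i D_i(left) D_i(right)` with per-node renormalization (the
bookkeeping is auditable: a switch disables renormalization and the
tests confirm identical likelihoods on small trees). The root uses
FitzJohn state weighting (`w_i` proportional to `D_i`) by default with a
flat-weights option, and survival conditioning
(dividing by the weighted `lam_i (1 - E_i)^2`) is off by default — both
defaults follow the cited reference implementation, are switchable, and
are recorded in every output. Complete sampling is assumed (the study
clade is fully sampled); a sampling-fraction extension is deliberately
out of scope. Polytomies are rejected with a clear error rather than
resolved silently.

The model family comprises the 15 constraint patterns over equal /
distinct / zero rates — the full 12-parameter model, the 3-parameter
equal-rates model, intermediate patterns, the three 2-class speciation
groupings with and without extinction, and the 2-parameter equal-rates
pure-birth model. Fitting is multi-start ML in log-rate space with
birth–death moment starts; the family is fitted simple-to-complex and
richer models are warm-started from the projected rates of the
best-fitting simpler models, which both speeds convergence and
stabilizes the likelihood monotonicity the nesting structure implies.
AICc again uses `n =` tips, the assumption made explicit because no
alternative is defensible at 27 tips.

## Ordination and PERMANOVA

The trait-space PCA is correlation-matrix PCA of species means (the
branching index excluded), with constant traits dropped and a
deterministic sign convention (largest-magnitude loading positive per
component). PERMANOVA uses Euclidean distances on z-scored traits — the
minimal distance choice consistent with a correlation-scaled PCA of the
same matrix — partitions the squared-distance matrix into among/within
class sums of squares, and permutes class labels freely (no strata),
999 permutations by default with inclusive p-values. Species with
missing trait values are dropped listwise, with a log message — the same
mechanism an empirical study uses when a rare species lacks a trait.

## The synthetic study: what it emulates and what it does not

No tree or raw trait data are deposited for the motivating system, so
the generators define the study conditions the package is tested under:

- a 27-species ultrametric crown clade of age 2.4 Myr (birth rate 1.1
  per Myr, chosen so expected richness at that age is about 27;
  extinction 0 by default). Conditioned-on-`n` trees come from the exact
  conditioned sampler in `ape::rphylo` rather than rejection sampling —
  an exact algorithm exists, so the simpler rejection design was dropped
  for the `n`-conditioned case and retained for fixed-horizon simulation
  and for the joint MuSSE simulator, where no packaged exact sampler
  exists;
- architectural classes of sizes 7 Monocaulous / 6 Intermediate / 14
  Branched, placed on the tree by ranking a Brownian liability so the
  discrete character carries phylogenetic signal;
- class-level index targets (photosynthetic / exploration) of 0.03/0.16,
  0.36/0.45 and 0.82/0.76 for the three classes — the field-reported
  class means this generator is calibrated to;
- species targets drawn from beta distributions around the class means
  (bounded support, hence beta rather than a truncated normal), with a
  Gaussian copula correlating a species' photosynthetic and exploration
  deviations, and individual values again beta-distributed around the
  species target. The two dispersion knobs were calibrated once:
  species-level concentration 80 and copula correlation 0.4 put the
  cross-species Spearman correlation of the two indexes at about 0.86
  (the empirical anchor) and make the three classes recoverable by the
  segregation procedure in essentially every seed. Looser dispersion
  (concentration near 30) reproduces the correlation but blurs the
  class boundaries enough that exact recovery drops well below the
  target, so it does not represent the reported class structure;
- measurements constructed so the computed indexes reproduce the drawn
  index values exactly: a lognormal trunk, a class-dependent branch
  census, two representative measured branches, and class-dependent
  leaf sizes (monocaulous species get few large leaves, branched
  species many small ones);
- 14 functional traits as Brownian motion (rate 0.5, lambda 1, 5
  replicates per species with residual SD 0.4), a subset of which
  (slenderness ratio, internode diameter, wood proportion, Huber value,
  mean leaf area, SLA, leaf number, fruit volume) get nonzero slopes
  against the scaled branching liability with signs following the
  field expectation.

What the generator does *not* emulate: real leaf and wood anatomy,
allometry, ontogenetic standardization, herbarium measurement error for
fruits, non-Brownian trait evolution, or diversification that actually
depends on architecture (the default MuSSE truth is state-independent).
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the stated generating models — not that any
biological conclusion about a particular clade is reproduced.

## Numerical choices and test scale

- Likelihood comparisons use a 1e-6 tolerance on nesting inequalities;
  oracle equivalences (pruning vs enumeration) hold to 1e-10 and the
  MuSSE/birth-death closed-form agreement to 1e-5 at the default
  integrator tolerances.
- Optimizers: L-BFGS-B in log-rate (or atanh-correlation) space
  throughout; seeded multi-start; convergence flags are carried in every
  fit object rather than silently dropped.
- Permutation p-values are always inclusive (`+1` correction), so 0 is
  impossible and calibration under the null is uniform on a discrete
  grid.
- The test suite runs its simulations at deliberately moderate sizes —
  e.g. 100-tip trees for lambda recovery, 200 tips for Mk rate recovery,
  27 tips and tens of replicates for MuSSE model selection, 500
  replicates for permutation-calibration checks — chosen as the smallest
  scales at which the distributional claims are stable, so the whole
  suite stays fast enough to run routinely.

## Known limitations

- The lambda search is bounded to `[0, 1]` by default; unbounded
  estimates are available but can exceed 1 only within matrix
  feasibility.
- The error-adjusted Blomberg K is an interpretation (see above), not a
  published closed form; treat cross-study comparisons of its absolute
  value with care.
- MuSSE at 27 tips has little power: the family machinery is exact, but
  model selection mostly expresses the AICc penalty at that size, as the
  equal-rates selection results illustrate.
- The PGLS kernel is Brownian only; OU or early-burst covariances and
  multi-predictor regressions are out of scope.
- `AICc`'s `n` is taken as the number of tips in both the Mk and MuSSE
  analyses; other conventions exist and would shift absolute AICc values
  (but rarely rankings) at this clade size.
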