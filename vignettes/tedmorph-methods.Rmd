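---
title: "Models and methods in tedmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tedmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedmorph)
```

# Scope

`tedmorph` implements Bayesian total-evidence tip dating restricted to
*continuous* morphological characters: a multivariate phylogenetic
Brownian-motion (BM) likelihood with intraspecific variance, linear
shrinkage estimation of among-character correlations, fossilized
birth–death (FBD) and birth–death-sequential-sampling (BDSS) tree priors
with forward simulators, a Metropolis–Hastings sampler over trees (node
ages, topology, sampled-ancestor attachments) and model parameters, and
the landmark preprocessing used upstream of such analyses (generalized
Procrustes superimposition, metric MDS). Discrete-morphology and
molecular likelihood components, and marginal-likelihood model comparison,
are deliberately out of scope.

# The continuous-character model

Tip values of $k$ characters on $n$ sampled taxa are modelled as one draw
from a multivariate normal distribution
$$\mathrm{vec}(M) \sim \mathcal N\!\big(y_0 \otimes 1,\; V\big),
\qquad V = T \otimes \Sigma \;(+\, I_n \otimes v_{\mathrm{err}}),$$
where

* $T$ ($n \times n$) is the phylogenetic covariance: entry $(u, w)$ is the
  rate-weighted shared path length from the root to the most recent common
  ancestor of $u$ and $w$, $t_{uw} = \sum_{z} c_m b_z z$ over branches $z$
  on the shared path, with global rate $c_m > 0$ and per-branch relative
  rates $b_z$ (all 1 under a strict clock, i.i.d. log-normal under the
  relaxed clock);
* $\Sigma$ ($k \times k$) is the among-character covariance,
  $\Sigma = \mathrm{diag}(r)\,\rho\,\mathrm{diag}(r)$ with relative
  character rates $r$ and correlation matrix $\rho$ (so $\Sigma = \rho$
  when all $r_i = 1$), or equivalently $\Sigma = L L^\top$ with an
  upper-triangular factor $L$ — the parameterization used when $\Sigma$ is
  estimated by MCMC, because any $L$ with non-zero diagonal yields a valid
  covariance;
* $v_{\mathrm{err}}$ ($k \times k$) is the intraspecific (tip-error)
  covariance $\mathrm{diag}(\sigma)\,\rho\,\mathrm{diag}(\sigma)$, added to
  each taxon's own diagonal block only. Normalizing each character by its
  estimated intraspecific standard deviation (`normalize_by_sd()`) reduces
  this increment to $\rho$ itself.

By default the likelihood functions start the BM process at the root of
the tree (`root_edge_time = 0`), the classic comparative-methods
convention. The sampler, however, runs the model with an *origin branch*
for the trait process: the root state is
$N(y_0, (x_0 - t_{\mathrm{root}})\,c_m\,\Sigma)$ rather than exactly
$y_0$. The reason is propriety, not taste: a fossil collapsed as a
sampled ancestor *at the root* observes the root state exactly; if that
state is deterministically $y_0$, the data contain an exact copy of a
fixed parameter, and the posterior density diverges (non-integrably) as
the fossil's attachment branch shrinks to zero — chains visibly freeze in
the spike. Diffusing the root state over the origin branch removes the
coincidence and makes every configuration's density proper, while leaving
the likelihood contract unchanged for users who keep the default.

## Three likelihood routes

`dense_loglik()` builds $V$ explicitly and evaluates the MVN density —
cubic cost, used as the in-package oracle. `pruning_loglik()` offers two
linear-time routes that only ever factorize the $k \times k$ matrix
$\Sigma$:

* `"felsenstein"` — post-order Gaussian message passing carrying a
  conditional mean, a $k \times k$ covariance and an accumulated
  log-density per node (C++/Armadillo). This is the multivariate
  generalization of the classic three-quantity contrast recursion.
* `"general"` — the intermediate-coefficient recursion: each node
  propagates the quadratic coefficients $(A, b, c)$ of its subtree
  log-likelihood as a function of the ancestral state; branches transform
  them through an explicit Gaussian integral, and the root evaluates (or
  maximizes, for profiled root values) the final quadratic.

Sampled ancestors are merged into their attachment node and treated as
*exact* observations of an internal state (a Gaussian message with zero
covariance), which both routes handle without epsilon-jitter. With
profiled root values (`y0 = "ML"`), the optimizer is the pruning byproduct
(the root's conditional mean) and equals the GLS estimate
$(1^\top T^{-1} M)/(1^\top T^{-1} 1)$ per character when no tip error is
present.

Degenerate corner: when a sampled ancestor sits at the root itself, its
trait value observes $y_0$ exactly; the dense route then reports a
singular covariance while the pruning routes return the correct profiled
density. Tests compare routes only on instances where the dense oracle is
defined.

A singular $\Sigma$ (e.g. duplicated, perfectly correlated characters)
raises a typed condition (`tedmorph_singular_error`); the MCMC layer
converts it into proposal rejection.

# Shrinkage estimation of $\rho$

From $m$ conspecific individuals, `estimate_variances()` and
`estimate_correlation()` give the unbiased variances and the sample
correlation $\hat\rho$, whose rank is at most $m - 1$; whenever
$k > m - 1$ the estimate is singular and the likelihood cannot be
evaluated. `ridge_shrink()` applies the archetypal linear ridge
$\rho^* = \delta I + (1 - \delta)\hat\rho$. The shrinkage weight is chosen
by `choose_delta()`: a deterministic grid search
($\delta \in \{0.01, \dots, 0.99\}$) scoring each candidate by
leave-one-out cross-validated Gaussian log-likelihood of held-out
individuals (ties break toward more shrinkage). The optimization procedure
behind the published estimator lives in literature we do not reproduce;
grid LOOCV was chosen as a simple, deterministic, testable surrogate, so
numerical values of $\delta$ are method-dependent. The shrinkage target is
the identity matrix; alternative targets are out of scope.

# Tree models

Both tree processes share rates $\lambda$ (speciation), $\mu$
(extinction), $\psi$ (Poisson fossilization along lineages) and the extant
sampling probability $\rho_s \in (0, 1]$, starting from one lineage at the
origin time $x_0$ and conditioning on at least one sample.

The FBD log-density uses the standard sampling-through-time closed forms
$p_0(t)$ (no sampled descendants) and $q(t)$ (per-branch factor), assembled
per event: $2\lambda\,q(x)$ per bifurcation, $\psi\,p_0(y)/q(y)$ per fossil
tip, $\psi$ per sampled ancestor, $\rho_s$ per extant sample, $q(x_0)$ for
the origin branch and $1/(1 - p_0(x_0))$ for survival. The factor
$2\lambda$ (not $\lambda$) per bifurcation makes this the density over
*labelled* trees — each split's two daughter assignments generate the same
labelled tree — and matters wherever the bifurcation count varies, exactly
the sampled-ancestor moves. We verified this convention three ways:
numerical integration of the two-state (fossil tip vs. sampled ancestor)
system, forward simulation frequencies, and prior-only MCMC.

The BDSS derivation is published only in supplementary material we do not
have; the package defines the BDSS density over left-to-right-oriented
trees (ties in tip times broken by simulation event order) as the labelled
density minus $B \log 2$ with $B$ bifurcations, which reduces to the FBD
density up to that documented constant when $\psi = 0$. Its direct
simulator draws by bounded-rejection forward simulation conditioned on the
requested extant/fossil sample counts. The coherence of each
simulator–density pair is validated by the same strategy throughout:
forward draws conditioned on a tip configuration are compared (root-age
Kolmogorov–Smirnov, sampled-ancestor frequencies) against prior-only MCMC
under the corresponding log-density with fossil ages, attachments and
sampled-ancestor status all sampled.

Conditioning is always on the origin time plus survival; the exact
conditioning used in the original analyses is a supplement-level detail,
and this choice is the simplest well-defined one.

# MCMC

A single-chain Metropolis–Hastings sampler (`run_chain()`) with a
fixed-weight mixture of moves: multiplicative scalers for positive scalars,
a reflected walk for $\rho_s$, element walks for $L$, uniform node-age
moves, a root-height multiplier, a whole-tree age scaling (with the
Jacobian $m \log f$ for the $m$ scaled nodes), a joint rate–height
multiplier that travels along the $c_m \times$ tree-height ridge,
constrained nephew–uncle exchanges for topology (Hastings ratio =
candidate-set size ratio), a reversible sampled-ancestor toggle (collapse
a fossil tip to a zero-length attachment / re-expand with a uniform
attachment age, Hastings ratio $1/(u - y)$ and its inverse), a fossil
prune-and-regraft that re-inserts a fossil tip on a uniformly chosen
compatible edge (the candidate set is counted on the detached tree, which
is direction-invariant, so only the attachment-interval lengths enter the
Hastings ratio), and optional fossil-age moves used for prior validation
(empirical fossil ages are data and stay fixed).
Monophyly constraints and a fixed extant subtopology are enforced by
rejection. Proposal weights are configuration, not inference: any choice
leaves the stationary distribution unchanged, which the prior-coherence
tests check directly.

Summaries follow the field's conventions: shortest-window HPD intervals,
ESS via Geyer's initial-positive-sequence truncation, 10% burn-in by
default, ESS ≥ 200 as the convergence criterion, and
maximum-clade-credibility trees with per-clade posterior support and
node-age HPDs.

# Synthetic data and what a green test establishes

`simulate_bm()` draws characters branch-by-branch down the tree (so
sampled ancestors observe internal states exactly), `simulate_wn()` draws
tree-free i.i.d. rows, and `blend()` mixes them with weight $w$
($M = (1-w) M_{WN} + w\,M_{BM}$; $w = 1$ is pure BM). The white-noise
mean defaults to the BM root values and its variance to the average BM tip
variance, so mixtures vary *signal structure*, not scale; the source
analyses leave the WN parameterization unstated, and this default is our
documented choice. `simulate_individuals()` draws conspecific replicates
around species means.

The calibration study (`coverage_study()`) is the package's strongest
correctness instrument: parameters drawn from priors, data simulated from
them, inference under the same priors — 95%-HPD coverage must then be
binomially distributed around 95% *if and only if* every factor
(likelihood, tree prior, Hastings ratios) is mutually consistent. Its
stated world is deliberately desk-scale: origin at 2 time units,
$\lambda \sim \mathrm{LN}(\log 1, 0.15^2)$,
$\mu \sim \mathrm{LN}(\log 0.3, 0.3^2)$,
$\psi \sim \mathrm{LN}(\log 0.7, 0.3^2)$, complete extant sampling, four
characters with factor elements
$L_{ii} \sim \mathrm{LN}(0, 0.1^2)$,
$L_{ij} \sim \mathrm{N}(0.5, 0.5^2)$ truncated to $[-1, 1]$,
root values standard normal, and focal rate
$c_m \sim \mathrm{LN}(0, 0.5^2)$. Nuisance parameters are conditioned on
their drawn truths during inference — conditioning on quantities drawn
from the prior preserves calibration for the focal parameter — and trees
are redrawn until they carry 2–16 samples, an event measurable from the
tip configuration the sampler conditions on, hence also
calibration-neutral. Replicates whose focal ESS falls below 200 get one
extension attempt with a three-fold longer chain and are excluded (and
reported) if still unconverged; chain length, not the world, is the knob
turned for convergence. A green coverage test establishes joint consistency of the
implementation at this scale; it does not establish mixing or
identifiability at empirical scale (dozens of taxa, $k \approx 87$), nor
robustness to model misspecification, which `accuracy_study()` probes
qualitatively instead.

# Morphometrics

Generalized Procrustes superimposition iterates translation to the
centroid, scaling to unit centroid size, and SVD rotation onto the running
mean until the mean configuration changes by less than $10^{-10}$;
reflections are allowed by default (the source is silent). Aligned
specimens flatten to a $3L$-column character matrix and are normalized by
per-coordinate intraspecific variances. `mds_embed()` implements SMACOF
majorization of raw metric stress with seeded multi-starts (classical
scaling plus random configurations); raw and normalized (Kruskal-type)
stress are both reported because the stress variant used originally is
unstated.

# Numerical choices and limitations

* All likelihoods in log space; only $k \times k$ factorizations inside
  pruning; the $nk \times nk$ covariance exists only in the dense oracle.
* The general pruning route requires $v_{\mathrm{err}}$ to be zero or
  positive definite; the Felsenstein route accepts any PSD tip error.
* Missing character values are unsupported (no stated missing-data
  mechanism).
* Tie-breaks: taxon order is lexicographic everywhere; $\delta$ grid ties
  shrink more; BDSS orientation ties follow event order.
* Single-sample trees are represented with a degree-1 origin root and are
  excluded from tree moves.
* OU/early-burst/trend processes, per-character branch rates, skyline
  rates, diversified sampling, and multi-species pooling of replicate
  tables are out of scope.
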