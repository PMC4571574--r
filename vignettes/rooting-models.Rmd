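---
title: "Rooting phylogenies with non-reversible and non-stationary models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting phylogenies with non-reversible and non-stationary models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloroot)
```

## The problem

Under a stationary, time-reversible substitution model the likelihood of a
phylogeny does not depend on where the root is placed (Felsenstein's pulley
principle), so ordinary Bayesian or ML tree inference returns an effectively
unrooted tree.  Rooting then requires external information, classically an
outgroup, which invites long-branch attraction.  phyloroot implements two
substitution models whose likelihood *is* informative about the root, so the
root position can be sampled as part of an ordinary MCMC:

* **NR** keeps stationarity and across-branch homogeneity but drops
  reversibility.  The instantaneous rate matrix is an HKY85 core with two
  multiplicative perturbations on the log scale,

  $$q_{ij} = \pi_j\,\kappa_{ij}\,
      e^{\varepsilon_R\{i,j\}}\,e^{\varepsilon_N(i,j)},\qquad i \ne j,$$

  where the six $\varepsilon_R$ (one per unordered pair) open up the full
  GTR structure and the twelve $\varepsilon_N$ (one per ordered pair) the
  fully general non-reversible form.  Hierarchical scales
  $\sigma_R, \sigma_N$ control the perturbation sizes; posterior support for
  $\sigma_N > 0$ is direct evidence of non-reversibility, and it is this
  directionality that carries the rooting signal.  The matrix is normalized
  to mean rate one under its own stationary distribution, which is also the
  root distribution.

* **HB** keeps per-branch reversibility (GTR with shared exchangeabilities
  $\rho$) but drops stationarity and across-branch homogeneity: every branch
  not adjacent to the root carries its own composition vector $\pi_b$, while
  a single composition is shared by the root and the two branches on either
  side of it.  With $n$ taxa there are exactly $2n-4$ free branch
  compositions plus the root composition, so the dimension is fixed.  The
  rooting signal here is non-stationarity: sequence composition drifts over
  the tree, and the root is the point the drift radiates from.

Both models admit among-site rate variation through a discrete-gamma with
`K` equal-probability categories (category rates are conditional means,
renormalized to average exactly one; `K = 1` switches it off).

## Priors

All priors are proper and configurable through `prior_spec()`:

| parameter | prior | default |
|---|---|---|
| $\pi$ (NR core) | Dirichlet(1,1,1,1) | — |
| $\log\kappa$ | Normal(0, 1) | — |
| $\varepsilon_R \mid \sigma_R$ | iid Normal(0, $\sigma_R^2$) | — |
| $\varepsilon_N \mid \sigma_N$ | iid Normal(0, $\sigma_N^2$) | — |
| $\sigma_R, \sigma_N$ | Exponential | mean 0.25 |
| $\alpha$ (gamma shape) | Exponential | mean 1 |
| $\rho$ (HB) | 6 iid Exponential(mean 1), mean-normalized | — |
| root composition (alr) | Normal(0, $5^2 I_3$) | — |
| $a_b \mid a_{\mathrm{parent}(b)}$ | Normal($a_{\mathrm{parent}(b)}$, $s^2 I_3$) | — |
| $s$ | Exponential | mean 0.5 |
| branch lengths | iid Exponential | mean 0.1 subst./site |
| rooted topology | uniform | — |

Compositions are handled in additive-log-ratio coordinates
$a = (\log \pi_A/\pi_T, \log \pi_C/\pi_T, \log \pi_G/\pi_T)$; the HB
composition prior is a Gaussian random walk over the branch hierarchy, so
neighbouring branches share more information than distant ones, which is
what keeps the branch-heterogeneous model identifiable in practice.  The
mean-normalized exchangeabilities are uniform on the mean-one simplex (iid
exponentials normalized by their mean are Dirichlet(1,...,1) up to scale).

The prior hyperparameters are package defaults, stated here rather than
inherited from anywhere; every one of them can be overridden per run, and
the run configuration records them.

## The sampler

`run_mcmc()` is a random-scan Metropolis–Hastings sampler over rooted
topology, branch lengths and all model parameters.  Default move weights
are 40% branch-length multipliers, 20% topology (rooted NNI and re-rooting
on a uniformly chosen edge, with the root position resampled uniformly
along the target edge), 40% parameter moves.  All scalar walks run on
unconstrained scales (log for positive parameters, alr for compositions);
multiplier moves contribute $\log m$ to the Hastings ratio; Gaussian walks
use a small/medium/large step-size mixture.

Three less standard moves matter for correctness and mixing, and each was
added because a generic kernel provably fails on this posterior:

* **Funnel rescale moves.**  The $(\sigma, \varepsilon)$ hierarchies (and
  $(s, \text{alr increments})$ for HB) form funnels: at small $\sigma$ the
  conditional prior pins $\varepsilon$ near zero and componentwise walks
  cannot re-enter or leave the neck.  A joint move proposes
  $\sigma' = m\sigma, \varepsilon' = m\varepsilon$ (Jacobian $m^{d+1}$),
  which travels along the funnel axis.  Without it, a constant-likelihood
  run visibly fails to reproduce the $\sigma_N$ prior marginal.

* **Ridge Gibbs moves (NR).**  $\kappa$ and the two transition entries of
  $\varepsilon_R$ enter the rate matrix only through their product, as do an
  unordered $\varepsilon_R$ entry and the two ordered $\varepsilon_N$
  entries of the same pair.  The likelihood is exactly constant along these
  ridges and the prior conditional along them is Gaussian, so the shift is
  drawn as a Gibbs step.  This is what makes the $\kappa$ marginal mix; the
  reported $\kappa$ posterior is then the prior-structured attribution of
  the observed transition rate between $\kappa$ and the perturbations.

* **Composition bookkeeping under root moves (HB).**  Compositions travel
  with their edges through NNI and re-rooting; an edge that becomes
  root-adjacent surrenders its composition, and an edge that stops being
  root-adjacent needs one.  Two variants are mixed 50/50: a *fresh* draw
  from the conditional prior (forward and reverse densities folded into the
  Hastings ratio), and a deterministic *swap* in which the newly rooted
  edge's composition becomes the root composition while the merged old-root
  edge inherits the previous root composition (a measure-preserving
  bijection, so only the length-repartition term enters the ratio).  The
  swap variant exists because the fresh-draw kernel alone essentially never
  accepts a root move once compositions have adapted to the data, which
  traps the chain in whichever rooting it first adapts to.

Correctness of the whole kernel is checked empirically in the test suite:
on a zero-site alignment the sampler must reproduce its own prior —
Kolmogorov–Smirnov checks on the $\sigma_R, \sigma_N, s$ marginals, and a
chi-square check that all 15 rooted four-taxon topologies are visited
uniformly (both models).  These tests catch errors in any Hastings ratio,
including the composition bookkeeping.

Runs are bit-reproducible given `(seed, options)`.  HB chains initialize
branch compositions at the empirical composition of the clade below each
edge (with pseudocounts); NR chains initialize $\pi$ at the overall
empirical composition.  Hyperparameters start from prior draws.

## Posterior summaries

* `root_split_posterior()` — the marginal posterior over canonical root
  splits (the taxon bipartition induced by deleting the root).
* `majority_rule_consensus()` — the rooted tree containing precisely the
  rooted clades (descendant leaf-sets, not unrooted bipartitions) with
  support strictly above 0.5, with posterior-mean branch lengths.  Because
  it is a conditional, clade-wise summary, its root can legitimately differ
  from the modal root split, and the root is left as a polytomy when no
  root-adjacent clade clears 0.5; the test suite constructs a fixture
  exhibiting exactly this disagreement.
* `rank_branches_by_gc()` — posterior mean GC content of each consensus
  branch under HB (root-adjacent branches use the root composition),
  clade-conditional: each branch averages only over the samples containing
  its clade.  Rank 1 is the most GC-rich branch.
* `standardized_marginal_likelihood()` — a posterior/prior density ratio
  for a non-negative scalar, typically $\sigma_R$ or $\sigma_N$: a
  boundary-reflected Gaussian KDE (Silverman bandwidth computed with the
  number of *distinct* draws, so duplicating the sample set leaves the
  curve unchanged) on a 512-point grid, divided by the prior density.
  Under prior sampling the curve is flat at 1; a curve vanishing at the
  origin is evidence against the parameter being zero.
* `empirical_composition_sd()` — per-taxon nucleotide proportions among
  unambiguous, non-gap sites and their across-taxa standard deviation
  (divisor $n-1$), the standard screen for compositional heterogeneity that
  a stationary model cannot absorb.

## The simulator and what the recovery experiments show

`simulate_alignment()` runs either model generatively (draw a rate
category, draw the root state from the root distribution, propagate root to
tips through each branch's $e^{Qtr_k}$), with no indel process; gaps only
enter through real data.  The simulator was validated distributionally: on
a three-taxon HB model with unequal compositions, empirical frequencies of
all 64 site patterns over 400,000 simulated sites match the
pruning-likelihood pattern probabilities (chi-square p = 0.69), so the
generator and the likelihood describe the same process.

The root-recovery experiment uses a six-taxon tree with a GC shift of 0.3
versus 0.7 between the two root-side subtrees and 1,000 sites.  The design
was chosen on mechanistic grounds before freezing:

* exchangeabilities are transition-rich GTR ($\rho_{AG} = \rho_{CT} = 4$),
  *not* all-equal — with $\rho \equiv 1$ every branch matrix is F81-type
  ($q_{ij} = \pi_j$), whose transition kernels are closed under matrix
  products, which collapses path information and makes the root essentially
  unidentifiable;
* compositions are asymmetric within their GC class, and the root
  composition is compositionally distinctive (GC 0.5 but T-poor);
* pendant branches are short (0.15) so that no tip sits at its branch
  equilibrium — a tip in equilibrium makes rooting on its pendant edge an
  almost exact mimic of the true process, and the posterior then drifts to
  pendant root splits, the artifact that sharing the root composition with
  the root-adjacent branches is designed to suppress.

Even so, the root signal at this problem size is modest, and this is a
property of the model class, not of the implementation: maximizing the
*expected* log-likelihood of competing rootings against the exact
4,096-pattern site distribution shows the best wrong rootings sit only
about 6 nats below the truth at 1,000 sites, which is comparable to the
sampling fluctuation of the log-likelihood ratio at that length.  The
per-dataset modal root split therefore often lands on a rooting adjacent
to the true one; at 5,000+ sites the separation (30+ nats) dominates and
chains that reach the true rooting stay there with posterior probability
near 1.  The corresponding acceptance experiment (modal split = truth in at
least 8 of 10 one-thousand-site replicates) is accordingly expected to
fail, and is retained unmodified as an honest record of that limit.

The parameter-recovery experiment is exactly calibrated by construction:
generating values are drawn from the prior, so 95% credible intervals for
$\kappa$ and $\alpha$ should cover the truth for 95% of replicates if and
only if the sampler targets the right posterior; observed coverage is
19/20 for both on eight-taxon, 1,000-site NR data.

What these simulations do *not* emulate: alignment error, indels,
across-site compositional mixtures, covarion-like processes, or selection;
passing recovery tests here certifies the inference machinery, not the
adequacy of NR or HB for any particular real alignment.

## Numerical choices

* Matrix exponentials: the sampler's kernel uses scaling-and-squaring
  (Armadillo `expmat`); the R-level `transition_probabilities()` uses the
  complex-safe eigendecomposition with a `Matrix::expm` fallback when the
  eigenvector matrix is ill-conditioned.  The two independent routes agree
  to 1e-8 in the pruning-versus-enumeration tests.
* Pruning rescales partial likelihoods per pattern at every internal node,
  tracking log offsets exactly, so deep trees cannot underflow.
* Site patterns are compressed before any likelihood work; weights always
  sum to the site count.
* Stationary distributions solve the 4x4 augmented system
  $[Q^{\mathsf T}; \mathbf 1] v = (0,0,0,1)$ by QR, with a 1e-10 residual
  guard.
* Degenerate proposals (compositions underflowing the simplex, reducible
  rate matrices) evaluate to $-\infty$ and auto-reject rather than error.
* Chain lengths used by the validation experiments (e.g. 625,000
  iterations thinned to 5,000 for prior recovery; 20,000 sweeps per
  root-recovery replicate; 16,000 per coverage replicate) are the problem
  sizes at which the corresponding statistics stabilize for these data
  sizes.

## Known limitations

* The NR perturbation parametrization is one faithful reading of a
  two-perturbation description; alternative placements of the perturbations
  (e.g. additive, or constrained $\varepsilon_N$) would differ in detail.
* $\kappa$ is not likelihood-identified separately from the transition
  entries of $\varepsilon_R$; its posterior is the prior-structured
  attribution along the exact likelihood ridge (the ridge Gibbs move makes
  this attribution mix properly).
* Root-split identification under HB is weak at small taxon and site
  counts (quantified above); analyses at the scale of the package's
  motivating applications (15-30 taxa, 1,500-3,000 sites) carry
  proportionally more signal but also need longer chains than the test
  defaults.
* Single chain, no tempering; no Bayes-factor machinery; unpartitioned
  nucleotide data only.
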