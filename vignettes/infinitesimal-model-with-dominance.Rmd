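---
title: "The infinitesimal model with dominance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The infinitesimal model with dominance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infdom)
```

## The model

A quantitative trait of a diploid individual is written as

$$\tilde Z = \bar z_0 + \frac{1}{\sqrt M}\sum_{l=1}^{M}
\big(\eta_l(\chi^1_l) + \eta_l(\chi^2_l) + \phi_l(\chi^1_l, \chi^2_l)\big)
+ E,$$

where $\chi^1_l, \chi^2_l$ are the allelic states of the two genes at locus
$l$ (copy 1 inherited from the first parent, copy 2 from the second),
$\eta_l$ is the additive effect, $\phi_l$ the symmetric dominance
deviation, $\bar z_0$ the ancestral mean, and $E \sim N(0, \sigma_E^2)$ an
environmental term.  Effects are *normalized* with respect to the
ancestral allele distribution $\hat\nu_l$ — $E[\eta_l(\hat\chi)] = 0$ and
$E[\phi_l(\hat\chi, x')] = 0$ for every $x'$ — which loses no generality
([`normalize_effects()`] performs the unique such decomposition of raw
genotype values).  Loci are unlinked; founders are drawn from an ancestral
population in Hardy–Weinberg and linkage equilibrium.

The infinitesimal limit states that, conditional on the pedigree, trait
values across the pedigree are asymptotically multivariate normal as
$M \to \infty$, with all moments expressible through six ancestral
variance components — the additive variance $\sigma_A^2$, dominance
variance $\sigma_D^2$, inbreeding depression $\iota$, the mean squared
locus-specific inbreeding depression $\iota^*$, the inbreeding dominance
variance $\sigma_{DI}^2$, and the additive–dominance covariance of inbred
individuals $\sigma_{ADI}$ ([`variance_components()`]) — together with
two-, three- and four-way identity-by-descent coefficients determined by
the pedigree.  Within a family the genetic value splits into a *shared*
part $A + D$ (identical for all full sibs; still random when dominance is
present, even given the parental traits) and a *Mendelian residual*
$RA + RD$, independent across sibs and unaffected by conditioning on the
parents.  This split is not the classical additive/dominance split: the
classical additive part is $\mathcal A = A + RA$ and the dominance
deviation is $\mathcal D = D + RD$.

## Identity coefficients

Pairwise kinship uses the textbook recursion on the later-born individual.
Three- and four-way coefficients — including the nine condensed identity
states $\Delta_1,\dots,\Delta_9$ of an ordered pair — are computed exactly
by a recursion over *generalized IBD functionals*: a state is a set of
groups of independent gene draws, and the latest individual's draws
resolve to parental gene copies with fair coins, merging groups that end
up sharing a physical gene.  The nine states are recovered by inverting a
linear system in eight such functionals.  The recursion is memoized and
implemented in C++ (`src/identity.cpp`); the state space grows quickly
with pedigree depth, so batched queries on one pedigree should share an
[`ibd_cache()`].  A Monte Carlo gene-dropping oracle
([`gene_drop_oracle()`]) provides an independent estimate of every
identity event and is used throughout the test suite as the arbiter of
correctness; exact benchmark values (full sibs: $\Delta_7 = 1/4$,
$\Delta_8 = 1/2$; selfing chains: $F_t = 1 - 2^{-t}$; first cousins,
half sibs, parent–offspring) are asserted to machine precision.

## Closed-form predictions and their coefficient readings

`shared_moments()`, `residual_variance()`, `cross_family_cov()`,
`trait_moments()`, `parent_offspring_shared_cov()` and
`conditional_shared_moments()` implement the closed-form moments.  Three
numerical readings deserve comment, because the package fixes them by
exact enumeration rather than by trusting any single printed rendering:

* **The $\iota^*\tilde F_{1212}$ term.**  In the shared/residual variance
  pair the coefficient of $\iota^* \tilde F_{1212}$ is $\pm 1/8$ (not
  $\pm 1/4$).  Both readings satisfy the sum rule (shared + residual =
  total variance with $F_{ii} = F_{12}$) because the term simply moves
  between the two expressions, so the sum rule cannot decide it.  An exact
  single-locus enumeration on a pedigree with full-sib parents does:
  with $\pm 1/8$ both variances match the enumerated values to machine
  precision.  The bi-allelic within-family shortcut for $V_{RD}$
  correspondingly carries coefficient $1$ (not $3/2$) on
  $\tilde F_{1212}$.
* **The cross-covariance subtraction.**  The subtraction term in
  $\mathrm{Cov}(Z_i, Z_j)$ and in $C(i, i[1])$ is $-\iota^* F_{ii}F_{jj}$,
  conditional on the pedigree.  With unlinked loci and founders in linkage
  equilibrium, per-locus contributions to different individuals are
  independent across loci, so only same-locus products survive; their
  aggregate is $\iota^*$, not $\iota^2$.  This matches the single-trait
  variance (whose subtraction is $-\iota^* F_{ii}^2$) and is verified
  exactly by a two-locus enumeration in which $\iota^2$ and $\iota^*$
  differ by two orders of magnitude.  (Forms with $\iota^2$ arise when the
  two-locus identity $\tilde f$ is *not* equal to $F_{ii}^2$, e.g. under
  identity disequilibrium in systems-of-mating calculations; conditional
  on a full pedigree with unlinked loci, $\tilde f = F_{ii}^2$ exactly.)
* **The $\sigma_{ADI}$ coefficient** in the cross-family covariance is
  $(F_{iij} + F_{ijj})$ with no factor $1/2$ — also settled by the
  enumeration.

All these formulas are pure functions of `(variance_components,
identity set)`, so they are property-tested on identity sets harvested
from random pedigrees, and exactness (tolerance $10^{-10}$) is asserted
against an independent enumeration oracle that sums over every founder
allele configuration and every transmission pattern of small pedigrees.

### Selfing

When $i[1] = i[2] = s$, the four parental gene slots collapse onto the two
physical genes of $s$, and the nine-state summary of a pair of *distinct*
parents can no longer encode the joint law: evaluated naively on the
degenerate identity set ($F_{12} = (1+F_{ss})/2$, $F_{112} = F_{122} =
F_{1122} = F_{ss}$, $\tilde F_{1212} = 1 - F_{ss}$, $\tilde F_{1122} = 0$)
the shared variance overshoots by exactly $\iota^*(1 - F_{ss})/8$ and the
residual undershoots by the same amount (their sum, the trait variance, is
unaffected).  The package therefore carries exact dedicated selfing
branches, derived from first principles:
$$\mathrm{Var}(A + D) = (1{+}F)\sigma_A^2 + \tfrac{1+3F}{2}\sigma_{ADI}
 + \tfrac{1+7F}{8}(\sigma_{DI}^2 + \iota^*)
 + \tfrac{2(1-F) - 4(1+F)^2}{16}\,\iota^* + \tfrac{1-F}{4}\sigma_D^2,$$
$$\mathrm{Var}(RA + RD) = (1 - F)\Big(\tfrac{\sigma_A^2}{2}
 + \tfrac{3\sigma_{DI}^2}{8} + \tfrac{\iota^*}{4} + \tfrac{\sigma_D^2}{4}
 + \tfrac{\sigma_{ADI}}{2}\Big),$$
with $F = F_{ss}$; both are enumeration-verified.  The parent–offspring
covariance needs no special branch (the generic expression evaluated on
the degenerate set is already exact), and conditioning reduces to the
univariate Gaussian case.

## The base-population generator

`make_biallelic_dominance_model()` builds the standing architecture of the
numerical studies: $M$ bi-allelic loci with complete dominance, genotype
values $-\alpha : -\alpha : +\alpha$ or $-\alpha : +\alpha : +\alpha$ with
$\alpha = 1/\sqrt M$ (stored scaled by $\sqrt M$, i.e. $\pm 1$), the
A-dominant pattern drawn per locus with probability
$H = 1/2 + c_H/\sqrt M$, and allele frequencies from a truncated
near-neutral distribution.  Two deliberately parameterized choices:

* **`c_H = 1` by default.**  The toy-model algebra pins the direction bias
  through $p_+ = \tfrac14 + \tfrac12 H = \tfrac12(1 + 1/\sqrt M)$, which
  forces $c = 1$; with the discrete frequency spectrum this predicts an
  inbreeding depression of $-0.42$ with a realization SD of $0.28$,
  consistent with the reported single realization ($-0.531$), whereas
  $c = 2$ predicts $-0.85$.  The constant is a parameter, not a constant,
  because the source renderings are ambiguous.
* **`freq_dialect = "sample_counts"` by default.**  Frequencies live on
  the grid $i/60$, $i = 1,\dots,59$, with weights
  $(i(60 - i))^{-1+\epsilon}$, $\epsilon = 10^{-3}$ — the neutral spectrum
  conditioned to segregate in a reference sample of $2N = 60$ genes.  In
  expectation this gives $\sigma_A^2 \approx 0.279$ and
  $\sigma_D^2 \approx 0.0716$ (realization SDs $\approx 0.009$ and
  $0.003$), bracketing the reported realization
  ($0.269$ / $0.073$).  The `continuous` dialect — density
  $\propto (p(1-p))^{-1+\epsilon}$ on $(0,1)$ with draws outside
  $(1/60,\,59/60)$ discarded, sampled exactly by inverse-CDF of the
  truncated Beta — is also provided; it centers $\sigma_A^2$ near
  $0.311$.

For every bi-allelic model $\sigma_D^2 = \iota^*$ holds exactly per locus,
and the per-locus inbreeding depression is $-2pqd$; both identities are
asserted in the tests.

```{r components}
vc <- variance_components(make_biallelic_dominance_model(1000, seed = 1))
unlist(vc[c("sigma_A2", "sigma_D2", "iota")])
```

## Simulation design

`simulate_pedigree_traits()` drops genes down a pedigree
generation-by-generation (vectorized over individuals and loci) and
returns the exact decomposition $Z = \bar z_0 + A + D + RA + RD$, which
telescopes to the direct genotype evaluation identically; founders carry
their whole deviation in $RA, RD$ so the identity holds uniformly.
Randomness is split into named streams (founders / per-generation,
per-candidate inheritance / noise) derived from one master seed, so a
truncation-selection run with one candidate per offspring
(`n_candidates = 1`) reproduces the neutral run bit for bit.  Selection
retains, per offspring, the trait-maximal of `n_candidates` independent
Mendelian draws from its realized parents — the pedigree, and hence every
identity coefficient, is untouched.  Selection acts on the genetic value
$Z$ by default (the environmental term can be attached via `sigma_E2`,
independent per individual or shared within families).

`neutral_experiment()` compares empirical moments with predictions
*per individual across replicates* (each individual has its own $F_{ii}$),
then averages within generations; Monte Carlo standard errors are reported
conservatively as generation means of per-individual standard errors,
without a $\sqrt N$ reduction, because individuals within a replicate are
correlated.  `genic_vs_total_variance()` contrasts variance components
with and without cross-locus (linkage-disequilibrium) covariances;
truncation selection depresses the total but barely moves the genic
components, which is the package's scaled-down version of the
convergence study (`convergence_experiment()` reports the trend of
|selected − neutral| genic components against $M$ with a log–log slope,
with no numeric target: the full-scale sweep is far beyond a desk run).

### Problem sizes used in the checks

The test suite works at the sizes the studies prescribe where that is
affordable and at reduced sizes where only the property (not a printed
number) is at stake: the standing pedigree recipe ($N = 30$ random-mating
monoecious diploids, no selfing) is exercised at $T = 10$ generations with
$M = 1000$ loci and 300 replicate ancestral draws for moment recovery;
within-family checks use 1000-offspring families; gene-dropping
validation uses $10^5$ replicates on a benchmark suite including a random
$N = 30$, $T = 5$ pedigree; the conditional-moment regression uses $10^4$
replicate draws of a sib-parent family at $M = 500$; convergence uses
$M \in \{25, 100, 400\}$.  These sizes are the package's choices for a
reproducible default run; all are parameters.

## What the synthetic data does and does not emulate

The generator reproduces the mechanism the theory is about — unlinked
loci, Hardy–Weinberg and linkage-equilibrium founders, fair Mendelian
transmission, complete dominance with a near-neutral frequency spectrum —
so passing tests show that the closed forms describe *this* mechanism
exactly and that the Gaussian limit is approached at the stated rates.
They do not show anything about linked loci, mutation, population
structure, non-Gaussian environments, or effect-size distributions with
unbounded support: all are outside the model class (and explicitly so).
Epistasis beyond first-order dominance (D×D and higher) is excluded.

## Numerical choices and degenerate inputs

* Identity coefficients are exact dyadic rationals computed in doubles;
  state probabilities are clipped at $10^{-14}$ to absorb round-off, and
  $\sum_k \Delta_k = 1$ is asserted at $10^{-12}$.
* `conditional_shared_moments()` refuses a singular parental covariance
  (exactly collinear parents) unless the selfing branch applies; adding
  observation noise `sigma_E2 > 0` regularizes the observed block, and
  `mvn_condition()` suggests the same when asked to condition on a
  singular set.
* Ties in truncation selection keep the earlier candidate (a
  probability-zero event for continuous traits).
* Toy-model posteriors use the exact binomial convolution for all $M$
  (enumeration over $2^{M-1}$ sign patterns is used only by the test
  oracle at small $M$); posterior/prior ratios at extreme offsets
  $|k| \approx M$ suffer benign cancellation at the $10^{-15}$ level.
* The toy module defaults to $c = 1$ like the generator; both accept any
  $c$ with $|c|/\sqrt M \le 1/2$.

## Limitations

Condensed identities on deep pedigrees are exponential-state
computations; with the C++ recursion a generation-10 pair on the $N = 30$
pedigree takes on the order of ten seconds (sharing a cache makes
subsequent pairs much cheaper), and generation-50 pairs are out of
comfortable reach — which is also why the within-family experiment
defaults to early-generation or ancestral parents.  Trait-moment
predictions ([`trait_moments()`], Eq.-level) need only $F_{ii}$ and scale
to the full pedigree via `kinship_matrix()`, which is $O(n^2)$ and covers
the 1530-individual standing pedigree in well under a second.
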