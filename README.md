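# infdom

Exact machinery for the infinitesimal model of a quantitative trait with
dominance, on explicit discrete-generation diploid pedigrees.

For a trait determined by `M` unlinked loci,

    Z = z0 + M^(-1/2) * sum_l [ eta_l(chi1_l) + eta_l(chi2_l) + phi_l(chi1_l, chi2_l) ]  (+ E),

with normalized additive effects `eta_l` and dominance deviations `phi_l`,
the within-family distribution of genetic values becomes Gaussian as
`M → ∞`, with moments determined by six ancestral variance components
(`σA²`, `σD²`, the inbreeding depression `ι`, `ι*`, `σDI²`, `σADI`) and by
two-, three- and four-way identity-by-descent coefficients of the
pedigree.  The offspring value splits into a part `A + D` shared by all
full sibs — still random, even given the parental traits, when dominance
is present — and a Mendelian residual `RA + RD`, independent across sibs,
whose variance is unchanged by conditioning on the parents.

The package is for quantitative and population geneticists who want to

* compute **exact pedigree identity coefficients**: kinship and inbreeding,
  and the nine Jacquard condensed four-gene states `Δ1..Δ9`
  (`kinship_matrix()`, `condensed_identity()`, `parental_identity_set()`),
  with a gene-dropping Monte Carlo oracle (`gene_drop_oracle()`) as an
  independent check;
* **simulate the finite-locus Mendelian model** down a pedigree with the
  exact trait decomposition `Z = z0 + A + D + RA + RD`
  (`simulate_pedigree_traits()`, `within_family_sample()`,
  within-family truncation selection via `truncation_selection_sim()`);
* evaluate the **closed-form infinitesimal predictions**: shared and
  residual family moments, cross-family covariances, trait moments as
  functions of `F_ii`, parent–offspring covariances, and conditional
  moments given parental trait values (`shared_moments()`,
  `residual_variance()`, `trait_moments()`, `conditional_shared_moments()`,
  `joint_trait_mvn()` / `mvn_condition()`);
* generate the **bi-allelic complete-dominance base population** with
  near-neutral allele frequencies
  (`make_biallelic_dominance_model()`), and run the replication
  experiments (`neutral_experiment()`, `family_experiment()`,
  `selection_experiment()`, `normality_diagnostics()`,
  `toy_posterior_single()` / `toy_posterior_pair()`,
  `convergence_experiment()`).

The four-gene identity recursion is implemented in C++ (Rcpp); everything
else is base R.

## Worked example

```r
library(infdom)

# a random-mating pedigree: 30 diploids per generation, no selfing
ped <- make_random_pedigree(30, 10, seed = 1)

# the standing trait architecture: 1000 bi-allelic loci, complete dominance
model <- make_biallelic_dominance_model(1000, seed = 1)
vc <- variance_components(model)
vc
#> variance components: sigma_A2 = 0.2648, sigma_D2 = 0.0680, iota = -0.5022,
#>   iota* = 0.0680, sigma_DI2 = 0.1383, sigma_ADI = -0.1288, z_bar_0 = 0, sigma_E2 = 0
```

`sigma_A2` and `sigma_D2` are the ancestral additive and dominance
variances of the trait; `iota` is the inbreeding depression — the expected
decline of the trait mean per unit inbreeding, so a fully inbred line is
expected `0.50` trait units below the ancestral mean.  Dominance variance
here is about a quarter of the additive variance, and `sigma_D2 == iota*`
exactly, as it must be for bi-allelic loci.

```r
# gene-drop the trait down the pedigree and compare a family's
# within-family residual variance with the closed-form prediction
sim <- simulate_pedigree_traits(ped, model, seed = 2)
pars <- generation_members(ped, 5)[1:2]
pid <- parental_identity_set(
  pedigree(c(ped$id, "kid"), c(ped$parent1, pars[1]),
           c(ped$parent2, pars[2]), c(ped$generation, 6)), "kid")
family_residual_components(vc, pid)
#>          VRA          VRD       VRA_RD
#>  0.125136443  0.064905555 -0.009638158
```

`VRA` is the Mendelian-segregation variance of the additive part within
that family — reduced below `sigma_A2/2 = 0.132` by the parents' own
inbreeding — `VRD` the dominance analogue, and `VRA_RD` their covariance.
A thousand simulated offspring of the same pair reproduce these numbers
within Monte Carlo error (this is one of the package's acceptance checks).

```r
# conditional moments of the shared component given the parents' traits
conditional_shared_moments(vc, pid, z1 = 0.8, z2 = -0.2)[c("mean", "variance")]
#> $mean
#> [1] 0.1941861
#> $variance
#> [1] 0.03165132
```

With dominance the conditional variance is strictly positive — knowing
the parental traits does not pin down the shared component — but it does
not depend on the observed values, which is the heart of the
infinitesimal model.

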