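# brute-force toy-model oracle: enumerate the 2^(M-1) sign patterns of the
# remaining loci (with locus-level genotype/direction classes for locus 1)
toy_brute <- function(M, k, c_bias = 1) {
  H <- 0.5 + c_bias / sqrt(M)
  p_plus <- 0.25 + 0.5 * H
  # distribution of sum over loci 2..M by explicit enumeration
  s_rest <- 0; p_rest <- 1
  for (l in 2:M) {
    s_rest <- c(s_rest + 1, s_rest - 1)
    p_rest <- c(p_rest * p_plus, p_rest * (1 - p_plus))
  }
  # locus 1 classes: genotype x direction
  cls <- expand.grid(geno = c("aa", "het", "AA"), dirplus = c(TRUE, FALSE))
  cls$prior <- c(0.25, 0.5, 0.25)[match(cls$geno, c("aa", "het", "AA"))] *
    ifelse(cls$dirplus, H, 1 - H)
  cls$psi1 <- with(cls, ifelse(geno == "AA", 1,
                        ifelse(geno == "aa", -1, ifelse(dirplus, 1, -1))))
  joint <- vapply(seq_len(nrow(cls)), function(r)
    cls$prior[r] * sum(p_rest[s_rest + cls$psi1[r] == k]), 0)
  pk <- sum(joint)
  post <- tapply(joint, cls$geno, sum) / pk
  prior <- tapply(cls$prior, cls$geno, sum)
  ratio <- post / prior
  c(AA = unname(ratio["AA"]), aa = unname(ratio["aa"]),
    het = unname(ratio["het"]))
}

test_that("single-locus toy posterior matches brute-force enumeration and the
           closed forms", {
  for (M in c(4, 8, 12)) {
    for (k in seq(-M, M, by = 2)) {
      tp <- toy_posterior_single(M, k)
      expect_equal(tp$ratio_exact, tp$ratio_formula, tolerance = 1e-12)
      br <- toy_brute(M, k)
      expect_equal(unname(tp$ratio_exact), unname(br), tolerance = 1e-12)
      expect_equal(sum(tp$posterior), 1, tolerance = 1e-12)
    }
  }
  # worked case: M = 4, k = 2, c = 1 -> AA ratio (1 + 2/4)/(1 + 1/2) = 1
  tp <- toy_posterior_single(4, 2, c_bias = 1)
  expect_equal(unname(tp$ratio_exact["AA"]), 1, tolerance = 1e-12)
  expect_error(toy_posterior_single(4, 3), "parity")
  expect_error(toy_posterior_single(4, 6), "exceed")
})

test_that("the two homozygote ratio formulas are reflections at k = 0", {
  for (M in c(4, 16, 36)) {
    tp <- toy_posterior_single(M, 0)
    # k -> -k swaps + and -: at k = 0 the two formulas are images under
    # c -> -c, and the exact ratios agree with them individually
    expect_equal(unname(tp$ratio_formula["AA"]), 1 / (1 + 1 / sqrt(M)),
                 tolerance = 1e-12)
    expect_equal(unname(tp$ratio_formula["aa"]), 1 / (1 - 1 / sqrt(M)),
                 tolerance = 1e-12)
    tpk <- toy_posterior_single(M, 4)
    tpk_m <- toy_posterior_single(M, -4)
    expect_equal(unname(tpk$ratio_formula["AA"]) * (1 + 1 / sqrt(M)),
                 unname(tpk_m$ratio_formula["aa"]) * (1 - 1 / sqrt(M)),
                 tolerance = 1e-12)
  }
})

test_that("pair posterior correction matches the closed form and scales as 1/M", {
  for (M in c(4, 16, 36)) {
    for (k in unique(c(0, 2, min(M, 6)))) {
      tp <- toy_posterior_pair(M, k)
      expect_equal(tp$correction_exact, tp$correction_formula,
                   tolerance = 1e-12)
    }
  }
  # at fixed k/sqrt(M), |correction| ~ 1/M (log-log slope near -1)
  Ms <- c(36, 64, 144, 400)
  corr <- vapply(Ms, function(M) {
    k <- 2 * sqrt(M)    # even and of typical size
    abs(toy_posterior_pair(M, k)$correction_exact)
  }, 0)
  slope <- coef(lm(log(corr) ~ log(Ms)))[2]
  expect_lt(abs(slope + 1), 0.2)
})

test_that("normality diagnostics separate Gaussian from skewed input", {
  set.seed(1)
  g <- normality_diagnostics(rnorm(5000))
  expect_lt(g$ks_distance, 0.03)
  sk <- normality_diagnostics(rexp(5000))
  expect_gt(sk$ks_distance, g$ks_distance)
  # family centering removes family means exactly
  fam <- rep(1:10, each = 200)
  x <- rnorm(2000) + fam * 10
  cd <- normality_diagnostics(x, family = fam, center_by_family = TRUE)
  expect_lt(cd$ks_distance, 0.05)
  expect_error(normality_diagnostics(rnorm(10)), "at least")
})

test_that("neutral experiment tracks the closed-form per-generation moments", {
  ped <- make_random_pedigree(8, 4, seed = 5)
  model <- make_biallelic_dominance_model(60, seed = 2)
  res <- neutral_experiment(ped, model, n_reps = 150, seed = 9)
  expect_equal(nrow(res), 5L)
  # generation 0: no inbreeding, mean dominance deviation near zero
  expect_lt(abs(res$emp_mean_D[1]), 3 * res$se_mean_D[1] + 1e-8)
  for (q in c("mean_Z", "mean_D", "var_A", "var_Z")) {
    dev <- abs(res[[paste0("emp_", q)]] - res[[paste0("pred_", q)]])
    expect_true(all(dev <= 4 * res[[paste0("se_", q)]] + 1e-8))
  }
})

test_that("family experiment predictions equal the formula route and flag selfing", {
  ped <- make_random_pedigree(6, 2, selfing_allowed = TRUE, seed = 31)
  model <- make_biallelic_dominance_model(40, seed = 3)
  vc <- variance_components(model)
  fam <- family_experiment(ped, model, generation = 2, n_pairs = 24,
                          n_offspring = 600, n_reps = 6, seed = 4)
  cache <- ibd_cache(ped)
  for (r in seq_len(nrow(fam))) {
    pid <- infdom:::pair_identity_set(ped, fam$parent1[r], fam$parent2[r],
                                      cache)
    frc <- family_residual_components(vc, pid)
    expect_equal(fam$pred_VRA[r], unname(frc["VRA"]), tolerance = 1e-12)
    expect_equal(fam$pred_VRD[r], unname(frc["VRD"]), tolerance = 1e-12)
  }
  # selfed pairs carry the with-replacement self-kinship >= 1/2
  if (any(fam$selfed)) {
    expect_true(all(fam$F12[fam$selfed] >= 0.5))
    if (any(!fam$selfed))
      expect_gt(mean(fam$F12[fam$selfed]), mean(fam$F12[!fam$selfed]))
  }
  # empirical values near predictions (pooled regression slope near 1)
  fit <- lm(I(fam$VRA + fam$VRD + 2 * fam$VRA_RD) ~
              I(fam$pred_VRA + fam$pred_VRD + 2 * fam$pred_VRA_RD) - 1)
  expect_lt(abs(coef(fit)[[1]] - 1), 0.15)
})

test_that("selection experiment couples arms and reports stable schema", {
  ped <- make_random_pedigree(8, 3, seed = 17)
  model <- make_biallelic_dominance_model(50, seed = 6)
  res <- selection_experiment(ped, model, n_reps = 6, seed = 2)
  expect_setequal(unique(res$arm), c("neutral", "selected"))
  expect_equal(sum(res$arm == "neutral"), 4L)
  expect_true(all(c("VG", "VG_genic", "mean_G") %in% names(res)))
  # paired arms are coupled: rerunning the experiment reproduces it exactly
  res2 <- selection_experiment(ped, model, n_reps = 6, seed = 2)
  expect_identical(res, res2)
})

test_that("convergence experiment: arm differences shrink with the locus count", {
  ped <- make_random_pedigree(6, 3, seed = 23)
  cv <- convergence_experiment(ped, M_grid = c(20L, 80L, 320L), n_reps = 8,
                               seed = 11)
  expect_setequal(unique(cv$table$component),
                  c("VA_genic", "VD_genic", "cov_AD_genic", "VG_genic"))
  expect_equal(nrow(cv$slopes), 4L)
  vg <- cv$table[cv$table$component == "VG_genic", ]
  expect_lt(vg$diff[vg$M == 320], vg$diff[vg$M == 20])
})
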