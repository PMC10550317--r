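# The enumeration oracle (helper-enumeration.R) computes exact moments of
# the Mendelian model on small pedigrees; the closed-form predictions must
# match it to numerical precision.

test_that("shared/residual/trait moments are exact on a sib-mating pedigree", {
  ped <- ped_sib_parents()        # f1,f2 -> s1,s2 -> i,j
  model <- test_model(p2 = c(0.3, 0.6), het = c(1, -1))
  vc <- variance_components(model)
  em <- enumerate_moments(ped, model)
  cache <- ibd_cache(ped)
  pid <- parental_identity_set(ped, "i", cache)

  sm <- shared_moments(vc, pid)
  expect_equal(sm$mean, em_mean(em, "A", "i") + em_mean(em, "D", "i"),
               tolerance = 1e-10)
  expect_equal(sm$variance, em_var_shared(em, "i"), tolerance = 1e-10)

  expect_equal(residual_variance(vc, pid), em_var_resid(em, "i"),
               tolerance = 1e-10)

  frc <- family_residual_components(vc, pid)
  expect_equal(unname(frc["VRA"]), em_cov(em, "RA", "i", "RA", "i"),
               tolerance = 1e-10)
  expect_equal(unname(frc["VRD"]), em_cov(em, "RD", "i", "RD", "i"),
               tolerance = 1e-10)
  expect_equal(unname(frc["VRA_RD"]), em_cov(em, "RA", "i", "RD", "i"),
               tolerance = 1e-10)

  # per-individual trait moments, Fii = parental F12
  Fii <- inbreeding(ped, "i")
  tm <- trait_moments(vc, Fii)
  expect_equal(tm$mean_Z, vc$z_bar_0 + em_mean(em, "Z", "i"),
               tolerance = 1e-10)
  expect_equal(tm$var_Z, em_cov(em, "Z", "i", "Z", "i"), tolerance = 1e-10)
  # classical components A = A + RA, D = D + RD
  expect_equal(tm$mean_D, em_mean(em, "D", "i") + em_mean(em, "RD", "i"),
               tolerance = 1e-10)
  varA <- em_cov(em, "A", "i", "A", "i") + em_cov(em, "RA", "i", "RA", "i") +
    2 * em_cov(em, "A", "i", "RA", "i")
  varD <- em_cov(em, "D", "i", "D", "i") + em_cov(em, "RD", "i", "RD", "i") +
    2 * em_cov(em, "D", "i", "RD", "i")
  covAD <- em_cov(em, "A", "i", "D", "i") + em_cov(em, "A", "i", "RD", "i") +
    em_cov(em, "RA", "i", "D", "i") + em_cov(em, "RA", "i", "RD", "i")
  expect_equal(tm$var_A, varA, tolerance = 1e-10)
  expect_equal(tm$var_D, varD, tolerance = 1e-10)
  expect_equal(tm$cov_AD, covAD, tolerance = 1e-10)

  # shared and residual parts are exactly uncorrelated
  expect_equal(em_cov(em, "A", "i", "RA", "i") +
               em_cov(em, "A", "i", "RD", "i") +
               em_cov(em, "D", "i", "RA", "i") +
               em_cov(em, "D", "i", "RD", "i"), 0, tolerance = 1e-12)

  # cross-family covariance of sibs equals Cov(Zi, Zj) and the shared
  # variance (sibs share A + D identically)
  pij <- paper_identities(ped, "i", "j", cache)
  cf <- cross_family_cov(vc, pij)
  expect_equal(cf, em_cov_shared(em, "i", "j"), tolerance = 1e-10)
  expect_equal(cf, em_cov(em, "Z", "i", "Z", "j"), tolerance = 1e-10)
  expect_equal(cf, sm$variance, tolerance = 1e-10)

  # parent-offspring covariance of the shared component, Eq for C(i, i[1])
  C <- parent_offspring_shared_cov(vc, pid)
  expect_equal(unname(C["C1"]), em_cov_shared_z(em, "i", "s1"),
               tolerance = 1e-10)
  expect_equal(unname(C["C2"]), em_cov_shared_z(em, "i", "s2"),
               tolerance = 1e-10)
})

test_that("moments stay exact for an inbred asymmetric parent pair", {
  # selfed line crossed with an outbred founder: F11 > 0, F22 = 0
  ped <- pedigree(c("f", "g", "s", "i", "j"),
                  c(NA, NA, "f", "s", "s"), c(NA, NA, "f", "g", "g"),
                  c(0, 0, 1, 2, 2), selfing_allowed = TRUE)
  model <- test_model(p2 = c(0.25, 0.7), het = c(1, -1))
  vc <- variance_components(model)
  em <- enumerate_moments(ped, model)
  cache <- ibd_cache(ped)
  pid <- parental_identity_set(ped, "i", cache)
  expect_equal(unname(pid["F11"]), 0.5)
  expect_equal(unname(pid["F22"]), 0)

  sm <- shared_moments(vc, pid)
  expect_equal(sm$mean, em_mean(em, "A", "i") + em_mean(em, "D", "i"),
               tolerance = 1e-10)
  expect_equal(sm$variance, em_var_shared(em, "i"), tolerance = 1e-10)
  expect_equal(residual_variance(vc, pid), em_var_resid(em, "i"),
               tolerance = 1e-10)
  C <- parent_offspring_shared_cov(vc, pid)
  expect_equal(unname(C["C1"]), em_cov_shared_z(em, "i", "s"),
               tolerance = 1e-10)
  expect_equal(unname(C["C2"]), em_cov_shared_z(em, "i", "g"),
               tolerance = 1e-10)
  pij <- paper_identities(ped, "i", "j", cache)
  expect_equal(cross_family_cov(vc, pij), em_cov(em, "Z", "i", "Z", "j"),
               tolerance = 1e-10)
})

test_that("selfed families use the exact degenerate branch", {
  ped <- ped_selfed_family()      # f -> s = self(f) -> i, j = self(s)
  model <- test_model(p2 = c(0.3, 0.6), het = c(1, -1))
  vc <- variance_components(model)
  em <- enumerate_moments(ped, model)
  pid <- parental_identity_set(ped, "i")
  expect_equal(unname(pid["selfed"]), 1)

  sm <- shared_moments(vc, pid)
  expect_equal(sm$mean, em_mean(em, "A", "i") + em_mean(em, "D", "i"),
               tolerance = 1e-10)
  expect_equal(sm$variance, em_var_shared(em, "i"), tolerance = 1e-10)
  expect_equal(residual_variance(vc, pid), em_var_resid(em, "i"),
               tolerance = 1e-10)
  frc <- family_residual_components(vc, pid)
  expect_equal(unname(frc["VRA"]), em_cov(em, "RA", "i", "RA", "i"),
               tolerance = 1e-10)
  expect_equal(unname(frc["VRD"]), em_cov(em, "RD", "i", "RD", "i"),
               tolerance = 1e-10)
  expect_equal(unname(frc["VRA_RD"]), em_cov(em, "RA", "i", "RD", "i"),
               tolerance = 1e-10)
  C <- parent_offspring_shared_cov(vc, pid)
  expect_equal(unname(C["C1"]), em_cov_shared_z(em, "i", "s"),
               tolerance = 1e-10)
  # shared + residual still assemble the full trait variance
  Fii <- inbreeding(ped, "i")
  expect_equal(sm$variance + residual_variance(vc, pid),
               trait_moments(vc, Fii)$var_Z, tolerance = 1e-10)
})

test_that("sum rule: shared + residual variance equals Var(Z) with Fii = F12", {
  vc <- variance_components(test_model(p2 = c(0.35, 0.55), het = c(1, -1)))
  for (pid in random_parental_sets(60, seed = 7)) {
    tot <- shared_moments(vc, pid)$variance + residual_variance(vc, pid)
    expect_equal(tot, trait_moments(vc, unname(pid["F12"]))$var_Z,
                 tolerance = 1e-10)
    frc <- family_residual_components(vc, pid)
    expect_equal(unname(frc["VRA"] + frc["VRD"] + 2 * frc["VRA_RD"]),
                 residual_variance(vc, pid), tolerance = 1e-10)
  }
})

test_that("purely additive components reproduce the classical reductions", {
  vc <- variance_components(test_additive_model())
  sA2 <- vc$sigma_A2
  for (pid in random_parental_sets(40, seed = 3)) {
    p <- as.list(pid)
    sm <- shared_moments(vc, pid)
    expect_equal(sm$mean, 0)
    rv <- residual_variance(vc, pid)
    if (p$selfed != 1) {
      expect_equal(sm$variance,
                   sA2 / 2 * (1 + (p$F11 + p$F22) / 2 + 2 * p$F12),
                   tolerance = 1e-12)
      expect_equal(rv, sA2 / 2 * (1 - (p$F11 + p$F22) / 2),
                   tolerance = 1e-12)
      C <- parent_offspring_shared_cov(vc, pid)
      expect_equal(unname(C["C1"]), sA2 / 2 * (1 + p$F11 + 2 * p$F12),
                   tolerance = 1e-12)
    }
    # conditional moments: mid-parent mean (z_bar_0 = 0), zero variance
    z1 <- rnorm(1); z2 <- rnorm(1)
    cm <- conditional_shared_moments(vc, pid, z1, z2)
    if (p$selfed == 1) {
      expect_equal(cm$mean, z1, tolerance = 1e-9)
    } else {
      expect_equal(cm$mean, (z1 + z2) / 2, tolerance = 1e-9)
    }
    expect_equal(cm$variance, 0, tolerance = 1e-9)
  }
  # identities-zero special case
  pid0 <- c(F11 = 0, F22 = 0, F12 = 0, F112 = 0, F122 = 0, F1122 = 0,
            Ft_1212 = 0, Ft_1122 = 0, selfed = 0)
  vcd <- variance_components(test_model())
  expect_equal(shared_moments(vcd, pid0)$variance,
               vcd$sigma_A2 / 2 + vcd$sigma_D2 / 4, tolerance = 1e-12)
  expect_equal(residual_variance(vcd, pid0),
               vcd$sigma_A2 / 2 + 3 * vcd$sigma_D2 / 4, tolerance = 1e-12)
  frc0 <- family_residual_components(vcd, pid0)
  expect_equal(unname(frc0), c(vcd$sigma_A2 / 2, 3 * vcd$sigma_D2 / 4, 0),
               tolerance = 1e-12)
  expect_equal(unname(parent_offspring_shared_cov(vcd, pid0)["C1"]),
               vcd$sigma_A2 / 2, tolerance = 1e-12)
})

test_that("conditional moments: variance is free of the observed values and
           the mean interpolates the unconditional one", {
  vc <- variance_components(test_model(p2 = c(0.3, 0.6), het = c(1, -1)))
  ped <- ped_sib_parents()
  pid <- parental_identity_set(ped, "i")
  tm <- trait_moments(vc, c(pid[["F11"]], pid[["F22"]]))
  cm0 <- conditional_shared_moments(vc, pid, tm$mean_Z[1], tm$mean_Z[2])
  expect_equal(cm0$mean, shared_moments(vc, pid)$mean, tolerance = 1e-12)
  for (dz in c(-2, 0.5, 3)) {
    cm <- conditional_shared_moments(vc, pid, tm$mean_Z[1] + dz,
                                     tm$mean_Z[2] - dz)
    expect_equal(cm$variance, cm0$variance, tolerance = 1e-12)
  }
  expect_lt(cm0$variance, shared_moments(vc, pid)$variance)
})

test_that("conditioning the joint Gaussian reproduces the closed-form route", {
  ped <- ped_sib_parents()
  model <- test_model(p2 = c(0.3, 0.6), het = c(1, -1))
  vc <- variance_components(model)
  pid <- parental_identity_set(ped, "i")
  # build (Z_s1, Z_s2, A+D) jointly: variances/covariances from the same
  # formula set, then condition on the parents
  sm <- shared_moments(vc, pid)
  C <- parent_offspring_shared_cov(vc, pid)
  tm <- trait_moments(vc, c(pid[["F11"]], pid[["F22"]]))
  cov12 <- cross_family_cov(vc, c(
    Fab = pid[["F12"]], Faa = pid[["F11"]], Fbb = pid[["F22"]],
    Faab = pid[["F112"]], Fabb = pid[["F122"]], Faabb = pid[["F1122"]],
    Ft_abab = pid[["Ft_1212"]], Ft_aabb = pid[["Ft_1122"]]))
  spec <- structure(list(
    mean = c(Z1 = tm$mean_Z[1], Z2 = tm$mean_Z[2], AD = sm$mean),
    cov = matrix(c(tm$var_Z[1], cov12, C[["C1"]],
                   cov12, tm$var_Z[2], C[["C2"]],
                   C[["C1"]], C[["C2"]], sm$variance), 3, 3),
    labels = c("Z1", "Z2", "AD")), class = "mvn_spec")
  z1 <- 0.7; z2 <- -0.4
  cond <- mvn_condition(spec, c(Z1 = z1, Z2 = z2))
  cm <- conditional_shared_moments(vc, pid, z1, z2)
  expect_equal(unname(cond$mean), cm$mean, tolerance = 1e-10)
  expect_equal(unname(cond$cov[1, 1]), cm$variance, tolerance = 1e-10)
})

test_that("mvn conditioning utilities obey the standard closed forms", {
  rho <- 0.6
  spec <- structure(list(mean = c(x = 0, y = 0),
                         cov = matrix(c(1, rho, rho, 1), 2, 2),
                         labels = c("x", "y")), class = "mvn_spec")
  cond <- mvn_condition(spec, c(y = 1.5))
  expect_equal(unname(cond$mean), rho * 1.5)
  expect_equal(unname(cond$cov[1, 1]), 1 - rho^2)
  # condition on nothing: unchanged
  expect_identical(mvn_condition(spec), spec)
  # order independence
  spec3 <- structure(list(mean = c(a = 1, b = 2, c = 3),
                          cov = matrix(c(2, .5, .3, .5, 1.5, .4,
                                         .3, .4, 1.2), 3, 3),
                          labels = c("a", "b", "c")), class = "mvn_spec")
  c1 <- mvn_condition(mvn_condition(spec3, c(a = 0)), c(b = 1))
  c2 <- mvn_condition(spec3, c(a = 0, b = 1))
  expect_equal(c1$mean, c2$mean, tolerance = 1e-12)
  expect_equal(c1$cov, c2$cov, tolerance = 1e-12)
})

test_that("joint pedigree Gaussian matches per-pair formulas and enumeration", {
  ped <- ped_sib_parents()
  model <- test_model(p2 = c(0.3, 0.6), het = c(1, -1))
  vc <- variance_components(model)
  em <- enumerate_moments(ped, model)
  spec <- joint_trait_mvn(ped, vc, c("s1", "s2", "i", "j"))
  ids <- spec$labels
  for (a in ids) expect_equal(spec$cov[a, a], em_cov(em, "Z", a, "Z", a),
                              tolerance = 1e-10)
  for (a in c("s1", "i")) for (b in c("s2", "j"))
    expect_equal(spec$cov[a, b], em_cov(em, "Z", a, "Z", b),
                 tolerance = 1e-10)
  expect_equal(unname(spec$mean), vc$z_bar_0 + sapply(ids, function(i)
    em_mean(em, "Z", i)), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("regression of family shared component on parental traits matches
           the conditional-mean coefficients", {
  ped <- ped_sib_parents()
  model <- test_model(p2 = c(0.3, 0.6), het = c(1, -1))
  vc <- variance_components(model)
  pid <- parental_identity_set(ped, "i")
  R <- 4000
  z1 <- numeric(R); z2 <- numeric(R); ad <- numeric(R)
  for (r in seq_len(R)) {
    sim <- simulate_pedigree_traits(ped, model, seed = 5000 + r)
    d <- sim$decomp
    z1[r] <- d$Z[d$id == "s1"]; z2[r] <- d$Z[d$id == "s2"]
    ad[r] <- d$A[d$id == "i"] + d$D[d$id == "i"]
  }
  fit <- lm(ad ~ z1 + z2)
  # theoretical regression coefficients from the conditional mean
  cm_a <- conditional_shared_moments(vc, pid, 1, 0)
  cm_b <- conditional_shared_moments(vc, pid, 0, 0)
  beta1 <- cm_a$mean - cm_b$mean
  beta2 <- conditional_shared_moments(vc, pid, 0, 1)$mean - cm_b$mean
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(coef(fit)[["z1"]] - beta1), 4 * se[["z1"]])
  expect_lt(abs(coef(fit)[["z2"]] - beta2), 4 * se[["z2"]])
  # empirical conditional variance shows no gross trend across parental
  # bins (with M = 2 loci the joint law is far from Gaussian, so only a
  # coarse bound is meaningful here; the large-M constancy is exercised in
  # the acceptance suite)
  mid <- (z1 + z2) / 2
  bins <- cut(mid, quantile(mid, seq(0, 1, 0.25)), include.lowest = TRUE)
  vbin <- tapply(ad - fitted(fit), bins, var)
  expect_lt(max(vbin) / min(vbin), 4)
})
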