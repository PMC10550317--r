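#' Moments of the shared family component (A + D)
#'
#' Mean and variance of the component of offspring genetic value shared by
#' all full sibs of a family, as functions of the ancestral variance
#' components and the identity coefficients of the parent pair
#' ([parental_identity_set()]).  The mean is \eqn{\iota F_{12}}.  The
#' variance is the exact conditional-on-pedigree expression
#' \deqn{\frac{\sigma_A^2}{2}\Big(1 + \tfrac{F_{11}+F_{22}}{2} + 2F_{12}\Big)
#'  + \sigma_{ADI}\Big(F_{12} + \tfrac{F_{112}+F_{122}}{2}\Big)
#'  + \frac{\sigma_{DI}^2+\iota^*}{4}(F_{12}+F_{112}+F_{122}+F_{1122})
#'  + \frac{\iota^*}{8}\tilde F_{1212} - \iota^* F_{12}^2
#'  + \frac{\sigma_D^2}{4}\big((1-F_{12}) + (F_{22}-F_{122}) +
#'    (F_{11}-F_{112}) + \tilde F_{1122} + \tfrac12 \tilde F_{1212}\big).}
#' For a selfed family (`pid["selfed"] == 1`) the four parental gene slots
#' collapse onto the two genes of the single parent and an exact dedicated
#' expression is used (it differs from the generic formula by
#' \eqn{\iota^*(1-F_{ss})/8}).
#'
#' @param vc a [variance_components()] list.
#' @param pid a [parental_identity_set()] (or any named vector with fields
#'   `F11, F22, F12, F112, F122, F1122, Ft_1212, Ft_1122` and optionally
#'   `selfed`).
#' @return List with `mean` and `variance`.
#' @export
shared_moments <- function(vc, pid) {
  p <- as.list(pid)
  mean <- vc$iota * p$F12
  if (isTRUE(p$selfed == 1)) {
    Fss <- p$F11
    variance <- vc$sigma_A2 * (1 + Fss) +
      vc$sigma_ADI * (1 + 3 * Fss) / 2 +
      (vc$sigma_DI2 + vc$iota_star) * (1 + 7 * Fss) / 8 +
      vc$iota_star * (2 * (1 - Fss) - 4 * (1 + Fss)^2) / 16 +
      vc$sigma_D2 * (1 - Fss) / 4
    return(list(mean = mean, variance = variance))
  }
  variance <- vc$sigma_A2 / 2 * (1 + (p$F11 + p$F22) / 2 + 2 * p$F12) +
    vc$sigma_ADI * (p$F12 + (p$F112 + p$F122) / 2) +
    (vc$sigma_DI2 + vc$iota_star) / 4 *
      (p$F12 + p$F112 + p$F122 + p$F1122) +
    vc$iota_star / 8 * p$Ft_1212 - vc$iota_star * p$F12^2 +
    vc$sigma_D2 / 4 * ((1 - p$F12) + (p$F22 - p$F122) +
                       (p$F11 - p$F112) + p$Ft_1122 + p$Ft_1212 / 2)
  list(mean = mean, variance = variance)
}

#' Variance of the Mendelian-sampling residual (RA + RD)
#'
#' The within-family segregation variance: mean zero, unchanged by
#' conditioning on parental trait values, with variance
#' \deqn{\frac{\sigma_A^2}{2}\Big(1-\tfrac{F_{11}+F_{22}}{2}\Big)
#'  + \frac{\sigma_{DI}^2+\iota^*}{4}(3F_{12}-F_{1122}-F_{112}-F_{122})
#'  + \frac{\sigma_D^2}{4}\big(3(1-F_{12}) - (F_{11}-F_{112}) -
#'    (F_{22}-F_{122}) - \tilde F_{1122} - \tfrac12\tilde F_{1212}\big)
#'  + \sigma_{ADI}\Big(F_{12}-\tfrac{F_{112}+F_{122}}{2}\Big)
#'  - \frac{\iota^*}{8}\tilde F_{1212},}
#' with an exact dedicated branch for selfed families.  Together with
#' [shared_moments()] it reconstructs the total genetic variance
#' ([trait_moments()] with \eqn{F_{ii} = F_{12}}) exactly.
#'
#' @inheritParams shared_moments
#' @return The variance (scalar).
#' @export
residual_variance <- function(vc, pid) {
  p <- as.list(pid)
  if (isTRUE(p$selfed == 1)) {
    Fss <- p$F11
    return((1 - Fss) * (vc$sigma_A2 / 2 +
                        3 * vc$sigma_DI2 / 8 + vc$iota_star / 4 +
                        vc$sigma_D2 / 4 +
                        vc$sigma_ADI / 2))
  }
  vc$sigma_A2 / 2 * (1 - (p$F11 + p$F22) / 2) +
    (vc$sigma_DI2 + vc$iota_star) / 4 *
      (3 * p$F12 - p$F1122 - p$F112 - p$F122) +
    vc$sigma_D2 / 4 * (3 * (1 - p$F12) - (p$F11 - p$F112) -
                       (p$F22 - p$F122) - p$Ft_1122 - p$Ft_1212 / 2) +
    vc$sigma_ADI * (p$F12 - (p$F112 + p$F122) / 2) -
    vc$iota_star / 8 * p$Ft_1212
}

#' Covariance of shared components across families
#'
#' \eqn{\mathrm{Cov}(A_i + D_i, A_j + D_j)} for two individuals `i`, `j`,
#' expressed in the identity coefficients of the individuals *themselves*
#' ([paper_identities()] of the pair): \deqn{2F_{ij}\sigma_A^2 +
#' (F_{ijj}+F_{iij})\sigma_{ADI} + \tilde F_{ijij}\sigma_D^2 +
#' F_{iijj}(\sigma_{DI}^2+\iota^*) + \iota^*\tilde F_{iijj} -
#' \iota^* F_{ii}F_{jj}.} For distinct individuals this also equals
#' \eqn{\mathrm{Cov}(Z_i, Z_j)}, the residuals being independent across
#' individuals.
#'
#' @param vc a [variance_components()] list.
#' @param pids a [paper_identities()] vector for the pair `(i, j)`.
#' @return The covariance (scalar).
#' @export
cross_family_cov <- function(vc, pids) {
  p <- as.list(pids)
  2 * p$Fab * vc$sigma_A2 + (p$Faab + p$Fabb) * vc$sigma_ADI +
    p$Ft_abab * vc$sigma_D2 + p$Faabb * (vc$sigma_DI2 + vc$iota_star) +
    vc$iota_star * p$Ft_aabb - vc$iota_star * p$Faa * p$Fbb
}

#' Trait moments of a single individual (and of the classical components)
#'
#' Conditional on the pedigree, \eqn{E[Z_i] = \bar z_0 + \iota F_{ii}} and
#' \deqn{\mathrm{Var}(Z_i) = \sigma_A^2(1+F_{ii}) + \sigma_D^2(1-F_{ii}) +
#' (\sigma_{DI}^2+\iota^*)F_{ii} + 2\sigma_{ADI}F_{ii} - \iota^* F_{ii}^2,}
#' with the classical additive part \eqn{\mathcal A = A + RA} and dominance
#' deviation \eqn{\mathcal D = D + RD} satisfying \eqn{E[\mathcal A] = 0},
#' \eqn{E[\mathcal D] = \iota F_{ii}},
#' \eqn{\mathrm{Var}(\mathcal A) = \sigma_A^2(1+F_{ii})},
#' \eqn{\mathrm{Cov}(\mathcal A,\mathcal D) = \sigma_{ADI}F_{ii}}, and
#' \eqn{\mathrm{Var}(\mathcal D) = \sigma_D^2(1-F_{ii}) +
#' \sigma_{DI}^2 F_{ii} + \iota^*(F_{ii}-F_{ii}^2)}.
#'
#' @param vc a [variance_components()] list.
#' @param F_ii inbreeding coefficient(s); vectorized.
#' @return Data frame with columns `F_ii`, `mean_Z`, `var_Z`, `mean_A`,
#'   `mean_D`, `var_A`, `var_D`, `cov_AD`.
#' @export
trait_moments <- function(vc, F_ii) {
  if (any(F_ii < 0 | F_ii > 1)) stop("F_ii must lie in [0, 1]")
  data.frame(
    F_ii = F_ii,
    mean_Z = vc$z_bar_0 + vc$iota * F_ii,
    var_Z = vc$sigma_A2 * (1 + F_ii) + vc$sigma_D2 * (1 - F_ii) +
      (vc$sigma_DI2 + vc$iota_star) * F_ii + 2 * vc$sigma_ADI * F_ii -
      vc$iota_star * F_ii^2,
    mean_A = 0,
    mean_D = vc$iota * F_ii,
    var_A = vc$sigma_A2 * (1 + F_ii),
    var_D = vc$sigma_D2 * (1 - F_ii) + vc$sigma_DI2 * F_ii +
      vc$iota_star * (F_ii - F_ii^2),
    cov_AD = vc$sigma_ADI * F_ii)
}

#' Covariance of the shared component with each parental trait
#'
#' \eqn{C(i, i[1]) = \mathrm{Cov}(A_i + D_i, Z_{i[1]})}:
#' \deqn{\frac{\sigma_A^2}{2}(1+F_{11}+2F_{12}) +
#' \frac{\sigma_{ADI}}{2}(F_{11}+F_{12}+2F_{112}) +
#' \sigma_D^2(F_{12}-F_{112}) + (\sigma_{DI}^2+\iota^*)F_{112} -
#' \iota^* F_{11}F_{12},} and symmetrically for `C(i, i[2])` with subscripts
#' 1 and 2 interchanged.  Under selfing both equal
#' \eqn{\mathrm{Cov}(A_i+D_i, Z_s)} computed exactly from the collapsed
#' slots.
#'
#' @inheritParams shared_moments
#' @return Named vector `c(C1, C2)`.
#' @export
parent_offspring_shared_cov <- function(vc, pid) {
  p <- as.list(pid)
  if (isTRUE(p$selfed == 1)) {
    Fss <- p$F11
    C <- (1 + Fss) * vc$sigma_A2 +
      vc$sigma_ADI * (1 + 7 * Fss) / 4 +
      Fss * (vc$sigma_DI2 + vc$iota_star) +
      (1 - Fss) * vc$sigma_D2 / 2 -
      Fss * (1 + Fss) * vc$iota_star / 2
    return(c(C1 = C, C2 = C))
  }
  C1 <- vc$sigma_A2 / 2 * (1 + p$F11 + 2 * p$F12) +
    vc$sigma_ADI / 2 * (p$F11 + p$F12 + 2 * p$F112) +
    vc$sigma_D2 * (p$F12 - p$F112) +
    (vc$sigma_DI2 + vc$iota_star) * p$F112 -
    vc$iota_star * p$F11 * p$F12
  C2 <- vc$sigma_A2 / 2 * (1 + p$F22 + 2 * p$F12) +
    vc$sigma_ADI / 2 * (p$F22 + p$F12 + 2 * p$F122) +
    vc$sigma_D2 * (p$F12 - p$F122) +
    (vc$sigma_DI2 + vc$iota_star) * p$F122 -
    vc$iota_star * p$F22 * p$F12
  c(C1 = C1, C2 = C2)
}

#' Conditional moments of the shared component given parental traits
#'
#' Standard bivariate-normal conditioning of \eqn{A_i + D_i} on the parental
#' genetic values \eqn{(Z_{i[1]}, Z_{i[2]})}: the mean is shifted by the
#' regression on the parental deviations and the variance is reduced by the
#' explained part; the conditional variance does not depend on the observed
#' values.  In the purely additive case the conditional mean reduces to the
#' mid-parent \eqn{(z_1+z_2)/2} and the conditional variance to zero.  For
#' a selfed family the univariate analogue conditions on the single
#' parent's trait.  With `sigma_E2 > 0` the conditioning is on observed
#' (noisy) traits: the parental covariance matrix gains `sigma_E2` on its
#' diagonal.
#'
#' @inheritParams shared_moments
#' @param z1,z2 observed parental trait values (`z2` ignored when selfed).
#' @param sigma_E2 environmental variance added to the diagonal of the
#'   parental covariance (default 0: conditioning on genetic values).
#' @return List with `mean`, `variance`, and the covariances `C1`, `C2`
#'   used in the regression.
#' @export
conditional_shared_moments <- function(vc, pid, z1, z2 = NULL,
                                       sigma_E2 = 0) {
  p <- as.list(pid)
  sm <- shared_moments(vc, pid)
  C <- parent_offspring_shared_cov(vc, pid)
  if (isTRUE(p$selfed == 1)) {
    varZ1 <- trait_moments(vc, p$F11)$var_Z + sigma_E2
    mZ1 <- vc$z_bar_0 + vc$iota * p$F11
    beta <- C[["C1"]] / varZ1
    return(list(mean = sm$mean + beta * (z1 - mZ1),
                variance = sm$variance - C[["C1"]]^2 / varZ1,
                C1 = C[["C1"]], C2 = C[["C1"]]))
  }
  tm <- trait_moments(vc, c(p$F11, p$F22))
  varZ1 <- tm$var_Z[1L] + sigma_E2
  varZ2 <- tm$var_Z[2L] + sigma_E2
  # Cov(Z1, Z2) from the cross-individual formula applied to the parents
  covZ12 <- cross_family_cov(vc, c(
    Fab = p$F12, Faa = p$F11, Fbb = p$F22, Faab = p$F112, Fabb = p$F122,
    Faabb = p$F1122, Ft_abab = p$Ft_1212, Ft_aabb = p$Ft_1122))
  det <- varZ1 * varZ2 - covZ12^2
  if (abs(det) < 1e-14 * max(varZ1 * varZ2, 1))
    stop("singular parental covariance; for selfed families pass the ",
         "degenerate parental identity set (selfed = 1)")
  d1 <- z1 - tm$mean_Z[1L]
  d2 <- z2 - tm$mean_Z[2L]
  mean <- sm$mean +
    ((C[["C1"]] * varZ2 - C[["C2"]] * covZ12) * d1 +
     (C[["C2"]] * varZ1 - C[["C1"]] * covZ12) * d2) / det
  variance <- sm$variance -
    (varZ1 * C[["C2"]]^2 + varZ2 * C[["C1"]]^2) / det +
    2 * covZ12 * C[["C1"]] * C[["C2"]] / det
  list(mean = mean, variance = variance, C1 = C[["C1"]], C2 = C[["C2"]],
       cov_Z12 = covZ12)
}

#' Within-family residual variance components
#'
#' The split of [residual_variance()] into the variance of `RA`, the
#' variance of `RD` and their covariance:
#' \eqn{V_{RA} = \sigma_A^2(1-F_W)/2} with
#' \eqn{F_W = (F_{11}+F_{22})/2};
#' \eqn{V_{RA,RD} = \tfrac{\sigma_{ADI}}{2}(F_{12} - F^{(3)})} with
#' \eqn{F^{(3)} = (F_{112}+F_{122})/2}; and
#' \eqn{V_{RD}} the remainder, which for bi-allelic loci
#' (\eqn{\sigma_D^2 = \iota^*}) collapses to
#' \deqn{\frac{\sigma_{DI}^2}{4}(3F_{12}-F_{1122}-F_{112}-F_{122}) +
#' \frac{\sigma_D^2}{4}\big(3-F_{11}-F_{22}-F_{1122}-\tilde F_{1122}
#' -\tilde F_{1212}\big).}
#'
#' @inheritParams shared_moments
#' @return Named vector `c(VRA, VRD, VRA_RD)` with
#'   `VRA + VRD + 2 VRA_RD = residual_variance(vc, pid)` exactly.
#' @export
family_residual_components <- function(vc, pid) {
  p <- as.list(pid)
  if (isTRUE(p$selfed == 1)) {
    Fss <- p$F11
    VRA <- (1 - Fss) * vc$sigma_A2 / 2
    VRA_RD <- (1 - Fss) * vc$sigma_ADI / 4
    VRD <- (1 - Fss) * (3 * vc$sigma_DI2 / 8 + vc$iota_star / 4 +
                        vc$sigma_D2 / 4)
    return(c(VRA = VRA, VRD = VRD, VRA_RD = VRA_RD))
  }
  FW <- (p$F11 + p$F22) / 2
  F3 <- (p$F112 + p$F122) / 2
  VRA <- vc$sigma_A2 * (1 - FW) / 2
  VRA_RD <- vc$sigma_ADI / 2 * (p$F12 - F3)
  VRD <- residual_variance(vc, pid) - VRA - 2 * VRA_RD
  c(VRA = VRA, VRD = VRD, VRA_RD = VRA_RD)
}

#' Joint multivariate-normal specification of trait values on a pedigree
#'
#' Builds the asymptotic joint Gaussian of the genetic values of a set of
#' individuals: means \eqn{\bar z_0 + \iota F_{ii}}, variances from
#' [trait_moments()], covariances from [cross_family_cov()] applied to each
#' pair, plus `sigma_E2` on the diagonal when observed traits are modeled.
#'
#' @param ped a [pedigree()].
#' @param vc a [variance_components()] list.
#' @param ids individual ids.
#' @param sigma_E2 added to the diagonal (observed traits).
#' @return List of class `mvn_spec` with `mean`, `cov`, `labels`.
#' @export
joint_trait_mvn <- function(ped, vc, ids, sigma_E2 = 0) {
  ids <- as.character(ids)
  n <- length(ids)
  cache <- ibd_cache(ped)
  Fii <- vapply(ids, function(i)
    2 * phi_groups(ped, list(c(i, i)), cache) - 1, 0)
  mu <- vc$z_bar_0 + vc$iota * Fii
  V <- diag(trait_moments(vc, Fii)$var_Z + sigma_E2, n)
  dimnames(V) <- list(ids, ids)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    cv <- cross_family_cov(vc, paper_identities(ped, ids[i], ids[j], cache))
    V[i, j] <- V[j, i] <- cv
  }
  structure(list(mean = stats::setNames(mu, ids), cov = V, labels = ids),
            class = "mvn_spec")
}

#' Condition a multivariate normal on observed coordinates
#'
#' Standard Gaussian conditioning: given observations on a subset of
#' coordinates, returns the conditional distribution of the remainder.
#' Conditioning is idempotent and independent of the order in which
#' observations are applied.
#'
#' @param spec an `mvn_spec` (list with `mean`, `cov`, `labels`).
#' @param observed named numeric vector of observed values (names in
#'   `spec$labels`); empty means no conditioning.
#' @return An `mvn_spec` for the unobserved coordinates.
#' @export
mvn_condition <- function(spec, observed = numeric()) {
  if (length(observed) == 0L) return(spec)
  obs_idx <- match(names(observed), spec$labels)
  if (anyNA(obs_idx)) stop("unknown label: ",
                           names(observed)[is.na(obs_idx)][1L])
  rest <- setdiff(seq_along(spec$labels), obs_idx)
  S <- spec$cov
  Soo <- S[obs_idx, obs_idx, drop = FALSE]
  cond <- tryCatch(solve(Soo, cbind(observed - spec$mean[obs_idx],
                                    t(S[rest, obs_idx, drop = FALSE]))),
                   error = function(e)
                     stop("singular observed block; consider adding ",
                          "environmental variance (sigma_E2 > 0)"))
  mu <- spec$mean[rest] + drop(S[rest, obs_idx, drop = FALSE] %*% cond[, 1L])
  V <- S[rest, rest, drop = FALSE] -
    S[rest, obs_idx, drop = FALSE] %*% cond[, -1L, drop = FALSE]
  structure(list(mean = mu, cov = (V + t(V)) / 2,
                 labels = spec$labels[rest]),
            class = "mvn_spec")
}
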