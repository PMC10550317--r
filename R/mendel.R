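#' Gene-drop simulation of trait values down a pedigree
#'
#' Founder genotypes are sampled from the ancestral model under
#' Hardy-Weinberg and linkage equilibrium; every non-founder receives gene
#' copy 1 from `parent1` and copy 2 from `parent2`, each copy chosen by an
#' independent fair coin per locus.  For every individual the exact
#' decomposition of the genetic value
#' \deqn{Z = \bar z_0 + A + D + RA + RD}
#' is returned: `A` and `D` are the average parental contributions (shared
#' by all full sibs; the mean over the four parental genes of the additive
#' effects, and over the four cross parental-gene pairings of the dominance
#' deviations), while `RA` and `RD` are the Mendelian-sampling residuals
#' (realized minus average contribution).  Founders carry their whole
#' deviation in `RA`, `RD` (their `A = D = 0`), so the identity holds
#' uniformly.  An environmental term `E ~ N(0, sigma_E2)` gives the
#' observed value `Z_tilde = Z + E`.
#'
#' With `n_candidates > 1`, within-family truncation selection is applied:
#' the pedigree (and hence all identity coefficients) is retained, but each
#' individual's genotype is the one with the largest genetic value among
#' `n_candidates` independent Mendelian draws from its realized parents.
#' `n_candidates = 1` reproduces the neutral simulation exactly under the
#' same seed (candidate streams are keyed per generation and candidate).
#'
#' @param ped a [pedigree()].
#' @param model an [ancestral_model()].
#' @param seed integer master seed.
#' @param n_candidates candidates per offspring (1 = neutral).
#' @param env_shared logical: share the environmental draw within each
#'   full-sib family instead of drawing independently per individual.
#' @param store_indicators keep the inheritance coin flips (`X` governs
#'   copy 1, `Y` copy 2) as attributes.
#' @return List of class `trait_sim`: `decomp` (data frame with `id`,
#'   `generation`, `A`, `D`, `RA`, `RD`, `E`, `Z`, `Z_tilde`), `g1`, `g2`
#'   (allele-index matrices, rows aligned with `ped`), and optionally `X`,
#'   `Y`.
#' @export
simulate_pedigree_traits <- function(ped, model, seed = 1L, n_candidates = 1L,
                                     env_shared = FALSE,
                                     store_indicators = FALSE) {
  stopifnot(n_candidates >= 1L)
  n <- nrow(ped); M <- model$M
  pi <- parent_index(ped)
  g1 <- matrix(0L, n, M); g2 <- matrix(0L, n, M)
  X <- if (store_indicators) matrix(NA, n, M) else NULL
  Y <- if (store_indicators) matrix(NA, n, M) else NULL
  A <- numeric(n); D <- numeric(n); RA <- numeric(n); RD <- numeric(n)

  f_idx <- which(is.na(pi[, 1L]))
  fg <- sample_founder_genotypes(model, length(f_idx), derive_seed(seed, "fnd"))
  g1[f_idx, ] <- fg$g1; g2[f_idx, ] <- fg$g2
  RA[f_idx] <- (rowSums(lookup_eta(model, fg$g1)) +
                rowSums(lookup_eta(model, fg$g2))) / sqrt(M)
  RD[f_idx] <- rowSums(lookup_phi(model, fg$g1, fg$g2)) / sqrt(M)

  for (t in seq_len(max(ped$generation))) {
    rows <- which(ped$generation == t)
    if (!length(rows)) next
    p1 <- pi[rows, 1L]; p2 <- pi[rows, 2L]
    nr <- length(rows)
    P11 <- g1[p1, , drop = FALSE]; P12 <- g2[p1, , drop = FALSE]
    P21 <- g1[p2, , drop = FALSE]; P22 <- g2[p2, , drop = FALSE]
    best <- NULL
    for (cand in seq_len(n_candidates)) {
      restore <- local_seed(derive_seed(seed, "inh", t, cand))
      x <- matrix(stats::runif(nr * M) < 0.5, nr, M)
      y <- matrix(stats::runif(nr * M) < 0.5, nr, M)
      restore()
      c1 <- P11 * x + P12 * (1 - x)
      c2 <- P21 * y + P22 * (1 - y)
      z <- trait_value(model, c1, c2)
      if (is.null(best)) {
        best <- list(c1 = c1, c2 = c2, z = z, x = x, y = y)
      } else {
        gain <- z > best$z
        if (any(gain)) {
          best$c1[gain, ] <- c1[gain, ]; best$c2[gain, ] <- c2[gain, ]
          best$x[gain, ] <- x[gain, ];   best$y[gain, ] <- y[gain, ]
          best$z[gain] <- z[gain]
        }
      }
    }
    g1[rows, ] <- best$c1; g2[rows, ] <- best$c2
    if (store_indicators) { X[rows, ] <- best$x; Y[rows, ] <- best$y }
    # shared components from the four parental genes / cross pairings
    A[rows] <- (rowSums(lookup_eta(model, P11)) +
                rowSums(lookup_eta(model, P12)) +
                rowSums(lookup_eta(model, P21)) +
                rowSums(lookup_eta(model, P22))) / (2 * sqrt(M))
    D[rows] <- (rowSums(lookup_phi(model, P11, P21)) +
                rowSums(lookup_phi(model, P11, P22)) +
                rowSums(lookup_phi(model, P12, P21)) +
                rowSums(lookup_phi(model, P12, P22))) / (4 * sqrt(M))
    RA[rows] <- (rowSums(lookup_eta(model, best$c1)) +
                 rowSums(lookup_eta(model, best$c2))) / sqrt(M) - A[rows]
    RD[rows] <- rowSums(lookup_phi(model, best$c1, best$c2)) / sqrt(M) -
      D[rows]
  }

  restore <- local_seed(derive_seed(seed, "noise"))
  E <- if (model$sigma_E2 > 0) {
    if (env_shared) {
      fam <- paste(ped$parent1, ped$parent2, ped$generation)
      fam[is.na(pi[, 1L])] <- paste0("founder", seq_along(which(is.na(pi[, 1L]))))
      u <- stats::rnorm(length(unique(fam)), 0, sqrt(model$sigma_E2))
      u[match(fam, unique(fam))]
    } else stats::rnorm(n, 0, sqrt(model$sigma_E2))
  } else numeric(n)
  restore()

  Z <- model$z_bar_0 + A + D + RA + RD
  out <- list(decomp = data.frame(id = ped$id, generation = ped$generation,
                                  A = A, D = D, RA = RA, RD = RD, E = E,
                                  Z = Z, Z_tilde = Z + E,
                                  stringsAsFactors = FALSE),
              g1 = g1, g2 = g2, X = X, Y = Y)
  class(out) <- "trait_sim"
  out
}

#' Within-family truncation selection run
#'
#' Convenience wrapper for [simulate_pedigree_traits()] with
#' `n_candidates` independent Mendelian draws per offspring, keeping the one
#' with the larger genetic value (selection acts on `Z`; the environmental
#' component is disregarded).
#'
#' @inheritParams simulate_pedigree_traits
#' @export
truncation_selection_sim <- function(ped, model, seed = 1L,
                                     n_candidates = 2L, ...) {
  simulate_pedigree_traits(ped, model, seed = seed,
                           n_candidates = n_candidates, ...)
}

#' Sample offspring of one fixed parent pair
#'
#' `n_offspring` independent Mendelian draws from two fixed parental
#' genotypes; the shared components `A`, `D` are constant across the family
#' and the residuals `RA`, `RD` are independent across offspring.
#'
#' @param model an [ancestral_model()].
#' @param parent1,parent2 lists with allele-index vectors `g1`, `g2` of
#'   length `M` (a row of a [simulate_pedigree_traits()] result, or founder
#'   draws).
#' @param n_offspring family size.
#' @param seed integer seed.
#' @return List with `decomp` (one row per offspring) and genotype matrices
#'   `g1`, `g2`.
#' @export
within_family_sample <- function(model, parent1, parent2, n_offspring,
                                 seed = 1L) {
  M <- model$M
  stopifnot(length(parent1$g1) == M, length(parent2$g1) == M)
  restore <- local_seed(derive_seed(seed, "family"))
  on.exit(restore(), add = TRUE)
  n <- as.integer(n_offspring)
  x <- matrix(stats::runif(n * M) < 0.5, n, M)
  y <- matrix(stats::runif(n * M) < 0.5, n, M)
  P11 <- matrix(parent1$g1, n, M, byrow = TRUE)
  P12 <- matrix(parent1$g2, n, M, byrow = TRUE)
  P21 <- matrix(parent2$g1, n, M, byrow = TRUE)
  P22 <- matrix(parent2$g2, n, M, byrow = TRUE)
  c1 <- P11 * x + P12 * (1 - x)
  c2 <- P21 * y + P22 * (1 - y)
  one <- function(v) matrix(v, 1L)
  A <- (sum(lookup_eta(model, one(parent1$g1))) +
        sum(lookup_eta(model, one(parent1$g2))) +
        sum(lookup_eta(model, one(parent2$g1))) +
        sum(lookup_eta(model, one(parent2$g2)))) / (2 * sqrt(M))
  D <- (sum(lookup_phi(model, one(parent1$g1), one(parent2$g1))) +
        sum(lookup_phi(model, one(parent1$g1), one(parent2$g2))) +
        sum(lookup_phi(model, one(parent1$g2), one(parent2$g1))) +
        sum(lookup_phi(model, one(parent1$g2), one(parent2$g2)))) /
    (4 * sqrt(M))
  RA <- (rowSums(lookup_eta(model, c1)) + rowSums(lookup_eta(model, c2))) /
    sqrt(M) - A
  RD <- rowSums(lookup_phi(model, c1, c2)) / sqrt(M) - D
  Z <- model$z_bar_0 + A + D + RA + RD
  list(decomp = data.frame(A = A, D = D, RA = RA, RD = RD, Z = Z),
       g1 = c1, g2 = c2)
}

#' Genic versus total variance components
#'
#' For each group of individuals, the "total" components are the sample
#' variances and covariance across individuals of the summed per-locus
#' additive contributions \eqn{a = M^{-1/2}\sum_l (\eta(\chi^1_l) +
#' \eta(\chi^2_l))} and dominance contributions
#' \eqn{d = M^{-1/2}\sum_l \phi(\chi^1_l, \chi^2_l)}; the "genic" components
#' drop the cross-locus (linkage-disequilibrium) covariances and sum the
#' per-locus variances/covariances instead.
#'
#' @param model an [ancestral_model()].
#' @param sim a `trait_sim` result (or any list with `g1`, `g2`).
#' @param grouping vector of group labels, one per row of `g1`.
#' @return Data frame with one row per group: total and genic `VA`, `VD`,
#'   `cov_AD`, `VG` and the group size `n`.
#' @export
genic_vs_total_variance <- function(model, sim, grouping) {
  g1 <- sim$g1; g2 <- sim$g2
  stopifnot(length(grouping) == nrow(g1))
  sm <- sqrt(model$M)
  out <- lapply(split(seq_len(nrow(g1)), grouping), function(rows) {
    if (!length(rows)) return(NULL)
    a_mat <- (lookup_eta(model, g1[rows, , drop = FALSE]) +
              lookup_eta(model, g2[rows, , drop = FALSE])) / sm
    d_mat <- lookup_phi(model, g1[rows, , drop = FALSE],
                        g2[rows, , drop = FALSE]) / sm
    n <- length(rows)
    if (n < 2L) {
      z <- data.frame(VA = 0, VD = 0, cov_AD = 0, VG = 0,
                      VA_genic = 0, VD_genic = 0, cov_AD_genic = 0,
                      VG_genic = 0, n = n)
      return(z)
    }
    a <- rowSums(a_mat); d <- rowSums(d_mat)
    ac <- sweep(a_mat, 2L, colMeans(a_mat))
    dc <- sweep(d_mat, 2L, colMeans(d_mat))
    va_g <- sum(colSums(ac^2)) / (n - 1)
    vd_g <- sum(colSums(dc^2)) / (n - 1)
    cad_g <- sum(colSums(ac * dc)) / (n - 1)
    data.frame(VA = stats::var(a), VD = stats::var(d),
               cov_AD = stats::cov(a, d), VG = stats::var(a + d),
               VA_genic = va_g, VD_genic = vd_g, cov_AD_genic = cad_g,
               VG_genic = va_g + vd_g + 2 * cad_g, n = n)
  })
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  res$group <- names(out)[keep]
  res[c("group", setdiff(names(res), "group"))]
}

#' Group-wise empirical moments of the trait decomposition
#'
#' Means, variances and covariance of the classical additive part
#' \eqn{\mathcal{A} = A + RA}, dominance deviation
#' \eqn{\mathcal{D} = D + RD}, and their sum \eqn{G}, per group.
#'
#' @param decomp the `decomp` data frame of a `trait_sim`.
#' @param grouping vector of group labels (defaults to `generation`).
#' @return Data frame with one row per group.
#' @export
empirical_moments <- function(decomp, grouping = decomp$generation) {
  out <- lapply(split(decomp, grouping), function(d) {
    Acl <- d$A + d$RA; Dcl <- d$D + d$RD; G <- Acl + Dcl
    n <- nrow(d)
    data.frame(mean_A = mean(Acl), mean_D = mean(Dcl), mean_G = mean(G),
               var_A = if (n > 1) stats::var(Acl) else 0,
               var_D = if (n > 1) stats::var(Dcl) else 0,
               cov_AD = if (n > 1) stats::cov(Acl, Dcl) else 0,
               var_G = if (n > 1) stats::var(G) else 0,
               mean_Z = mean(d$Z), var_Z = if (n > 1) stats::var(d$Z) else 0,
               n = n)
  })
  res <- do.call(rbind, out)
  res$group <- rownames(res)
  rownames(res) <- NULL
  res[c("group", setdiff(names(res), "group"))]
}
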