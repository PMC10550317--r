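#' Normalize raw genotype effects into mean, additive and dominance tables
#'
#' Given the raw (order-one, scaled) genotype values \eqn{g(x,x')} of one
#' locus and the ancestral allele distribution \eqn{\nu}, returns the unique
#' decomposition \eqn{g(x,x') = \mu + \eta(x) + \eta(x') + \phi(x,x')} with
#' \eqn{E[\eta(\hat\chi)] = 0} and \eqn{E[\phi(\hat\chi, x')] = 0} for every
#' \eqn{x'}: \eqn{\mu} is the mean genotype value under Hardy-Weinberg
#' proportions, \eqn{\eta(x) = E[g(x,\hat\chi)] - \mu} the average
#' (additive) effect, and \eqn{\phi} the dominance deviation table.  The
#' operation is idempotent and loses no information.
#'
#' @param raw symmetric numeric k x k matrix of genotype values.
#' @param nu probability vector of length k.
#' @return List with `mu` (scalar), `eta` (length-k vector) and `phi`
#'   (k x k symmetric matrix).
#' @examples
#' normalize_effects(matrix(c(-1, 1, 1, 1), 2, 2), c(0.5, 0.5))
#' @export
normalize_effects <- function(raw, nu) {
  raw <- as.matrix(raw)
  if (!isSymmetric(unname(raw), tol = 1e-12))
    stop("raw genotype table must be symmetric")
  if (length(nu) != nrow(raw) || any(nu < 0) || abs(sum(nu) - 1) > 1e-10)
    stop("nu must be a probability vector matching the table dimension")
  nu <- nu / sum(nu)
  mu <- drop(nu %*% raw %*% nu)
  eta <- drop(raw %*% nu) - mu
  phi <- raw - mu - outer(eta, eta, `+`)
  list(mu = mu, eta = eta, phi = phi)
}

#' Construct an ancestral locus model
#'
#' Bundles per-locus allele distributions and normalized effect tables into
#' an `ancestral_model`.  The genetic trait value of a genotype is
#' \deqn{Z = \bar z_0 + M^{-1/2} \sum_l (\eta_l(\chi^1_l) + \eta_l(\chi^2_l)
#'   + \phi_l(\chi^1_l, \chi^2_l)),}
#' so the stored `eta`/`phi` tables are order one and the single
#' \eqn{M^{-1/2}} factor lives in trait assembly.
#'
#' @param loci list with one entry per locus: `alleles` (labels), `nu`,
#'   `eta`, `phi`, `mu` (as produced by [normalize_effects()]).
#' @param z_bar_0 ancestral mean trait value.
#' @param sigma_E2 environmental variance (default 0).
#' @return An `ancestral_model`: list with `loci`, `M`, `z_bar_0`, `B`
#'   (effect bound), `sigma_E2`, and dense lookup arrays `nu_mat` (M x k),
#'   `eta_mat` (M x k), `phi_arr` (M x k x k) padded with zeros where a
#'   locus has fewer alleles.
#' @export
ancestral_model <- function(loci, z_bar_0 = 0, sigma_E2 = 0) {
  stopifnot(length(loci) >= 1L, sigma_E2 >= 0)
  M <- length(loci)
  kmax <- max(vapply(loci, function(l) length(l$nu), 0L))
  nu_mat <- matrix(0, M, kmax)
  eta_mat <- matrix(0, M, kmax)
  phi_arr <- array(0, c(M, kmax, kmax))
  for (l in seq_len(M)) {
    k <- length(loci[[l]]$nu)
    nu_mat[l, seq_len(k)] <- loci[[l]]$nu
    eta_mat[l, seq_len(k)] <- loci[[l]]$eta
    phi_arr[l, seq_len(k), seq_len(k)] <- loci[[l]]$phi
  }
  model <- list(loci = loci, M = M, z_bar_0 = z_bar_0,
                B = max(abs(eta_mat), abs(phi_arr)), sigma_E2 = sigma_E2,
                nu_mat = nu_mat, eta_mat = eta_mat, phi_arr = phi_arr)
  class(model) <- "ancestral_model"
  check_normalized(model)
  model
}

check_normalized <- function(model, tol = 1e-8) {
  for (l in seq_len(model$M)) {
    loc <- model$loci[[l]]
    if (abs(sum(loc$nu * loc$eta)) > tol)
      stop("locus ", l, " not normalized: E[eta] != 0")
    if (max(abs(drop(loc$phi %*% loc$nu))) > tol)
      stop("locus ", l, " not normalized: E[phi(., x')] != 0")
  }
  invisible(model)
}

#' @export
print.ancestral_model <- function(x, ...) {
  vc <- variance_components(x)
  cat(sprintf(paste0("ancestral_model: M = %d loci, z_bar_0 = %.4g, ",
                     "sigma_E2 = %.4g\n"), x$M, x$z_bar_0, x$sigma_E2))
  cat(sprintf("  sigma_A2 = %.4f  sigma_D2 = %.4f  iota = %.4f\n",
              vc$sigma_A2, vc$sigma_D2, vc$iota))
  invisible(x)
}

#' Variance components of an ancestral model
#'
#' Exact sums over the per-locus allele distributions of the classical
#' quantities: additive variance
#' \eqn{\sigma_A^2 = (2/M)\sum_l E[\eta_l(\hat\chi)^2]}, dominance variance
#' \eqn{\sigma_D^2 = (1/M)\sum_l E[\phi_l(\hat\chi^1,\hat\chi^2)^2]},
#' inbreeding depression
#' \eqn{\iota = M^{-1/2}\sum_l E[\phi_l(\hat\chi,\hat\chi)]}, the sum of
#' squared locus-specific inbreeding depressions
#' \eqn{\iota^* = (1/M)\sum_l E[\phi_l(\hat\chi,\hat\chi)]^2}, the dominance
#' variance among inbred individuals
#' \eqn{\sigma_{DI}^2 = (1/M)\sum_l \mathrm{Var}[\phi_l(\hat\chi,\hat\chi)]},
#' and the additive-dominance covariance of inbred individuals
#' \eqn{\sigma_{ADI} = (2/M)\sum_l E[\eta_l(\hat\chi)\phi_l(\hat\chi,\hat\chi)]}.
#'
#' @param model an [ancestral_model()].
#' @return List of class `variance_components` with fields `sigma_A2`,
#'   `sigma_D2`, `iota`, `iota_star`, `sigma_DI2`, `sigma_ADI`, `z_bar_0`,
#'   `sigma_E2`, plus `cross_term` (the exact per-locus mean of
#'   \eqn{E[\eta(\hat\chi^1)\phi(\hat\chi^1,\hat\chi^2)]}, identically zero
#'   after normalization).
#' @export
variance_components <- function(model) {
  check_normalized(model)
  nu <- model$nu_mat; eta <- model$eta_mat
  M <- model$M
  Eeta2 <- rowSums(nu * eta^2)
  m <- numeric(M); v <- numeric(M); d <- numeric(M); cc <- numeric(M)
  cross <- numeric(M)
  for (l in seq_len(M)) {
    nul <- nu[l, ]; phil <- model$phi_arr[l, , ]
    diagphi <- diag(phil)
    m[l] <- sum(nul * diagphi)
    v[l] <- sum(nul * diagphi^2)
    d[l] <- drop(nul %*% phil^2 %*% nul)
    cc[l] <- sum(nul * eta[l, ] * diagphi)
    cross[l] <- drop((nul * eta[l, ]) %*% phil %*% nul)
  }
  out <- list(sigma_A2 = 2 * mean(Eeta2), sigma_D2 = mean(d),
              iota = sum(m) / sqrt(M), iota_star = mean(m^2),
              sigma_DI2 = mean(v - m^2), sigma_ADI = 2 * mean(cc),
              z_bar_0 = model$z_bar_0, sigma_E2 = model$sigma_E2,
              cross_term = mean(cross))
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("variance components: sigma_A2 = %.4f, sigma_D2 = %.4f,",
                     " iota = %.4f,\n  iota* = %.4f, sigma_DI2 = %.4f, ",
                     "sigma_ADI = %.4f, z_bar_0 = %.4g, sigma_E2 = %.4g\n"),
              x$sigma_A2, x$sigma_D2, x$iota, x$iota_star, x$sigma_DI2,
              x$sigma_ADI, x$z_bar_0, x$sigma_E2))
  invisible(x)
}

#' Sample allele frequencies mimicking near-neutral segregating loci
#'
#' Two dialects of the same recipe.  `continuous`: frequencies on (0, 1)
#' with density proportional to \eqn{(p(1-p))^{-1+\epsilon}} (the neutral
#' frequency spectrum, regularized by a small \eqn{\epsilon}), with draws in
#' \eqn{[0, 1/2N]} and \eqn{[1 - 1/2N, 1]} discarded; sampled exactly by
#' inverse-CDF of the truncated Beta(\eqn{\epsilon,\epsilon}).
#' `sample_counts`: frequencies restricted to the grid \eqn{i/2N},
#' \eqn{i = 1,\dots,2N-1}, with weights \eqn{(i(2N-i))^{-1+\epsilon}} (the
#' spectrum conditioned to segregate in a sample of \eqn{2N} genes).
#'
#' @param n number of draws.
#' @param dialect `"sample_counts"` (default) or `"continuous"`.
#' @param two_N_ref reference number of genes (default 60).
#' @param eps regularization exponent (default 0.001).
#' @return Numeric vector of frequencies in (0, 1).
#' @keywords internal
sample_neutral_freqs <- function(n, dialect = c("sample_counts", "continuous"),
                                 two_N_ref = 60, eps = 0.001) {
  dialect <- match.arg(dialect)
  if (dialect == "continuous") {
    lo <- stats::pbeta(1 / two_N_ref, eps, eps)
    hi <- stats::pbeta(1 - 1 / two_N_ref, eps, eps)
    stats::qbeta(stats::runif(n, lo, hi), eps, eps)
  } else {
    i <- seq_len(two_N_ref - 1L)
    w <- (i * (two_N_ref - i))^(eps - 1)
    i[sample.int(length(i), n, replace = TRUE, prob = w)] / two_N_ref
  }
}

#' Generate a bi-allelic complete-dominance base population
#'
#' The standing recipe for the numerical studies: `M` unlinked bi-allelic
#' loci; at each locus the three genotypes `aa : aA : AA` take (unscaled)
#' values \eqn{-\alpha : -\alpha : +\alpha} or
#' \eqn{-\alpha : +\alpha : +\alpha} with \eqn{\alpha = 1/\sqrt M}, the
#' second (A-dominant) pattern chosen independently per locus with
#' probability \eqn{H = 1/2 + c_H/\sqrt M}; allele frequencies are drawn
#' from a truncated near-neutral distribution
#' ([sample_neutral_freqs()]).  Raw values are scaled by \eqn{\sqrt M}
#' (giving order-one \eqn{\pm 1} effects, the \eqn{M^{-1/2}} factor living
#' in trait assembly) and passed through [normalize_effects()].  The small
#' \eqn{O(1/\sqrt M)} excess of A-dominant loci keeps the inbreeding
#' depression \eqn{\iota} bounded while individual locus contributions
#' cancel in a random-walk fashion.
#'
#' @param M number of loci.
#' @param seed integer seed.
#' @param c_H dominance-direction bias constant (default 1): the per-locus
#'   probability of the A-dominant pattern is \eqn{1/2 + c_H/\sqrt M}.
#' @param freq_dialect `"sample_counts"` (default) or `"continuous"`.
#' @param two_N_ref,eps frequency-distribution parameters.
#' @param sigma_E2 environmental variance attached to the model.
#' @return An [ancestral_model()] whose per-locus entries carry `p` (the
#'   drawn frequency of allele `A`) and `dominant_plus` (whether the
#'   heterozygote takes the `+` value) alongside the normalized tables.
#' @examples
#' m <- make_biallelic_dominance_model(100, seed = 1)
#' variance_components(m)
#' @export
make_biallelic_dominance_model <- function(M, seed = 1L, c_H = 1,
                                           freq_dialect = c("sample_counts",
                                                            "continuous"),
                                           two_N_ref = 60, eps = 0.001,
                                           sigma_E2 = 0) {
  stopifnot(M >= 1)
  freq_dialect <- match.arg(freq_dialect)
  restore <- local_seed(derive_seed(seed, "basepop"))
  on.exit(restore(), add = TRUE)
  p <- sample_neutral_freqs(M, freq_dialect, two_N_ref, eps)
  H <- 0.5 + c_H / sqrt(M)
  if (H > 1 || H < 0) stop("c_H/sqrt(M) pushes H outside [0, 1]")
  dominant_plus <- stats::runif(M) < H
  z0 <- 0
  loci <- vector("list", M)
  for (l in seq_len(M)) {
    nu <- c(a = 1 - p[l], A = p[l])
    het <- if (dominant_plus[l]) 1 else -1   # scaled by sqrt(M): alpha -> 1
    raw <- matrix(c(-1, het, het, 1), 2, 2,
                  dimnames = list(c("a", "A"), c("a", "A")))
    nm <- normalize_effects(raw, nu)
    z0 <- z0 + nm$mu
    loci[[l]] <- list(alleles = c("a", "A"), nu = unname(nu),
                      eta = unname(nm$eta), phi = unname(nm$phi),
                      mu = nm$mu, p = p[l],
                      dominant_plus = dominant_plus[l])
  }
  # deviations are measured from the ancestral mean: z_bar_0 = 0 by
  # convention; per-locus means are recorded in loci[[l]]$mu
  ancestral_model(loci, z_bar_0 = 0, sigma_E2 = sigma_E2)
}

#' Sample founder genotypes under Hardy-Weinberg and linkage equilibrium
#'
#' Each gene copy is an independent draw from the locus allele distribution,
#' independently across individuals, loci and copies.
#'
#' @param model an [ancestral_model()].
#' @param n_founders number of individuals.
#' @param seed integer seed.
#' @return List with integer allele-index matrices `g1`, `g2`
#'   (`n_founders` x `M`).
#' @export
sample_founder_genotypes <- function(model, n_founders, seed = 1L) {
  stopifnot(n_founders >= 1)
  restore <- local_seed(derive_seed(seed, "founders"))
  on.exit(restore(), add = TRUE)
  draw_genotype_matrix(model, n_founders)
}

# n x M allele-index draws from nu, twice (uses current RNG state)
draw_genotype_matrix <- function(model, n) {
  M <- model$M
  cum <- t(apply(model$nu_mat, 1L, cumsum))     # M x k
  draw1 <- function() {
    u <- matrix(stats::runif(n * M), n, M)
    g <- matrix(1L, n, M)
    if (ncol(cum) > 1L) for (j in 2:ncol(cum))
      g <- g + (u > rep(cum[, j - 1L], each = n))
    g
  }
  list(g1 = draw1(), g2 = draw1())
}

#' Genetic trait values of genotypes
#'
#' Evaluates \eqn{Z = \bar z_0 + M^{-1/2}\sum_l(\eta_l(\chi^1_l) +
#' \eta_l(\chi^2_l) + \phi_l(\chi^1_l,\chi^2_l))} for one genotype or a
#' matrix of genotypes.
#'
#' @param model an [ancestral_model()].
#' @param g1,g2 integer allele indices, vectors of length `M` or
#'   `n x M` matrices.
#' @return Numeric vector of trait values.
#' @export
trait_value <- function(model, g1, g2) {
  if (is.null(dim(g1))) g1 <- matrix(g1, 1L)
  if (is.null(dim(g2))) g2 <- matrix(g2, 1L)
  stopifnot(ncol(g1) == model$M, all(dim(g1) == dim(g2)))
  if (any(g1 < 1L) || any(g2 < 1L) || any(g1 > ncol(model$nu_mat)) ||
      any(g2 > ncol(model$nu_mat)))
    stop("allele index out of range")
  model$z_bar_0 +
    (rowSums(lookup_eta(model, g1)) + rowSums(lookup_eta(model, g2)) +
     rowSums(lookup_phi(model, g1, g2))) / sqrt(model$M)
}

# eta/phi lookups for n x M genotype matrices
lookup_eta <- function(model, g) {
  n <- nrow(g)
  matrix(model$eta_mat[cbind(rep(seq_len(model$M), each = n), as.vector(g))],
         n, model$M)
}
lookup_phi <- function(model, ga, gb) {
  n <- nrow(ga)
  matrix(model$phi_arr[cbind(rep(seq_len(model$M), each = n), as.vector(ga),
                             as.vector(gb))], n, model$M)
}

#' Read / write ancestral models as JSON
#'
#' Serializes the per-locus tables (`alleles`, `nu`, `eta`, `phi`, `mu`) and
#' the model-level fields (`M`, `z_bar_0`, `B`, `sigma_E2`).
#'
#' @param model an [ancestral_model()].
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(M = model$M, z_bar_0 = model$z_bar_0, B = model$B,
              sigma_E2 = model$sigma_E2,
              loci = lapply(model$loci, function(l)
                list(alleles = l$alleles, nu = l$nu, eta = l$eta,
                     phi = l$phi, mu = l$mu)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  loci <- lapply(obj$loci, function(e) {
    k <- length(e$nu)
    list(alleles = unlist(e$alleles), nu = as.numeric(unlist(e$nu)),
         eta = as.numeric(unlist(e$eta)),
         phi = matrix(as.numeric(unlist(e$phi)), k, k, byrow = TRUE),
         mu = as.numeric(e$mu))
  })
  ancestral_model(loci, z_bar_0 = as.numeric(obj$z_bar_0),
                  sigma_E2 = as.numeric(obj$sigma_E2))
}
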