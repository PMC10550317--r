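#' Neutral-evolution experiment: empirical versus predicted moments
#'
#' One fixed pedigree; `n_reps` replicate ancestral draws and gene drops.
#' For every individual the across-replicate mean and variance of the
#' classical additive part \eqn{\mathcal A = A + RA}, dominance deviation
#' \eqn{\mathcal D = D + RD}, their covariance, and the trait `Z` are
#' accumulated and averaged within generations, next to the closed-form
#' predictions driven by each individual's inbreeding coefficient
#' ([trait_moments()]).  Monte Carlo standard errors are returned
#' conservatively as the generation-average of the per-individual standard
#' errors (individuals within a replicate are correlated, so no
#' \eqn{\sqrt{N}} reduction is claimed).
#'
#' @param ped a [pedigree()].
#' @param model an [ancestral_model()].
#' @param n_reps replicate count.
#' @param seed master seed.
#' @param n_candidates 1 for neutral; >1 applies within-family truncation
#'   selection ([truncation_selection_sim()]).
#' @return Data frame, one row per generation: empirical columns (`emp_*`),
#'   predictions (`pred_*`), and standard errors (`se_*`).
#' @export
neutral_experiment <- function(ped, model, n_reps = 100L, seed = 1L,
                               n_candidates = 1L) {
  n <- nrow(ped)
  acc <- matrix(0, n, 10L,
                dimnames = list(NULL, c("A", "D", "Z", "A2", "D2", "AD",
                                        "Z2", "G", "G2", "E")))
  for (r in seq_len(n_reps)) {
    sim <- simulate_pedigree_traits(ped, model, seed = derive_seed(seed, "rep", r),
                                    n_candidates = n_candidates)
    d <- sim$decomp
    Acl <- d$A + d$RA; Dcl <- d$D + d$RD; G <- Acl + Dcl
    acc <- acc + cbind(Acl, Dcl, d$Z, Acl^2, Dcl^2, Acl * Dcl, d$Z^2,
                       G, G^2, d$E)
  }
  acc <- acc / n_reps
  R <- n_reps
  vA <- (acc[, "A2"] - acc[, "A"]^2) * R / (R - 1)
  vD <- (acc[, "D2"] - acc[, "D"]^2) * R / (R - 1)
  cAD <- (acc[, "AD"] - acc[, "A"] * acc[, "D"]) * R / (R - 1)
  vZ <- (acc[, "Z2"] - acc[, "Z"]^2) * R / (R - 1)
  K <- kinship_matrix(ped)
  Fii <- 2 * diag(K) - 1
  pred <- trait_moments(variance_components(model), Fii)
  per_ind <- data.frame(generation = ped$generation,
                        emp_mean_A = acc[, "A"], emp_mean_D = acc[, "D"],
                        emp_mean_Z = acc[, "Z"], emp_var_A = vA,
                        emp_var_D = vD, emp_cov_AD = cAD, emp_var_Z = vZ,
                        se_mean_A = sqrt(pmax(vA, 0) / R),
                        se_mean_D = sqrt(pmax(vD, 0) / R),
                        se_mean_Z = sqrt(pmax(vZ, 0) / R),
                        se_var_A = vA * sqrt(2 / (R - 1)),
                        se_var_D = vD * sqrt(2 / (R - 1)),
                        se_var_Z = vZ * sqrt(2 / (R - 1)),
                        se_cov_AD = sqrt(pmax(vA * vD, 0) / (R - 1)),
                        pred_mean_A = pred$mean_A, pred_mean_D = pred$mean_D,
                        pred_mean_Z = pred$mean_Z, pred_var_A = pred$var_A,
                        pred_var_D = pred$var_D, pred_cov_AD = pred$cov_AD,
                        pred_var_Z = pred$var_Z, F_ii = Fii)
  agg <- stats::aggregate(per_ind[-1L], by = list(generation = per_ind$generation),
                          FUN = mean)
  attr(agg, "per_individual") <- per_ind
  agg
}

#' Within-family residual-variance experiment
#'
#' Parent pairs are drawn (with replacement) from one generation of the
#' pedigree; each family produces `n_offspring` Mendelian draws per
#' replicate.  Empirical within-family variances and covariance of `RA`,
#' `RD`, averaged over replicates, are returned next to the closed-form
#' predictions [family_residual_components()] evaluated on each pair's
#' identity coefficients.  Selfed pairs (same parent twice) are flagged.
#'
#' @param ped a [pedigree()].
#' @param model an [ancestral_model()].
#' @param generation generation from which parents are drawn.
#' @param n_pairs number of parent pairs.
#' @param n_offspring family size.
#' @param n_reps replicates (fresh ancestral draw each, same pairs).
#' @param seed master seed.
#' @param selfing allow a pair to be the same individual twice.
#' @return Data frame, one row per pair: `parent1`, `parent2`, `selfed`,
#'   empirical `VRA`, `VRD`, `VRA_RD`, predictions `pred_*`, and `F12`.
#' @export
family_experiment <- function(ped, model, generation = 0L, n_pairs = 100L,
                              n_offspring = 1000L, n_reps = 1L, seed = 1L,
                              selfing = TRUE) {
  members <- generation_members(ped, generation)
  restore <- local_seed(derive_seed(seed, "pairs"))
  pick1 <- sample(members, n_pairs, replace = TRUE)
  pick2 <- sample(members, n_pairs, replace = TRUE)
  restore()
  if (!selfing) {
    clash <- pick1 == pick2
    while (any(clash)) {
      restore <- local_seed(derive_seed(seed, "pairs2", sum(clash)))
      pick2[clash] <- sample(members, sum(clash), replace = TRUE)
      restore()
      clash <- pick1 == pick2
    }
  }
  # identity sets of each pair, via a child-extended pedigree
  cache <- ibd_cache(ped)
  vc <- variance_components(model)
  pids <- lapply(seq_len(n_pairs), function(k)
    pair_identity_set(ped, pick1[k], pick2[k], cache))
  pred <- t(vapply(pids, function(p) family_residual_components(vc, p),
                   c(VRA = 0, VRD = 0, VRA_RD = 0)))

  accVRA <- accVRD <- accC <- numeric(n_pairs)
  rows1 <- match(pick1, ped$id); rows2 <- match(pick2, ped$id)
  for (r in seq_len(n_reps)) {
    sim <- simulate_pedigree_traits(ped, model,
                                    seed = derive_seed(seed, "famrep", r))
    for (k in seq_len(n_pairs)) {
      fam <- within_family_sample(
        model,
        list(g1 = sim$g1[rows1[k], ], g2 = sim$g2[rows1[k], ]),
        list(g1 = sim$g1[rows2[k], ], g2 = sim$g2[rows2[k], ]),
        n_offspring, seed = derive_seed(seed, "fam", r, k))
      accVRA[k] <- accVRA[k] + stats::var(fam$decomp$RA)
      accVRD[k] <- accVRD[k] + stats::var(fam$decomp$RD)
      accC[k] <- accC[k] + stats::cov(fam$decomp$RA, fam$decomp$RD)
    }
  }
  data.frame(parent1 = pick1, parent2 = pick2, selfed = pick1 == pick2,
             VRA = accVRA / n_reps, VRD = accVRD / n_reps,
             VRA_RD = accC / n_reps,
             pred_VRA = pred[, "VRA"], pred_VRD = pred[, "VRD"],
             pred_VRA_RD = pred[, "VRA_RD"],
             F12 = vapply(pids, function(p) unname(p["F12"]), 0),
             stringsAsFactors = FALSE)
}

# identity set of an arbitrary (possibly selfed) prospective parent pair
pair_identity_set <- function(ped, a, b, cache = ibd_cache(ped)) {
  if (a == b) {
    Fss <- 2 * phi_groups(ped, list(c(a, a)), cache) - 1
    return(c(F11 = Fss, F22 = Fss, F12 = (1 + Fss) / 2, F112 = Fss,
             F122 = Fss, F1122 = Fss, Ft_1212 = 1 - Fss, Ft_1122 = 0,
             selfed = 1))
  }
  p <- paper_identities(ped, a, b, cache)
  c(F11 = unname(p["Faa"]), F22 = unname(p["Fbb"]), F12 = unname(p["Fab"]),
    F112 = unname(p["Faab"]), F122 = unname(p["Fabb"]),
    F1122 = unname(p["Faabb"]), Ft_1212 = unname(p["Ft_abab"]),
    Ft_1122 = unname(p["Ft_aabb"]), selfed = 0)
}

#' Neutral versus truncation-selection trajectories
#'
#' Paired runs on the same pedigree and founder draws: a neutral arm and a
#' within-family truncation-selection arm (`n_candidates` draws per
#' offspring, larger genetic value retained).  Per generation and arm the
#' replicate-averaged means of \eqn{\mathcal A}, \eqn{\mathcal D}, `G` and
#' the total and genic variance components are returned.
#'
#' @inheritParams neutral_experiment
#' @param n_candidates candidates per offspring in the selected arm.
#' @return Data frame with columns `arm`, `generation`, means, total and
#'   genic components (replicate averages).
#' @export
selection_experiment <- function(ped, model, n_reps = 20L, seed = 1L,
                                 n_candidates = 2L) {
  run_arm <- function(arm, cand) {
    per_rep <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      sim <- simulate_pedigree_traits(ped, model,
                                      seed = derive_seed(seed, "rep", r),
                                      n_candidates = cand)
      em <- empirical_moments(sim$decomp)
      gt <- genic_vs_total_variance(model, sim, sim$decomp$generation)
      gt <- gt[match(em$group, gt$group), ]
      per_rep[[r]] <- cbind(em[c("group", "mean_A", "mean_D", "mean_G")],
                            gt[c("VA", "VD", "cov_AD", "VG", "VA_genic",
                                 "VD_genic", "cov_AD_genic", "VG_genic")])
    }
    num <- Reduce(`+`, lapply(per_rep, function(d) as.matrix(d[-1L]))) / n_reps
    data.frame(arm = arm, generation = as.integer(per_rep[[1L]]$group), num,
               stringsAsFactors = FALSE)
  }
  out <- rbind(run_arm("neutral", 1L), run_arm("selected", n_candidates))
  out[order(out$arm, out$generation), ]
}

#' Normality diagnostics of shared and residual components
#'
#' Residual values are centered by their family mean and pooled across
#' families and replicates; shared values are pooled directly.  For each
#' requested column the standardized empirical distribution is compared to
#' a Gaussian: the z-transformed CDF pairs and the Kolmogorov-Smirnov
#' distance (against the normal with the sample's fitted mean and variance)
#' are returned.
#'
#' @param values numeric vector of component values.
#' @param family factor of family labels (used for centering when
#'   `center_by_family = TRUE`).
#' @param center_by_family subtract family means before pooling (use for
#'   residual components; shared components are pooled as-is).
#' @param min_n minimum pooled sample size.
#' @return List with `ks_distance`, `ks_p`, `n`, and a data frame `cdf`
#'   with the sorted standardized values `z` and normal quantiles
#'   `z_normal` (straight line = Gaussian).
#' @export
normality_diagnostics <- function(values, family = NULL,
                                  center_by_family = FALSE, min_n = 50L) {
  if (center_by_family) {
    stopifnot(!is.null(family))
    values <- values - stats::ave(values, family)
  }
  values <- values[is.finite(values)]
  if (length(values) < min_n)
    stop("need at least ", min_n, " values for a normality diagnostic")
  zs <- (values - mean(values)) / stats::sd(values)
  ks <- suppressWarnings(stats::ks.test(zs, "pnorm"))
  srt <- sort(zs)
  pp <- stats::ppoints(length(srt))
  list(ks_distance = unname(ks$statistic), ks_p = ks$p.value,
       n = length(values),
       cdf = data.frame(z = srt, z_normal = stats::qnorm(pp)))
}

#' Exact toy-model posterior for a single held-out locus
#'
#' The toy bi-allelic trait: `M` loci, genotype priors 1/4 : 1/2 : 1/4, and
#' per-locus contributions \eqn{\Psi_l/\sqrt M} with
#' \eqn{\Psi_l = \pm 1}; the heterozygote takes the `+` value with
#' probability \eqn{H = 1/2 + c/\sqrt M}, so
#' \eqn{p_+ = P(\Psi_l = 1) = \frac12(1 + c/\sqrt M)}.  Conditioning on the
#' total \eqn{\sum_l \Psi_l = k}, Bayes' rule gives posterior/prior ratios
#' for the genotype classes at one locus:
#' \deqn{\frac{P[AA \mid k]}{P[AA]} = \frac{1 + k/M}{1 + c/\sqrt M},\qquad
#' \frac{P[aa \mid k]}{P[aa]} = \frac{1 - k/M}{1 - c/\sqrt M},}
#' and the heterozygote ratio is the direction mixture
#' \eqn{H\frac{1+k/M}{1+c/\sqrt M} + (1-H)\frac{1-k/M}{1-c/\sqrt M}}.
#' Both the closed forms and the exact convolution-based posteriors are
#' returned.
#'
#' @param M even positive number of loci.
#' @param k integer trait offset, `|k| <= M`, same parity as `M`.
#' @param c_bias direction-bias constant `c` (default 1).
#' @return List with `ratio_formula`, `ratio_exact` (each `c(AA, aa, het)`)
#'   and the posterior class probabilities `posterior`.
#' @export
toy_posterior_single <- function(M, k, c_bias = 1) {
  check_toy(M, k)
  H <- 0.5 + c_bias / sqrt(M)
  p_plus <- 0.25 + 0.5 * H
  prior <- c(AA = 0.25, aa = 0.25, het = 0.5)
  # P(sum_{l>=2} Psi = s) for s = k-1, k+1; exact binomial convolution
  ratio_tail <- function(s) {
    if (abs(s) > M - 1 || (M - 1 - s) %% 2 != 0) return(0)
    stats::dbinom((M - 1 + s) / 2, M - 1, p_plus)
  }
  denom <- stats::dbinom((M + k) / 2, M, p_plus)
  r_plus <- ratio_tail(k - 1) / denom   # P[sum rest = k-1]/P[sum = k]
  r_minus <- ratio_tail(k + 1) / denom
  ratio_exact <- c(AA = r_plus, aa = r_minus,
                   het = H * r_plus + (1 - H) * r_minus)
  ratio_formula <- c(AA = (1 + k / M) / (2 * p_plus),
                     aa = (1 - k / M) / (2 * (1 - p_plus)),
                     het = H * (1 + k / M) / (2 * p_plus) +
                       (1 - H) * (1 - k / M) / (2 * (1 - p_plus)))
  list(ratio_exact = ratio_exact, ratio_formula = ratio_formula,
       posterior = prior * ratio_exact, prior = prior,
       p_plus = p_plus, H = H)
}

#' Exact toy-model joint posterior for two held-out loci
#'
#' Joint posterior that loci 1 and 2 are both `AA`, its factorization into
#' the product of single-locus posteriors, and the exact correction term
#' \deqn{P[AA_1]P[AA_2]\,\frac{1+k/M}{(1+c/\sqrt M)^2}
#' \Big(\frac{k-1}{M-1} - \frac{k}{M}\Big),}
#' which is \eqn{O(1/M)} for typical trait values
#' (\eqn{k = O(\sqrt M)}).
#'
#' @inheritParams toy_posterior_single
#' @return List with `joint_exact`, `product_of_marginals`,
#'   `correction_exact` (= joint - product), `correction_formula`.
#' @export
toy_posterior_pair <- function(M, k, c_bias = 1) {
  check_toy(M, k)
  stopifnot(M >= 4)
  H <- 0.5 + c_bias / sqrt(M)
  p_plus <- 0.25 + 0.5 * H
  prior_AA <- 0.25
  denom <- stats::dbinom((M + k) / 2, M, p_plus)
  tail2 <- function(s) {
    if (abs(s) > M - 2 || (M - 2 - s) %% 2 != 0) return(0)
    stats::dbinom((M - 2 + s) / 2, M - 2, p_plus)
  }
  joint_ratio <- tail2(k - 2) / denom
  single <- toy_posterior_single(M, k, c_bias)
  joint_exact <- prior_AA^2 * joint_ratio
  prod_marg <- unname(single$posterior["AA"])^2
  corr_formula <- prior_AA^2 * (1 + k / M) / (2 * p_plus)^2 *
    ((k - 1) / (M - 1) - k / M)
  list(joint_exact = joint_exact, product_of_marginals = prod_marg,
       correction_exact = joint_exact - prod_marg,
       correction_formula = corr_formula)
}

check_toy <- function(M, k) {
  if (M < 2 || M %% 2 != 0) stop("M must be an even positive integer")
  if (abs(k) > M) stop("|k| must not exceed M")
  if ((M - k) %% 2 != 0) stop("k must have the same parity as M")
  invisible(TRUE)
}

#' Convergence of variance components with the number of loci
#'
#' Scaled-down sweep: for each `M` in `M_grid`, paired neutral and
#' truncation-selection runs on one pedigree; reported are the absolute
#' differences of the final-generation genic variance components between
#' arms, with Monte Carlo standard errors over replicates, and the log-log
#' regression slope of the difference against `M`.
#'
#' @param ped a [pedigree()].
#' @param M_grid vector of locus counts.
#' @param n_reps replicates per arm and `M`.
#' @param seed master seed.
#' @param model_args extra arguments for [make_biallelic_dominance_model()].
#' @return List with `table` (per-`M` differences and SEs) and `slopes`
#'   (log-log slope and SE per component).
#' @export
convergence_experiment <- function(ped, M_grid = c(100L, 300L, 1000L),
                                   n_reps = 10L, seed = 1L,
                                   model_args = list()) {
  comp <- c("VA_genic", "VD_genic", "cov_AD_genic", "VG_genic")
  last_gen <- max(ped$generation)
  rows <- lapply(M_grid, function(M) {
    model <- do.call(make_biallelic_dominance_model,
                     c(list(M = M, seed = derive_seed(seed, "model", M)),
                       model_args))
    diffs <- matrix(0, n_reps, length(comp), dimnames = list(NULL, comp))
    for (r in seq_len(n_reps)) {
      s0 <- simulate_pedigree_traits(ped, model,
                                     seed = derive_seed(seed, "cv", M, r))
      s1 <- simulate_pedigree_traits(ped, model,
                                     seed = derive_seed(seed, "cv", M, r),
                                     n_candidates = 2L)
      gsel <- function(s) {
        g <- genic_vs_total_variance(model, s, s$decomp$generation)
        as.numeric(g[g$group == as.character(last_gen), comp])
      }
      diffs[r, ] <- abs(gsel(s1) - gsel(s0))
    }
    data.frame(M = M, component = comp, diff = colMeans(diffs),
               se = apply(diffs, 2L, stats::sd) / sqrt(n_reps))
  })
  tab <- do.call(rbind, rows)
  slopes <- do.call(rbind, lapply(split(tab, tab$component), function(d) {
    fit <- stats::lm(log(pmax(d$diff, 1e-12)) ~ log(d$M))
    data.frame(component = d$component[1L],
               slope = unname(stats::coef(fit)[2L]),
               slope_se = summary(fit)$coefficients[2L, 2L])
  }))
  rownames(slopes) <- NULL
  list(table = tab, slopes = slopes)
}
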