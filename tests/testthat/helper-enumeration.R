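# Independent exact-moment oracle: enumerates every founder allele
# configuration and every Mendelian transmission pattern of a small
# pedigree, locus by locus, and accumulates the exact joint first and
# second moments of the per-individual quantities (A, D, RA, RD, Z).
# Written from the definitions (average parental contribution over the four
# parental genes / cross pairings; residual = realized - average); it never
# calls the package's simulator or formula code.
#
# Per-locus quantities are independent across loci given the pedigree, so
# totals combine as mean_tot = sum_l mean_l / sqrt(M) and
# cov_tot = sum_l cov_l / M.

enumerate_moments <- function(ped, model) {
  n <- nrow(ped)
  pidx <- cbind(match(ped$parent1, ped$id), match(ped$parent2, ped$id))
  fidx <- which(is.na(pidx[, 1L]))
  cidx <- which(!is.na(pidx[, 1L]))
  Fn <- length(fidx); Cn <- length(cidx)
  qn <- c("A", "D", "RA", "RD", "Z")
  labs <- as.vector(outer(qn, ped$id, paste, sep = "."))
  mean_tot <- stats::setNames(numeric(5L * n), labs)
  cov_tot <- matrix(0, 5L * n, 5L * n, dimnames = list(labs, labs))
  M <- model$M

  for (l in seq_len(M)) {
    nu <- model$loci[[l]]$nu
    eta <- model$loci[[l]]$eta
    phi <- model$loci[[l]]$phi
    k <- length(nu)
    m1 <- numeric(5L * n)
    m2 <- matrix(0, 5L * n, 5L * n)
    # founder gene configs: digits base k for 2*Fn genes
    n_cfg <- k^(2L * Fn)
    for (cfg in 0:(n_cfg - 1L)) {
      digits <- integer(2L * Fn); x <- cfg
      for (d in seq_len(2L * Fn)) { digits[d] <- x %% k + 1L; x <- x %/% k }
      pg <- prod(nu[digits])
      if (pg == 0) next
      g1 <- integer(n); g2 <- integer(n)
      g1[fidx] <- digits[seq_len(Fn) * 2L - 1L]
      g2[fidx] <- digits[seq_len(Fn) * 2L]
      for (bits in 0:(4L^Cn - 1L)) {
        pr <- pg / 4L^Cn
        b <- bits
        for (ci in cidx) {
          xbit <- b %% 2L; b <- b %/% 2L
          ybit <- b %% 2L; b <- b %/% 2L
          p1 <- pidx[ci, 1L]; p2 <- pidx[ci, 2L]
          g1[ci] <- if (xbit == 1L) g1[p1] else g2[p1]
          g2[ci] <- if (ybit == 1L) g1[p2] else g2[p2]
        }
        vec <- numeric(5L * n)
        for (i in seq_len(n)) {
          al <- eta[g1[i]] + eta[g2[i]]
          dl <- phi[g1[i], g2[i]]
          if (is.na(pidx[i, 1L])) {
            Ai <- 0; Di <- 0
          } else {
            p1 <- pidx[i, 1L]; p2 <- pidx[i, 2L]
            Ai <- (eta[g1[p1]] + eta[g2[p1]] + eta[g1[p2]] + eta[g2[p2]]) / 2
            Di <- (phi[g1[p1], g1[p2]] + phi[g1[p1], g2[p2]] +
                   phi[g2[p1], g1[p2]] + phi[g2[p1], g2[p2]]) / 4
          }
          o <- (i - 1L) * 5L
          vec[o + 1L] <- Ai; vec[o + 2L] <- Di
          vec[o + 3L] <- al - Ai; vec[o + 4L] <- dl - Di
          vec[o + 5L] <- al + dl
        }
        m1 <- m1 + pr * vec
        m2 <- m2 + pr * tcrossprod(vec)
      }
    }
    cov_l <- m2 - tcrossprod(m1)
    mean_tot <- mean_tot + m1 / sqrt(M)
    cov_tot <- cov_tot + cov_l / M
  }
  # labels are ordered per individual: A, D, RA, RD, Z; Z excludes z_bar_0
  labs2 <- as.vector(t(outer(ped$id, qn, function(i, q) paste(q, i, sep = "."))))
  list(mean = mean_tot, cov = cov_tot,
       get = function(q, i) paste(q, i, sep = "."))
}

# convenience extractors on an enumerate_moments() result
em_mean <- function(em, q, i) unname(em$mean[paste(q, i, sep = ".")])
em_cov <- function(em, q1, i1, q2, i2)
  em$cov[paste(q1, i1, sep = "."), paste(q2, i2, sep = ".")]
em_var_shared <- function(em, i)   # Var(A_i + D_i)
  em_cov(em, "A", i, "A", i) + em_cov(em, "D", i, "D", i) +
  2 * em_cov(em, "A", i, "D", i)
em_var_resid <- function(em, i)
  em_cov(em, "RA", i, "RA", i) + em_cov(em, "RD", i, "RD", i) +
  2 * em_cov(em, "RA", i, "RD", i)
em_cov_shared <- function(em, i, j)  # Cov(A_i+D_i, A_j+D_j)
  em_cov(em, "A", i, "A", j) + em_cov(em, "A", i, "D", j) +
  em_cov(em, "D", i, "A", j) + em_cov(em, "D", i, "D", j)
em_cov_shared_z <- function(em, i, p)  # Cov(A_i+D_i, Z_p)
  em_cov(em, "A", i, "Z", p) + em_cov(em, "D", i, "Z", p)
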