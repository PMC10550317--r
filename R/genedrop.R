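#' Monte Carlo gene-dropping estimates of identity coefficients
#'
#' Founders receive unique gene labels; labels are dropped down the pedigree
#' with independent fair coin flips per gene, individual and replicate.  For
#' each requested pair the empirical frequencies of the identity events (all
#' [paper_identities()] fields and the nine condensed states) are returned
#' together with binomial standard errors.  This is the validation oracle
#' for the exact recursion: an independent estimate of the same pedigree
#' functionals.
#'
#' @param ped a [pedigree()].
#' @param pairs two-column matrix or data frame of ids; `a == b` rows are
#'   allowed and report within-individual identity only.
#' @param n_reps number of replicate drops.
#' @param seed integer seed.
#' @return A data frame, one row per pair, with columns `<event>` and
#'   `<event>_se`.
#' @export
gene_drop_oracle <- function(ped, pairs, n_reps = 1e5, seed = 1L) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("empty pair list")
  stopifnot(n_reps >= 1)
  n_reps <- as.integer(n_reps)
  restore <- local_seed(derive_seed(seed, "genedrop"))
  on.exit(restore(), add = TRUE)

  n <- nrow(ped)
  pi <- parent_index(ped)
  need <- unique(as.vector(pairs))
  need_idx <- match(need, ped$id)
  if (anyNA(need_idx)) stop("unknown id: ", need[is.na(need_idx)][1L])

  # lab1[[i]], lab2[[i]]: integer vectors over replicates
  lab1 <- vector("list", n); lab2 <- vector("list", n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (is.na(pi[i, 1L])) {
      lab1[[i]] <- rep.int(next_label + 1L, n_reps)
      lab2[[i]] <- rep.int(next_label + 2L, n_reps)
      next_label <- next_label + 2L
    } else {
      p1 <- pi[i, 1L]; p2 <- pi[i, 2L]
      x <- stats::runif(n_reps) < 0.5
      y <- stats::runif(n_reps) < 0.5
      lab1[[i]] <- ifelse(x, lab1[[p1]], lab2[[p1]])
      lab2[[i]] <- ifelse(y, lab1[[p2]], lab2[[p2]])
    }
  }

  est <- function(hits) {
    p <- mean(hits)
    c(p, sqrt(p * (1 - p) / n_reps))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    ia <- match(pairs[r, 1L], ped$id); ib <- match(pairs[r, 2L], ped$id)
    a1 <- lab1[[ia]]; a2 <- lab2[[ia]]; b1 <- lab1[[ib]]; b2 <- lab2[[ib]]
    within_a <- a1 == a2; within_b <- b1 == b2
    # one random gene from each (resampled per replicate)
    ra <- ifelse(stats::runif(n_reps) < 0.5, a1, a2)
    rb <- ifelse(stats::runif(n_reps) < 0.5, b1, b2)
    if (pairs[r, 1L] == pairs[r, 2L]) {
      ev <- rbind(Faa = est(within_a))
    } else {
      cross11 <- a1 == b1; cross12 <- a1 == b2
      cross21 <- a2 == b1; cross22 <- a2 == b2
      any_cross_a1 <- cross11 | cross12
      any_cross_a2 <- cross21 | cross22
      all4 <- within_a & within_b & cross11
      disjoint <- (cross11 & cross22 & !within_a) |
                  (cross12 & cross21 & !within_a)
      n_cross <- cross11 + cross12 + cross21 + cross22
      ev <- rbind(
        Fab    = est(ra == rb),
        Faa    = est(within_a),
        Fbb    = est(within_b),
        Faab   = est(within_a & (a1 == rb)),
        Fabb   = est(within_b & (b1 == ra)),
        Faabb  = est(all4),
        Ft_abab = est(disjoint),
        Ft_aabb = est(within_a & within_b & !all4),
        delta1 = est(all4),
        delta2 = est(within_a & within_b & !all4),
        delta3 = est(within_a & !within_b & any_cross_a1),
        delta4 = est(within_a & !within_b & !any_cross_a1),
        delta5 = est(within_b & !within_a & any_cross_a2 |
                     (within_b & !within_a & any_cross_a1)),
        delta6 = est(!within_a & within_b & n_cross == 0),
        delta7 = est(disjoint),
        delta8 = est(!within_a & !within_b & n_cross == 1),
        delta9 = est(!within_a & !within_b & n_cross == 0))
    }
    out <- as.data.frame(t(c(ev[, 1L], stats::setNames(ev[, 2L],
                                                       paste0(rownames(ev), "_se")))))
    cbind(data.frame(a = pairs[r, 1L], b = pairs[r, 2L],
                     stringsAsFactors = FALSE), out)
  })
  do.call(rbind, rows)
}
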