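#' Kinship and inbreeding coefficients on a pedigree
#'
#' `kinship_matrix()` returns the full matrix of kinship coefficients
#' \eqn{F_{ab}}: the probability that one gene drawn uniformly at random
#' from `a` and one from `b` are identical by descent.  Diagonal entries
#' hold the *with-replacement* self-kinship \eqn{(1 + F_{aa})/2}, where
#' \eqn{F_{aa}} is the inbreeding coefficient (identity of the two distinct
#' genes of `a`, equal to the kinship of its parents).  Values are exact
#' dyadic rationals computed by the recursion
#' \eqn{F_{ab} = (F_{a[1]b} + F_{a[2]b})/2} on the later-born argument, with
#' founders pairwise unrelated and non-inbred.
#'
#' @param ped a [pedigree()].
#' @return A symmetric numeric matrix with dimnames `ped$id`.
#' @seealso [kinship()], [inbreeding()], [condensed_identity()]
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  pi <- parent_index(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (is.na(pi[i, 1L])) {
      K[i, i] <- 0.5
      next
    }
    p1 <- pi[i, 1L]; p2 <- pi[i, 2L]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * (K[p1, j] + K[p2, j])
      K[i, j] <- v
      K[j, i] <- v
    }
    K[i, i] <- 0.5 * (1 + K[p1, p2])
  }
  K
}

#' @rdname kinship_matrix
#' @param a,b individual ids.  `kinship(ped, a, a)` returns the
#'   with-replacement self-kinship \eqn{(1+F_{aa})/2}.
#' @export
kinship <- function(ped, a, b) {
  phi_groups(ped, list(c(a, b)))
}

#' @rdname kinship_matrix
#' @export
inbreeding <- function(ped, a) {
  i <- match(as.character(a), ped$id)
  if (is.na(i)) stop("unknown id: ", a)
  if (is.na(ped$parent1[i])) return(0)
  kinship(ped, ped$parent1[i], ped$parent2[i])
}

#' Mean pairwise identity per generation
#'
#' The mean of the kinship coefficient \eqn{F_{ab}} over unordered distinct
#' pairs within each generation.  Under random mating in a population of
#' constant size \eqn{N} this tracks \eqn{1 - (1 - 1/2N)^t}.
#'
#' @param ped a [pedigree()].
#' @return A data frame with columns `generation`, `mean_identity`, `n_pairs`.
#' @export
mean_pairwise_identity_by_generation <- function(ped) {
  K <- kinship_matrix(ped)
  gens <- sort(unique(ped$generation))
  out <- lapply(gens, function(t) {
    idx <- which(ped$generation == t)
    if (length(idx) < 2L)
      return(data.frame(generation = t, mean_identity = NA_real_, n_pairs = 0L))
    sub <- K[idx, idx, drop = FALSE]
    ut <- sub[upper.tri(sub)]
    data.frame(generation = t, mean_identity = mean(ut),
               n_pairs = length(ut))
  })
  do.call(rbind, out)
}
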