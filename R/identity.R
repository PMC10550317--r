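#' Generalized identity-by-descent functionals
#'
#' `phi_groups()` computes the probability that, at a single autosomal locus,
#' several independently sampled genes are simultaneously identical by
#' descent within each of one or more groups.  Each group is a multiset of
#' individual ids; every occurrence of an id stands for one independent
#' uniform draw among that individual's two genes (sampling *with
#' replacement* when an id is repeated).  The event is "within every group,
#' all sampled genes are IBD"; identity across groups is unconstrained.
#'
#' The computation is an exact recursion on the latest-generation individual
#' appearing in the state: each of its \eqn{k} draws independently resolves
#' to gene copy 1 (descended from `parent1`) or copy 2 (from `parent2`).
#' Draws resolving to the same copy are the *same* physical gene, so groups
#' that share it merge; the copy itself is one fresh draw from the
#' corresponding parent.  Averaging the recursively evaluated probability
#' over the \eqn{2^k} equiprobable resolutions gives the value.  Founder
#' genes are IBD only to themselves.  States are memoized, so batched
#' computations on one pedigree should share a `cache`.
#'
#' Two-way, three-way and four-way identity coefficients, including the nine
#' Jacquard condensed states, are linear combinations of these functionals.
#'
#' @param ped a [pedigree()].
#' @param groups list of character vectors of ids (one vector per group;
#'   repeats allowed).
#' @param cache an environment used for memoization (see [ibd_cache()]).
#' @return A probability.
#' @references Jacquard condensed identity states; recursive generalized
#'   kinship algorithms of the Karigl type.
#' @export
phi_groups <- function(ped, groups, cache = ibd_cache(ped)) {
  idx <- lapply(groups, function(g) {
    i <- match(as.character(g), ped$id)
    if (anyNA(i)) stop("unknown id: ", g[is.na(i)][1L])
    i
  })
  pi <- parent_index(ped)
  phi_groups_cpp(idx, as.integer(ped$generation),
                 as.integer(pi[, 1L] - 1L), as.integer(pi[, 2L] - 1L),
                 cache)
}

#' @rdname phi_groups
#' @export
ibd_cache <- function(ped) ibd_cache_cpp()

#' Condensed identity coefficients for a pair of individuals
#'
#' The nine Jacquard condensed states \eqn{\Delta_1,\dots,\Delta_9} classify
#' the joint IBD configuration of the four genes carried at one locus by an
#' ordered pair of distinct individuals `(a, b)`:
#' \eqn{\Delta_1} all four IBD; \eqn{\Delta_2} each individual's pair IBD
#' within itself but not across; \eqn{\Delta_3}/\eqn{\Delta_5} one
#' individual's pair IBD and IBD with exactly one gene of the other;
#' \eqn{\Delta_4}/\eqn{\Delta_6} one individual's pair IBD only;
#' \eqn{\Delta_7} two disjoint cross-pairs IBD; \eqn{\Delta_8} exactly one
#' cross-pair IBD; \eqn{\Delta_9} no IBD.  They are recovered exactly by
#' inverting the linear system linking them to eight generalized functionals
#' ([phi_groups()]).
#'
#' @param ped a [pedigree()].
#' @param a,b distinct individual ids.
#' @param cache memoization environment shared across calls on one pedigree.
#' @return `condensed_identity`: numeric vector `delta1..delta9` summing to
#'   one.  `paper_identities`: the derived two-, three- and four-way
#'   identity probabilities used by the trait-moment formulas (see Details).
#' @details `paper_identities` returns, for the ordered pair `(a, b)`:
#' `Fab` (kinship), `Faa`, `Fbb` (inbreeding coefficients), `Faab`, `Fabb`
#' (three-way identities of one individual's pair with a random gene of the
#' other), `Faabb` (all four genes IBD), `Ft_abab` (\eqn{\Delta_7}) and
#' `Ft_aabb` (\eqn{\Delta_2}).  The mapping from the condensed states is
#' `Fab = Δ1 + (Δ3+Δ5+Δ7)/2 + Δ8/4`, `Faa = Δ1+Δ2+Δ3+Δ4`,
#' `Fbb = Δ1+Δ2+Δ5+Δ6`, `Faab = Δ1 + Δ3/2`, `Fabb = Δ1 + Δ5/2`,
#' `Faabb = Δ1`.
#' @export
condensed_identity <- function(ped, a, b, cache = ibd_cache(ped)) {
  a <- as.character(a); b <- as.character(b)
  if (identical(a, b))
    stop("condensed identity is defined for distinct individuals")
  k    <- phi_groups(ped, list(c(a, b)), cache)
  Faa  <- 2 * phi_groups(ped, list(c(a, a)), cache) - 1
  Fbb  <- 2 * phi_groups(ped, list(c(b, b)), cache) - 1
  paab <- phi_groups(ped, list(c(a, a, b)), cache)
  pabb <- phi_groups(ped, list(c(a, b, b)), cache)
  paabb  <- phi_groups(ped, list(c(a, a, b, b)), cache)
  p_aa_bb <- phi_groups(ped, list(c(a, a), c(b, b)), cache)
  p_ab_ab <- phi_groups(ped, list(c(a, b), c(a, b)), cache)

  d1 <- 4 * paabb - 2 * paab - 2 * pabb + k
  d3 <- 2 * (2 * paab - k - d1)
  d5 <- 2 * (2 * pabb - k - d1)
  d7 <- 8 * (p_ab_ab - paabb)
  d2 <- 4 * p_aa_bb - 1 - Faa - Fbb - d1
  d4 <- Faa - d1 - d2 - d3
  d6 <- Fbb - d1 - d2 - d5
  d8 <- 4 * k - 4 * d1 - 2 * d3 - 2 * d5 - 2 * d7
  d9 <- 1 - (d1 + d2 + d3 + d4 + d5 + d6 + d7 + d8)
  delta <- c(delta1 = d1, delta2 = d2, delta3 = d3, delta4 = d4,
             delta5 = d5, delta6 = d6, delta7 = d7, delta8 = d8, delta9 = d9)
  # clip tiny negative round-off
  delta[abs(delta) < 1e-14] <- pmax(delta[abs(delta) < 1e-14], 0)
  delta
}

#' @rdname condensed_identity
#' @export
paper_identities <- function(ped, a, b, cache = ibd_cache(ped)) {
  d <- condensed_identity(ped, a, b, cache)
  c(Fab = unname(d["delta1"] + (d["delta3"] + d["delta5"] + d["delta7"]) / 2 +
        d["delta8"] / 4),
    Faa = unname(d["delta1"] + d["delta2"] + d["delta3"] + d["delta4"]),
    Fbb = unname(d["delta1"] + d["delta2"] + d["delta5"] + d["delta6"]),
    Faab = unname(d["delta1"] + d["delta3"] / 2),
    Fabb = unname(d["delta1"] + d["delta5"] / 2),
    Faabb = unname(d["delta1"]),
    Ft_abab = unname(d["delta7"]),
    Ft_aabb = unname(d["delta2"]))
}

#' Identity coefficients of an individual's parents
#'
#' Relabels [paper_identities()] of the parent pair `(i[1], i[2])` in the
#' `F11, F22, F12, F112, F122, F1122, Ft_1212, Ft_1122` notation used by the
#' within-family moment formulas, where `F12` equals the individual's own
#' inbreeding coefficient.  When the individual was produced by selfing
#' (`i[1] == i[2] = s`), the four parental gene slots collapse onto the two
#' physical genes of `s` and the set degenerates to
#' `F11 = F22 = F112 = F122 = F1122 = Fss`, `F12 = (1 + Fss)/2`,
#' `Ft_1212 = 1 - Fss`, `Ft_1122 = 0`, with `Fss` the inbreeding coefficient
#' of `s`; the returned set carries `selfed = 1`.
#'
#' @inheritParams condensed_identity
#' @param i a non-founder id.
#' @return Named numeric vector with the eight identity coefficients plus a
#'   `selfed` indicator (0/1).
#' @export
parental_identity_set <- function(ped, i, cache = ibd_cache(ped)) {
  pr <- parents(ped, i)
  if (is.null(pr)) stop("individual ", i, " is a founder")
  if (pr[1L] == pr[2L]) {
    Fss <- 2 * phi_groups(ped, list(c(pr[1L], pr[1L])), cache) - 1
    return(c(F11 = Fss, F22 = Fss, F12 = (1 + Fss) / 2,
             F112 = Fss, F122 = Fss, F1122 = Fss,
             Ft_1212 = 1 - Fss, Ft_1122 = 0, selfed = 1))
  }
  p <- paper_identities(ped, pr[1L], pr[2L], cache)
  c(F11 = unname(p["Faa"]), F22 = unname(p["Fbb"]), F12 = unname(p["Fab"]),
    F112 = unname(p["Faab"]), F122 = unname(p["Fabb"]),
    F1122 = unname(p["Faabb"]), Ft_1212 = unname(p["Ft_abab"]),
    Ft_1122 = unname(p["Ft_aabb"]), selfed = 0)
}

#' Batch identity table for pairs of individuals
#'
#' One row per pair with the nine condensed coefficients and the derived
#' identity probabilities; computations share one memoization cache.
#'
#' @param ped a [pedigree()].
#' @param pairs two-column character matrix or data frame of ids.
#' @return A data frame.
#' @export
identity_table <- function(ped, pairs) {
  pairs <- as.matrix(pairs)
  cache <- ibd_cache(ped)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    d <- condensed_identity(ped, a, b, cache)
    p <- paper_identities(ped, a, b, cache)
    data.frame(a = a, b = b, t(d), t(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
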