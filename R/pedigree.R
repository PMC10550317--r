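#' Discrete-generation diploid pedigrees
#'
#' A `pedigree` is a data frame with one row per diploid individual and
#' columns `id`, `parent1`, `parent2` and `generation`.  Founders occupy
#' generation 0 and have both parents `NA`; every non-founder has two parent
#' references (possibly equal, when selfing is allowed) pointing at
#' individuals of a strictly earlier generation.  Parent order is meaningful:
#' gene copy 1 of an individual descends from `parent1`, copy 2 from
#' `parent2`.  The population is monoecious with non-overlapping generations.
#'
#' @param id character or integer vector of unique individual labels.
#' @param parent1,parent2 parent labels (`NA` for founders).
#' @param generation non-negative integer generation indices.
#' @param selfing_allowed logical; may `parent1 == parent2`?
#'
#' @return An object of class `pedigree`: a data frame with the four columns
#'   above (ids stored as character) plus attributes `selfing_allowed` and
#'   `n_generations`, topologically ordered by generation.
#' @seealso [make_random_pedigree()], [read_pedigree()], [kinship()]
#' @export
pedigree <- function(id, parent1, parent2, generation, selfing_allowed = FALSE) {
  ped <- data.frame(
    id = as.character(id),
    parent1 = as.character(parent1),
    parent2 = as.character(parent2),
    generation = as.integer(generation),
    stringsAsFactors = FALSE
  )
  ped <- ped[order(ped$generation), , drop = FALSE]
  rownames(ped) <- NULL
  attr(ped, "selfing_allowed") <- isTRUE(selfing_allowed)
  attr(ped, "n_generations") <- max(ped$generation)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree's structural invariants
#'
#' Checks uniqueness of ids, the founder convention (both parents `NA` iff
#' generation 0 membership is consistent), existence of parents, strictly
#' increasing generations along parent-child edges, and the selfing flag.
#' Errors name the offending row.
#'
#' @param ped a [pedigree()].
#' @return `ped`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  need <- c("id", "parent1", "parent2", "generation")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns id, parent1, parent2, generation")
  if (anyDuplicated(ped$id))
    stop("duplicate individual id: ", ped$id[duplicated(ped$id)][1L])
  if (any(ped$generation < 0L))
    stop("negative generation for id ", ped$id[ped$generation < 0L][1L])
  one_na <- is.na(ped$parent1) != is.na(ped$parent2)
  if (any(one_na))
    stop("exactly one parent missing for id ", ped$id[one_na][1L],
         " (founders must have both parents NA)")
  founder <- is.na(ped$parent1)
  bad_f <- founder & ped$generation != 0L
  if (any(bad_f))
    stop("unparented individual ", ped$id[bad_f][1L],
         " in generation > 0")
  bad_g0 <- !founder & ped$generation == 0L
  if (any(bad_g0))
    stop("generation-0 individual ", ped$id[bad_g0][1L], " has parents")
  gen_of <- stats::setNames(ped$generation, ped$id)
  for (col in c("parent1", "parent2")) {
    p <- ped[[col]][!founder]
    miss <- !(p %in% ped$id)
    if (any(miss))
      stop("unknown ", col, " '", p[miss][1L], "' for id ",
           ped$id[!founder][miss][1L])
    late <- gen_of[p] >= ped$generation[!founder]
    if (any(late))
      stop("parent generation not earlier than child for id ",
           ped$id[!founder][late][1L])
  }
  if (!isTRUE(attr(ped, "selfing_allowed"))) {
    selfed <- !founder & ped$parent1 == ped$parent2
    if (any(selfed))
      stop("selfing (parent1 == parent2) for id ", ped$id[!founder][
        ped$parent1[!founder] == ped$parent2[!founder]][1L],
        " but selfing_allowed is FALSE")
  }
  invisible(ped)
}

#' Simulate a random-mating pedigree of constant size
#'
#' Generation 0 holds `n_per_generation` unrelated founders; each individual
#' of a later generation draws its two (ordered) parents uniformly at random
#' from the previous generation, independently across individuals, so a
#' parent may appear in many matings.  With `selfing_allowed = FALSE` the two
#' parents are distinct.
#'
#' @param n_per_generation population size per generation (at least 2 unless
#'   selfing is allowed).
#' @param n_generations number of generations after the founders (0 gives a
#'   founders-only pedigree).
#' @param selfing_allowed logical.
#' @param seed integer seed; the result is a deterministic function of the
#'   arguments.
#' @return A [pedigree()] of `n_per_generation * (n_generations + 1)` rows.
#' @examples
#' ped <- make_random_pedigree(30, 50, seed = 1)
#' nrow(ped)  # 1530
#' @export
make_random_pedigree <- function(n_per_generation, n_generations,
                                 selfing_allowed = FALSE, seed = 1L) {
  stopifnot(n_per_generation >= 1L, n_generations >= 0L)
  if (!selfing_allowed && n_per_generation < 2L)
    stop("n_per_generation must be >= 2 when selfing is disallowed")
  N <- as.integer(n_per_generation)
  Tg <- as.integer(n_generations)
  ids <- function(t) sprintf("g%d_%d", t, seq_len(N))
  rows <- vector("list", Tg + 1L)
  rows[[1L]] <- data.frame(id = ids(0L), parent1 = NA_character_,
                           parent2 = NA_character_, generation = 0L,
                           stringsAsFactors = FALSE)
  withr_seed <- local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  if (Tg > 0L) for (t in seq_len(Tg)) {
    prev <- ids(t - 1L)
    p1 <- sample.int(N, N, replace = TRUE)
    if (selfing_allowed) {
      p2 <- sample.int(N, N, replace = TRUE)
    } else {
      # second parent uniform on the other N-1 members
      p2 <- sample.int(N - 1L, N, replace = TRUE)
      p2 <- ifelse(p2 >= p1, p2 + 1L, p2)
    }
    rows[[t + 1L]] <- data.frame(id = ids(t), parent1 = prev[p1],
                                 parent2 = prev[p2], generation = t,
                                 stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  pedigree(all$id, all$parent1, all$parent2, all$generation,
           selfing_allowed = selfing_allowed)
}

#' Read / write pedigrees as tab-separated text
#'
#' The on-disk format is UTF-8 TSV with header
#' `id<TAB>parent1<TAB>parent2<TAB>generation`; founders carry the literal
#' `NA` in both parent columns.  `read_pedigree(write_pedigree(p))` returns a
#' pedigree identical to `p` field for field.
#'
#' @param path file path.
#' @param ped a [pedigree()].
#' @param selfing_allowed logical flag attached to the pedigree on read; if
#'   `NA` (default) it is inferred from the rows.
#' @return `read_pedigree` returns a [pedigree()]; `write_pedigree` returns
#'   `path` invisibly.
#' @export
read_pedigree <- function(path, selfing_allowed = NA) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "NA")
  if (!all(c("id", "parent1", "parent2", "generation") %in% names(tab)))
    stop("pedigree file must have header id, parent1, parent2, generation")
  if (is.na(selfing_allowed)) {
    nf <- !is.na(tab$parent1) & !is.na(tab$parent2)
    selfing_allowed <- any(tab$parent1[nf] == tab$parent2[nf])
  }
  pedigree(tab$id, tab$parent1, tab$parent2, as.integer(tab$generation),
           selfing_allowed = selfing_allowed)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  validate_pedigree(ped)
  utils::write.table(as.data.frame(ped)[c("id", "parent1", "parent2",
                                          "generation")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Pedigree accessors
#'
#' `founders()` returns the generation-0 ids, `parents()` the ordered pair
#' `(parent1, parent2)` of an individual (`NULL` for a founder), and
#' `generation_members()` the ids of one generation.
#'
#' @param ped a [pedigree()].
#' @param id an individual id.
#' @param t a generation index.
#' @export
founders <- function(ped) ped$id[ped$generation == 0L]

#' @rdname founders
#' @export
parents <- function(ped, id) {
  i <- match(as.character(id), ped$id)
  if (is.na(i)) stop("unknown id: ", id)
  if (is.na(ped$parent1[i])) return(NULL)
  c(ped$parent1[i], ped$parent2[i])
}

#' @rdname founders
#' @export
generation_members <- function(ped, t) ped$id[ped$generation == as.integer(t)]

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals, generations 0..%d, selfing %s\n",
              nrow(x), attr(x, "n_generations"),
              if (isTRUE(attr(x, "selfing_allowed"))) "allowed" else "disallowed"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# integer row indices of the two parents for each row (NA for founders)
parent_index <- function(ped) {
  cbind(p1 = match(ped$parent1, ped$id), p2 = match(ped$parent2, ped$id))
}
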