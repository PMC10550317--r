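# Fixture pedigrees and tiny locus models, built in code.

# bi-allelic locus with allele-2 ("A") frequency p2 and heterozygote value
# `het` (+1: A dominant, -1: a dominant); values scaled to order one
test_locus <- function(p2, het = 1) {
  nu <- c(1 - p2, p2)
  raw <- matrix(c(-1, het, het, 1), 2, 2)
  nm <- normalize_effects(raw, nu)
  list(alleles = c("a", "A"), nu = nu, eta = nm$eta, phi = nm$phi, mu = nm$mu)
}

# small model with dominance, sigma_ADI != 0 and iota^2 != iota*
test_model <- function(p2 = c(0.3, 0.6), het = c(1, -1), z_bar_0 = 0,
                       sigma_E2 = 0) {
  loci <- Map(test_locus, p2, het)
  ancestral_model(loci, z_bar_0 = z_bar_0, sigma_E2 = sigma_E2)
}

# purely additive model (phi == 0)
test_additive_model <- function(u = c(0.8, -0.4), p2 = c(0.3, 0.6)) {
  loci <- Map(function(ui, pi) {
    raw <- outer(c(-ui, ui), c(-ui, ui), `+`)
    nm <- normalize_effects(raw, c(1 - pi, pi))
    list(alleles = c("a", "A"), nu = c(1 - pi, pi), eta = nm$eta,
         phi = nm$phi, mu = nm$mu)
  }, u, p2)
  ancestral_model(loci)
}

ped_full_sibs <- function() {
  pedigree(c("f1", "f2", "s1", "s2"), c(NA, NA, "f1", "f1"),
           c(NA, NA, "f2", "f2"), c(0, 0, 1, 1))
}

ped_half_sibs <- function() {
  pedigree(c("f1", "f2", "f3", "h1", "h2"), c(NA, NA, NA, "f1", "f3"),
           c(NA, NA, NA, "f2", "f2"), c(0, 0, 0, 1, 1))
}

ped_parent_offspring <- function() {
  pedigree(c("f1", "f2", "c"), c(NA, NA, "f1"), c(NA, NA, "f2"), c(0, 0, 1))
}

ped_first_cousins <- function() {
  pedigree(c("g1", "g2", "m1", "m2", "u1", "u2", "c1", "c2"),
           c(NA, NA, NA, NA, "g1", "g1", "u1", "u2"),
           c(NA, NA, NA, NA, "g2", "g2", "m1", "m2"),
           c(0, 0, 0, 0, 1, 1, 2, 2))
}

# t successive selfings of one founder line
ped_selfing_chain <- function(t = 3L) {
  ids <- paste0("x", 0:t)
  pedigree(ids, c(NA, ids[-(t + 1L)]), c(NA, ids[-(t + 1L)]), 0:t,
           selfing_allowed = TRUE)
}

# f1,f2 -> full sibs s1,s2 -> their children i,j (sib mating)
ped_sib_parents <- function() {
  pedigree(c("f1", "f2", "s1", "s2", "i", "j"),
           c(NA, NA, "f1", "f1", "s1", "s1"),
           c(NA, NA, "f2", "f2", "s2", "s2"),
           c(0, 0, 1, 1, 2, 2))
}

# founder f -> s = self(f) -> i = self(s): selfed family with Fss = 1/2
ped_selfed_family <- function() {
  pedigree(c("f", "s", "i", "j"), c(NA, "f", "s", "s"), c(NA, "f", "s", "s"),
           c(0, 1, 2, 2), selfing_allowed = TRUE)
}

# random identity sets harvested from small random pedigrees
random_parental_sets <- function(n = 100L, seed = 42L) {
  out <- list()
  s <- seed
  while (length(out) < n) {
    s <- s + 1L
    ped <- make_random_pedigree(4, 3, selfing_allowed = TRUE, seed = s)
    cache <- ibd_cache(ped)
    nf <- ped$id[!is.na(ped$parent1)]
    for (i in sample(nf, min(3L, length(nf)))) {
      out[[length(out) + 1L]] <- parental_identity_set(ped, i, cache)
      if (length(out) >= n) break
    }
  }
  out
}
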