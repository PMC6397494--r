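# Three-generation fixture pedigree:
#   gp1 x gp2 -> fa, uncle      gp3 x gp4 -> mo
#   fa x mo -> c1, c2, c3
#   uncle x aunt(married in) -> cousin
#   fa x step (second partner) -> halfsib
# plus "lone", an unconnected founder.
fixture_pedigree <- function() {
  tibble::tibble(
    person_id = c("gp1", "gp2", "gp3", "gp4", "fa", "uncle", "aunt", "mo",
                  "step", "c1", "c2", "c3", "cousin", "halfsib", "lone"),
    father_id = c(NA, NA, NA, NA, "gp1", "gp1", NA, "gp3",
                  NA, "fa", "fa", "fa", "uncle", "fa", NA),
    mother_id = c(NA, NA, NA, NA, "gp2", "gp2", NA, "gp4",
                  NA, "mo", "mo", "mo", "aunt", "step", NA),
    sex = c("M", "F", "M", "F", "M", "M", "F", "F",
            "F", "M", "F", "F", "M", "M", "M"),
    birth_year = c(1900L, 1901L, 1902L, 1899L, 1927L, 1929L, 1930L, 1928L,
                   1932L, 1955L, 1957L, 1959L, 1956L, 1961L, 1940L),
    born_in_state = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                      TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    death_year = c(1980L, 1985L, 1978L, 1990L, 2001L, 2005L, 2010L, 2003L,
                   2008L, NA, NA, NA, NA, NA, 2015L)
  )
}

# Independent relationship-degree oracle via kinship coefficients.
# Processes individuals parents-first and fills the kinship matrix by the
# standard recursion phi(i,j) = (phi(i, father(j)) + phi(i, mother(j))) / 2,
# phi(j,j) = 1/2 + phi(father(j), mother(j)) / 2 (missing parents contribute
# 0). In an outbred pedigree phi = 1/4 exactly for first-degree pairs and
# 1/8 for second-degree pairs, which is a numeric route to degree entirely
# separate from the package's set-based traversal.
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$person_id)
  mo <- match(ped$mother_id, ped$person_id)
  depth <- rep(NA_integer_, n)
  dep <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    d <- 1L + max(0L, if (!is.na(fa[i])) dep(fa[i]) else 0L,
                  if (!is.na(mo[i])) dep(mo[i]) else 0L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) dep(i)
  ord <- order(depth)
  phi <- matrix(0, n, n)
  col_of <- function(j, i) if (is.na(j)) 0 else phi[i, j]
  for (j in ord) {
    if (is.na(fa[j]) && is.na(mo[j])) {
      phi[j, j] <- 0.5
    } else {
      prev <- ord[seq_len(which(ord == j) - 1)]
      for (i in prev) {
        v <- (col_of(fa[j], i) + col_of(mo[j], i)) / 2
        phi[i, j] <- v
        phi[j, i] <- v
      }
      fm <- if (is.na(fa[j]) || is.na(mo[j])) 0 else phi[fa[j], mo[j]]
      phi[j, j] <- 0.5 + fm / 2
    }
  }
  dimnames(phi) <- list(ped$person_id, ped$person_id)
  phi
}

oracle_degree_sets <- function(ped, id, phi = kinship_matrix(ped)) {
  v <- phi[id, ]
  list(
    fdr = names(v)[names(v) != id & abs(v - 1 / 4) < 1e-12],
    sdr = names(v)[names(v) != id & abs(v - 1 / 8) < 1e-12]
  )
}

# Direct-summation Poisson upper tail, independent of ppois: sums
# exp(-lambda) * lambda^k / k! from k = obs upward in log space, so deep
# tails keep full relative precision.
poisson_upper_tail_direct <- function(obs, lambda, terms = 800) {
  k <- obs:(obs + terms)
  sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
}

# Binomial tail probabilities by direct summation (for Clopper-Pearson
# root checks), independent of pbinom/qbeta.
binom_ge_direct <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}
binom_le_direct <- function(k, n, p) {
  sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - (0:k)))
}

# Small random pedigree for property tests; shape varies with the seed.
random_pedigree <- function(seed) {
  simulate_pedigree(sim_config(
    seed = seed,
    n_founder_couples = 2L + seed %% 3L,
    n_generations = 3L + seed %% 2L,
    mean_offspring = 2.2,
    marriage_prob = 0.8
  ), seed = seed)
}
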