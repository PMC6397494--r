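#' Simulation configuration
#'
#' Bundles every parameter of the synthetic genealogy/registry/assay
#' generator. Defaults describe the study-scale scenario: a multi-generation
#' genealogy in the style of a state population database, a biallelic risk
#' SNP whose carrier (heterozygote or homozygote) fraction in the general
#' population is 8% under Hardy-Weinberg (allele frequency
#' `1 - sqrt(0.92)` = 0.0408), 102 genotyped probands of whom roughly 40%
#' link to three or more generations of genealogy and roughly 44% carry the
#' risk allele (disease-based ascertainment enriches carriers far above the
#' population frequency), a 43/21/38 somatic-only/germline-only/both DNA
#' source mix, and somatic assay error rates matching 85.7% sensitivity and
#' 95.8% specificity.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_founder_couples Founder couples in generation 1.
#' @param n_generations Number of discrete, non-overlapping generations.
#' @param mean_offspring Mean children per couple (Poisson).
#' @param marriage_prob Probability that a child of a non-terminal
#'   generation marries (an unrelated, newly created spouse) and reproduces.
#' @param base_birth_year Mean founder birth year.
#' @param generation_gap Years between generations.
#' @param birth_jitter_sd SD of birth-year jitter within a generation.
#' @param p_born_in_state Probability an individual carries the in-state
#'   birth flag (length 2: founders/immigrant spouses, in-pedigree births).
#' @param mean_lifespan,lifespan_sd Lifespan distribution (years).
#' @param g_allele_frequency Risk-allele frequency in founders.
#' @param baseline_rates Baseline lifetime per-person incidence proportions,
#'   a tibble `site, sex, rate` (`sex = NA` means both sexes); see
#'   [default_baseline_rates()].
#' @param planted_rr Named list of planted relative-risk multipliers by
#'   group: elements of `carrier_fdr`, `carrier_sdr`, `proband`, each a
#'   named numeric vector by site (`ANY` applies to every site). Multipliers
#'   compose multiplicatively for persons in several groups; products are
#'   clipped so no probability exceeds 1 (with a warning).
#' @param n_probands Number of genotyped probands.
#' @param linked_fraction Fraction of probands drawn from individuals with
#'   at least 3 generations of genealogy (the rest emulate probands whose
#'   records fail to link deeply).
#' @param proband_carrier_fraction Target carrier fraction among probands.
#' @param source_mix Integer weights for DNA source assignment, named
#'   `somatic`, `germline`, `both`.
#' @param n_replicates_germline Germline replicates plated per person.
#' @param assay_error List with `somatic_false_negative`,
#'   `somatic_false_positive` (person-level somatic call error rates) and
#'   `germline_run_discordance` (per-replicate probability that the two
#'   germline runs disagree).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founder_couples = 40,
                       n_generations = 4,
                       mean_offspring = 2.8,
                       marriage_prob = 0.85,
                       base_birth_year = 1900,
                       generation_gap = 27,
                       birth_jitter_sd = 3,
                       p_born_in_state = c(founder = 0.6, child = 0.9),
                       mean_lifespan = 78,
                       lifespan_sd = 12,
                       g_allele_frequency = 1 - sqrt(0.92),
                       baseline_rates = default_baseline_rates(),
                       planted_rr = list(),
                       n_probands = 102,
                       linked_fraction = 41 / 102,
                       proband_carrier_fraction = 18 / 41,
                       source_mix = c(somatic = 43, germline = 21, both = 38),
                       n_replicates_germline = 2,
                       assay_error = list(somatic_false_negative = 1 - 0.857,
                                          somatic_false_positive = 1 - 0.958,
                                          germline_run_discordance = 0.05)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_generations >= 1, cfg$n_founder_couples >= 1,
            cfg$g_allele_frequency >= 0, cfg$g_allele_frequency <= 1,
            all(unlist(cfg$assay_error) >= 0),
            all(unlist(cfg$assay_error) <= 1))
  bad_groups <- setdiff(names(cfg$planted_rr),
                        c("carrier_fdr", "carrier_sdr", "proband"))
  if (length(bad_groups) > 0) {
    stop("unknown planted_rr group(s): ", paste(bad_groups, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(cfg$planted_rr) < 0)) {
    stop("planted_rr multipliers must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default baseline incidence proportions
#'
#' Lifetime cumulative per-person proportions by site, loosely calibrated to
#' a mid-20th-century US registry population: a catch-all `OTHER` site
#' carries most of the any-cancer burden, prostate applies to males only,
#' and oligodendroglioma is rare (order 1e-4). Together they give an
#' any-site cumulative incidence of roughly 7% per person, comparable to
#' the implied expected counts of a registry window that misses cancers
#' diagnosed early or out of state.
#'
#' @return A tibble `site, sex, rate`; `sex = NA` applies to both sexes.
#' @export
default_baseline_rates <- function() {
  tibble::tibble(
    site = c("BRAIN", "OLIGODENDROGLIOMA", "COLORECTAL", "THYROID",
             "PROSTATE", "OTHER"),
    sex = c(NA, NA, NA, NA, "M", NA),
    rate = c(0.0035, 0.0004, 0.012, 0.004, 0.03, 0.05)
  )
}

new_id <- function(prefix, n, offset = 0) {
  sprintf("%s%05d", prefix, offset + seq_len(n))
}

#' Simulate a multi-generation pedigree
#'
#' Forward-time generator of a discrete, non-overlapping-generation
#' genealogy. Founders (and the unrelated spouses who marry into each later
#' generation) have no recorded parents; every in-pedigree birth has two
#' recorded parents, so degree classification is unambiguous and there is
#' no inbreeding. Birth years increase by a fixed generation gap with
#' Gaussian jitter; lifespans are Gaussian. Fully deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override; `NULL` uses the current RNG state
#'   (so [simulate_study()] can drive everything from one stream).
#' @return A genealogy tibble (columns of [read_genealogy()]).
#' @export
simulate_pedigree <- function(config, seed = config$seed) {
  run <- function() {
    rows <- list()
    counter <- 0
    add <- function(n, father, mother, sex, birth, in_state_p) {
      ids <- new_id("I", n, counter)
      counter <<- counter + n
      birth <- as.integer(round(birth))
      life <- pmax(1, round(stats::rnorm(n, config$mean_lifespan,
                                         config$lifespan_sd)))
      rows[[length(rows) + 1]] <<- tibble::tibble(
        person_id = ids, father_id = father, mother_id = mother, sex = sex,
        birth_year = birth,
        born_in_state = stats::runif(n) < in_state_p,
        death_year = as.integer(birth + life)
      )
      ids
    }
    n0 <- config$n_founder_couples
    founder_birth <- function(n) {
      stats::rnorm(n, config$base_birth_year, config$birth_jitter_sd)
    }
    fathers <- add(n0, NA_character_, NA_character_, "M", founder_birth(n0),
                   config$p_born_in_state[["founder"]])
    mothers <- add(n0, NA_character_, NA_character_, "F", founder_birth(n0),
                   config$p_born_in_state[["founder"]])
    couples <- tibble::tibble(father = fathers, mother = mothers)

    for (g in seq_len(config$n_generations - 1)) {
      if (nrow(couples) == 0) {
        warning("generation ", g, " produced no couples; pedigree truncated")
        break
      }
      n_kids <- stats::rpois(nrow(couples), config$mean_offspring)
      kid_father <- rep(couples$father, n_kids)
      kid_mother <- rep(couples$mother, n_kids)
      n <- length(kid_father)
      if (n == 0) {
        warning("generation ", g + 1, " is empty (zero fertility draw)")
        couples <- couples[0, ]
        next
      }
      birth <- config$base_birth_year + g * config$generation_gap +
        stats::rnorm(n, 0, config$birth_jitter_sd)
      sex <- sample(c("M", "F"), n, replace = TRUE)
      kids <- add(n, kid_father, kid_mother, sex, birth,
                  config$p_born_in_state[["child"]])
      if (g + 1 < config$n_generations) {
        marries <- stats::runif(n) < config$marriage_prob
        idx <- which(marries)
        m <- length(idx)
        if (m > 0) {
          sp_sex <- ifelse(sex[idx] == "M", "F", "M")
          spouses <- add(m, NA_character_, NA_character_, sp_sex,
                         birth[idx] + stats::rnorm(m, 0, config$birth_jitter_sd),
                         config$p_born_in_state[["founder"]])
          couples <- tibble::tibble(
            father = ifelse(sex[idx] == "M", kids[idx], spouses),
            mother = ifelse(sex[idx] == "M", spouses, kids[idx])
          )
        } else {
          couples <- couples[0, ]
        }
      }
    }
    validate_genealogy(dplyr::bind_rows(rows))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Mendelian transmission of a biallelic SNP
#'
#' Assigns genotypes at a biallelic locus: founders (individuals without
#' recorded parents) are drawn under Hardy-Weinberg equilibrium at the
#' configured allele frequency; every individual with recorded parents
#' receives one allele from each parent, chosen uniformly. Works on any
#' valid genealogy, processing individuals in ancestor-depth order.
#'
#' @param ped A genealogy tibble.
#' @param g_allele_frequency Risk-allele frequency `f`; founder genotype
#'   probabilities are `((1-f)^2, 2f(1-f), f^2)`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A tibble `person_id, genotype` with genotype in `AA, AG, GG`.
#' @export
transmit_genotypes <- function(ped, g_allele_frequency, seed = NULL) {
  run <- function() {
    f <- g_allele_frequency
    depth <- ancestor_depths(ped)
    idx <- parent_index(ped)
    n <- nrow(ped)
    # count of G alleles per person
    g_count <- integer(n)
    # allele passed to a child: G with prob g_count/2; a missing parent
    # contributes a population allele at frequency f
    pass_allele <- function(parent_rows) {
      m <- length(parent_rows)
      out <- logical(m)
      known <- parent_rows > 0L
      out[known] <- stats::runif(sum(known)) <
        g_count[parent_rows[known]] / 2
      out[!known] <- stats::runif(sum(!known)) < f
      out
    }
    for (d in sort(unique(depth))) {
      at <- which(depth == d)
      founder <- idx$father[at] == 0L & idx$mother[at] == 0L
      fo <- at[founder]
      if (length(fo) > 0) {
        g_count[fo] <- sample(0:2, length(fo), replace = TRUE,
                              prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
      }
      ch <- at[!founder]
      if (length(ch) > 0) {
        g_count[ch] <- pass_allele(idx$father[ch]) + pass_allele(idx$mother[ch])
      }
    }
    tibble::tibble(person_id = ped$person_id,
                   genotype = c("AA", "AG", "GG")[g_count + 1L])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# group membership used for planting risk: probands, and FDR/SDR of
# carrier probands (excluding all probands)
risk_groups <- function(ped, probands_id, carrier_id) {
  list(
    proband = probands_id,
    carrier_fdr = relative_set(ped, carrier_id, 1, exclude = probands_id),
    carrier_sdr = relative_set(ped, carrier_id, 2, exclude = probands_id)
  )
}

# per-person per-site incidence probability with planted multipliers
incidence_probs <- function(ped, config, groups) {
  base <- config$baseline_rates
  grid <- tidyr::crossing(
    tibble::tibble(person_id = ped$person_id, sex = ped$sex),
    site = base$site
  )
  grid <- dplyr::left_join(grid, base, by = "site", suffix = c("", ".req"))
  grid <- grid[is.na(grid$sex.req) | grid$sex.req == grid$sex, , drop = FALSE]
  for (g in names(config$planted_rr)) {
    mult <- config$planted_rr[[g]]
    member <- grid$person_id %in% groups[[g]]
    for (s in names(mult)) {
      hit <- member & (s == "ANY" | grid$site == s)
      grid$rate[hit] <- grid$rate[hit] * mult[[s]]
    }
  }
  if (any(grid$rate > 1)) {
    warning(sum(grid$rate > 1),
            " incidence probabilities clipped to 1 after planting")
    grid$rate <- pmin(grid$rate, 1)
  }
  grid[, c("person_id", "site", "rate")]
}

#' Simulate a cancer registry
#'
#' Gives each person, independently per site, a registry record with
#' probability `baseline rate x planted multiplier` for every risk group
#' the person belongs to (multipliers compose multiplicatively; clipped at
#' probability 1 with a warning). Diagnosis years are drawn uniformly over
#' adult life. Sex-restricted sites only occur in the matching sex.
#'
#' @param ped A genealogy tibble.
#' @param genotypes Output of [transmit_genotypes()].
#' @param probands Tibble `person_id, g_allele_carrier` designating the
#'   genotyped probands (carrier status defines whose relatives carry
#'   planted risk).
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A registry tibble `person_id, site_code, diagnosis_year`.
#' @export
simulate_registry <- function(ped, genotypes, probands, config, seed = NULL) {
  run <- function() {
    groups <- risk_groups(ped, probands$person_id,
                          probands$person_id[probands$g_allele_carrier])
    probs <- incidence_probs(ped, config, groups)
    hit <- stats::runif(nrow(probs)) < probs$rate
    rec <- probs[hit, , drop = FALSE]
    rows <- match(rec$person_id, ped$person_id)
    birth <- ped$birth_year[rows]
    death <- ped$death_year[rows]
    onset_lo <- birth + 20
    onset_hi <- pmax(onset_lo + 1, ifelse(is.na(death), birth + 85, death))
    tibble::tibble(
      person_id = rec$person_id,
      site_code = rec$site,
      diagnosis_year = as.integer(round(onset_lo +
        stats::runif(nrow(rec)) * (onset_hi - onset_lo)))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a replicate genotype assay
#'
#' Emits germline and/or somatic assay records for each proband according
#' to the configured DNA source mix. Germline replicates report the true
#' genotype in both runs, except that with probability
#' `germline_run_discordance` a replicate's second run is corrupted (a
#' failed or wrong-zygosity read), making that replicate uninformative
#' under the two-run agreement rule. Somatic calls err at the person level:
#' a true carrier's tumour reads all-`AA` with probability
#' `somatic_false_negative`, and a true noncarrier's tumour shows the G
#' allele in one run with probability `somatic_false_positive` — matching
#' the published sensitivity and specificity at the default rates.
#'
#' @param genotypes Output of [transmit_genotypes()].
#' @param probands Tibble with `person_id`; a `source` column
#'   (`somatic`/`germline`/`both`) is honoured if present, otherwise
#'   sources are assigned from `config$source_mix`.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return An assay tibble (columns of [read_assay()]).
#' @export
simulate_assay <- function(genotypes, probands, config, seed = NULL) {
  run <- function() {
    ids <- probands$person_id
    stopifnot(all(ids %in% genotypes$person_id))
    geno <- genotypes$genotype[match(ids, genotypes$person_id)]
    if ("source" %in% names(probands)) {
      source <- probands$source
    } else {
      mix <- config$source_mix / sum(config$source_mix)
      source <- sample(names(mix), length(ids), replace = TRUE, prob = mix)
    }
    err <- config$assay_error
    recs <- list()
    sample_counter <- 0
    emit <- function(person, src, replicate, r1, r2) {
      n <- length(person)
      sample_counter <<- sample_counter + n
      recs[[length(recs) + 1]] <<- tibble::tibble(
        sample_id = new_id("S", n, sample_counter - n),
        person_id = person, source = src,
        replicate = as.integer(replicate), run1_call = r1, run2_call = r2
      )
    }
    # germline replicates
    has_germ <- source %in% c("germline", "both")
    for (r in seq_len(config$n_replicates_germline)) {
      p <- ids[has_germ]
      g <- geno[has_germ]
      run2 <- g
      discord <- stats::runif(length(p)) < err$germline_run_discordance
      corrupt <- ifelse(stats::runif(length(p)) < 0.5, "fail",
                        ifelse(g == "AG", "GG", "AG"))
      run2[discord] <- corrupt[discord]
      emit(p, "germline", r, g, run2)
    }
    # somatic: person-level detection error
    has_soma <- source %in% c("somatic", "both")
    p <- ids[has_soma]
    g <- geno[has_soma]
    is_carrier <- g %in% G_CALLS
    u <- stats::runif(length(p))
    false_neg <- is_carrier & u < err$somatic_false_negative
    false_pos <- !is_carrier & u < err$somatic_false_positive
    r1 <- ifelse(is_carrier & !false_neg, g, "AA")
    r2 <- r1
    r1[false_neg] <- "AA"
    r2[false_neg] <- "AA"
    r2[false_pos] <- "AG"
    emit(p, "somatic", 1L, r1, r2)
    out <- dplyr::bind_rows(recs)
    dplyr::arrange(out, .data$person_id, .data$source, .data$replicate)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# sample probands: stratified by (>=3 generations linked) x carrier truth
sample_probands <- function(ped, genotypes, config) {
  depth <- generations_linked(ped)$generations
  carrier <- genotypes$genotype[match(ped$person_id,
                                      genotypes$person_id)] %in% G_CALLS
  n_linked <- round(config$n_probands * config$linked_fraction)
  n_unlinked <- config$n_probands - n_linked
  pick <- function(pool, n) {
    if (length(pool) < n) {
      warning("proband pool smaller than requested; taking ", length(pool))
      n <- length(pool)
    }
    sample(pool, n)
  }
  take_split <- function(deep, n_total) {
    n_car <- round(n_total * config$proband_carrier_fraction)
    c(pick(ped$person_id[deep & carrier], n_car),
      pick(ped$person_id[deep & !carrier], n_total - n_car))
  }
  ids <- c(take_split(depth >= 3, n_linked),
           take_split(depth < 3, n_unlinked))
  tibble::tibble(
    person_id = ids,
    g_allele_carrier = carrier[match(ids, ped$person_id)]
  )
}

#' Simulate a complete familial-risk study
#'
#' One call generating every input the pipeline needs: pedigree, genotypes,
#' proband sample (stratified so the configured fractions are linked to
#' three or more generations and carry the risk allele), cancer registry
#' with any planted familial risks, and the replicate genotype assay. All
#' randomness flows from `config$seed`; a fixed seed reproduces every
#' output byte-for-byte.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements `genealogy`,
#'   `genotypes`, `probands` (true carrier status and assigned DNA source),
#'   `registry`, `assay`, `groups` (the planted risk-group id sets) and
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    ped <- simulate_pedigree(config, seed = NULL)
    genotypes <- transmit_genotypes(ped, config$g_allele_frequency,
                                    seed = NULL)
    probands <- sample_probands(ped, genotypes, config)
    mix <- config$source_mix / sum(config$source_mix)
    probands$source <- sample(names(mix), nrow(probands),
                              replace = TRUE, prob = mix)
    registry <- simulate_registry(ped, genotypes, probands, config,
                                  seed = NULL)
    assay <- simulate_assay(genotypes, probands, config, seed = NULL)
    groups <- risk_groups(ped, probands$person_id,
                          probands$person_id[probands$g_allele_carrier])
    structure(
      list(genealogy = ped, genotypes = genotypes, probands = probands,
           registry = registry, assay = assay, groups = groups,
           config = config),
      class = "sim_study"
    )
  })
}

#' Write the simulated study to CSV files
#'
#' Writes `genealogy.csv`, `probands.csv`, `registry.csv` and `assay.csv`
#' in the formats read by [read_genealogy()], [read_probands()],
#' [read_registry()] and [read_assay()]; unknown fields are written as
#' empty strings. Deterministic for a fixed config seed.
#'
#' @param sim A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genealogy = file.path(dir, "genealogy.csv"),
    probands = file.path(dir, "probands.csv"),
    registry = file.path(dir, "registry.csv"),
    assay = file.path(dir, "assay.csv")
  )
  readr::write_csv(sim$genealogy, paths[["genealogy"]], na = "")
  readr::write_csv(sim$probands[, c("person_id", "g_allele_carrier")],
                   paths[["probands"]], na = "")
  readr::write_csv(sim$registry, paths[["registry"]], na = "")
  readr::write_csv(sim$assay, paths[["assay"]], na = "")
  invisible(paths)
}
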