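#' Read a cancer-registry file
#'
#' Registry CSV with header `person_id,site_code,diagnosis_year`; one row
#' per recorded primary. A person may have records at several sites;
#' repeated records of the same site for one person count once everywhere
#' downstream.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `person_id`, `site_code`, `diagnosis_year`.
#' @export
read_registry <- function(path) {
  as_plain_tibble(readr::read_csv(
    path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      site_code = readr::col_character(),
      diagnosis_year = readr::col_integer()
    ),
    na = ""
  ))
}

#' Assign birth-cohort strata
#'
#' Maps each individual to the stratum used for indirect standardization:
#' sex, born-in-state flag, and the 5-year birth block containing the birth
#' year (block start = `birth_year - birth_year %% block_width`, so blocks
#' are anchored at multiples of the width). Individuals with unknown birth
#' year get `NA` blocks — they are "uncohortable" and are excluded, with a
#' logged count, from both rate denominators and expected counts.
#'
#' @param ped A genealogy tibble.
#' @param block_width Width of the birth-year block in years, default 5.
#' @return A tibble `person_id, sex, born_in_state, birth_block`.
#' @export
assign_cohort <- function(ped, block_width = 5) {
  stopifnot(block_width >= 1)
  tibble::tibble(
    person_id = ped$person_id,
    sex = ped$sex,
    born_in_state = ped$born_in_state,
    birth_block = ped$birth_year - ped$birth_year %% as.integer(block_width)
  )
}

#' Cohort-specific cumulative incidence rates
#'
#' Builds the reference rate table for indirect standardization: for every
#' (sex, born-in-state, birth-block) stratum and every configured site, the
#' proportion of persons in the stratum with at least one registry record of
#' that site. Rates are lifetime cumulative proportions per person
#' (cases/persons), not person-year rates, because expected counts are
#' formed by multiplying relative *counts* by rates. The pseudo-site `ANY`
#' counts persons with a record of any configured site.
#'
#' @param ped The genealogy defining the reference population.
#' @param registry A registry tibble (see [read_registry()]).
#' @param sites Character vector of site codes to tabulate; `"ANY"` is added
#'   automatically.
#' @param block_width Birth-block width in years, default 5.
#' @param exclude Person ids excluded from the denominators (typically the
#'   genotyped probands themselves).
#' @return A tibble of class `rate_table` with columns `sex`,
#'   `born_in_state`, `birth_block`, `site`, `cases`, `n`, `rate`, carrying
#'   the number of uncohortable individuals in attribute `n_uncohortable`.
#' @export
compute_rate_table <- function(ped, registry, sites, block_width = 5,
                               exclude = NULL) {
  if (length(sites) == 0) stop("sites must be nonempty", call. = FALSE)
  sites <- union("ANY", sites)
  cohorts <- assign_cohort(ped, block_width)
  cohorts <- cohorts[!cohorts$person_id %in% exclude, , drop = FALSE]
  n_uncohortable <- sum(is.na(cohorts$birth_block))
  if (n_uncohortable > 0) {
    message(n_uncohortable,
            " individual(s) without birth year excluded from rate table")
  }
  cohorts <- cohorts[!is.na(cohorts$birth_block), , drop = FALSE]

  denom <- dplyr::count(cohorts, .data$sex, .data$born_in_state,
                        .data$birth_block, name = "n")

  reg <- registry[registry$site_code %in% setdiff(sites, "ANY"), , drop = FALSE]
  reg <- dplyr::distinct(reg, .data$person_id, .data$site_code)
  any_reg <- dplyr::distinct(reg, .data$person_id)
  any_reg$site_code <- "ANY"
  reg <- dplyr::bind_rows(reg, any_reg)
  reg <- dplyr::inner_join(reg, cohorts, by = "person_id")
  cases <- dplyr::count(reg, .data$sex, .data$born_in_state,
                        .data$birth_block, .data$site_code, name = "cases")

  grid <- tidyr::crossing(denom, site = sites)
  tab <- dplyr::left_join(
    grid, cases,
    by = c("sex", "born_in_state", "birth_block", site = "site_code")
  )
  tab$cases <- ifelse(is.na(tab$cases), 0L, tab$cases)
  tab$rate <- ifelse(tab$n > 0, tab$cases / tab$n, 0)
  tab <- tab[, c("sex", "born_in_state", "birth_block", "site",
                 "cases", "n", "rate")]
  if (any(tab$n == 0)) warning("empty cohort cell: rate stored as 0")
  structure(tab, class = c("rate_table", class(tab)),
            sites = sites, block_width = block_width,
            n_uncohortable = n_uncohortable)
}

#' Expected cancer count for a relative set
#'
#' Indirectly standardized expected count: the relatives are partitioned by
#' cohort and each cohort's size is multiplied by its reference rate for the
#' site, then summed over cohorts. Expected counts are additive over any
#' partition of the relative set and scale linearly in the rates.
#'
#' @param relatives Character vector of person ids; every id must exist in
#'   `ped`. Relatives without a birth year are uncohortable and excluded
#'   with a message.
#' @param ped The genealogy tibble.
#' @param rates A `rate_table` from [compute_rate_table()].
#' @param site A site code present in the table.
#' @return A non-negative number.
#' @export
expected_count <- function(relatives, ped, rates, site) {
  if (length(relatives) == 0) return(0)
  if (!site %in% attr(rates, "sites")) {
    stop("site not in rate table: ", site, call. = FALSE)
  }
  rows <- match(relatives, ped$person_id)
  if (anyNA(rows)) {
    stop("relative(s) not in genealogy: ",
         paste(utils::head(relatives[is.na(rows)], 5), collapse = ", "),
         call. = FALSE)
  }
  coh <- assign_cohort(ped[rows, , drop = FALSE], attr(rates, "block_width"))
  n_unc <- sum(is.na(coh$birth_block))
  if (n_unc > 0) {
    message(n_unc, " uncohortable relative(s) excluded from expected count")
    coh <- coh[!is.na(coh$birth_block), , drop = FALSE]
  }
  counts <- dplyr::count(coh, .data$sex, .data$born_in_state,
                         .data$birth_block, name = "n_rel")
  tab <- rates[rates$site == site, , drop = FALSE]
  joined <- dplyr::left_join(counts, tab,
                             by = c("sex", "born_in_state", "birth_block"))
  if (anyNA(joined$rate)) {
    warning("relative cohort(s) absent from rate table; rate treated as 0")
    joined$rate[is.na(joined$rate)] <- 0
  }
  sum(joined$n_rel * joined$rate)
}

#' Observed cancer count for a relative set
#'
#' Number of distinct persons in the relative set with at least one registry
#' record of the site (`"ANY"` = any configured site in the registry).
#'
#' @param relatives Character vector of person ids.
#' @param registry A registry tibble.
#' @param site A site code, or `"ANY"`.
#' @param sites Site vocabulary used to interpret `"ANY"`; defaults to every
#'   site present in the registry.
#' @return A non-negative integer, at most `length(relatives)`.
#' @export
observed_count <- function(relatives, registry, site,
                           sites = unique(registry$site_code)) {
  keep <- if (identical(site, "ANY")) {
    registry$site_code %in% sites
  } else {
    registry$site_code == site
  }
  length(unique(registry$person_id[keep & registry$person_id %in% relatives]))
}
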