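#' Run the full familial cancer-risk study
#'
#' End-to-end driver tying the modules together: resolves proband carrier
#' status from the assay (with somatic-to-germline imputation for probands
#' lacking blood DNA), applies the minimum-generations eligibility filter,
#' builds the cohort rate table from the genealogy population (genotyped
#' probands excluded from the denominators), runs the observed/expected
#' relative-risk analysis for first- and second-degree relatives of the
#' carrier and noncarrier groups, and computes the somatic-vs-germline
#' concordance report. Every exclusion (unlinked probands, individuals
#' without a birth year, persons without paired calls) is surfaced via
#' messages and the returned counts.
#'
#' @param genealogy Genealogy tibble (see [read_genealogy()]).
#' @param registry Registry tibble (see [read_registry()]).
#' @param assay Assay tibble (see [read_assay()]), or `NULL` if `probands`
#'   supplies resolved calls directly; the concordance report then requires
#'   `assay`.
#' @param probands Optional tibble `person_id, g_allele_carrier` of
#'   pre-resolved calls; derived from `assay` when `NULL`.
#' @param sites Site vocabulary; defaults to the sites in the registry.
#' @param min_generations Eligibility threshold on linked generations,
#'   default 3.
#' @param block_width Birth-cohort width in years, default 5.
#' @param mask_threshold Small-count masking threshold, default 5.
#' @param alpha_low,alpha_high Exact-CI levels (see [exact_poisson_ci()]).
#' @param prevalence Prevalence for predictive values, default 0.40.
#' @param impute_germline Impute germline status from somatic calls for
#'   probands without usable germline DNA, default `TRUE`.
#' @return A list of class `familial_study`: `sir` (a `fam_sir` tibble),
#'   `concordance` (a `diag_report` or `NULL`), `rates` (the `rate_table`),
#'   `probands` (the eligible probands used), and `counts` (probands
#'   genotyped / resolved / eligible, uncohortable individuals).
#' @export
run_familial_study <- function(genealogy, registry, assay = NULL,
                               probands = NULL, sites = NULL,
                               min_generations = 3, block_width = 5,
                               mask_threshold = 5,
                               alpha_low = 0.05, alpha_high = 0.025,
                               prevalence = 0.40, impute_germline = TRUE) {
  if (is.null(sites)) sites <- sort(unique(registry$site_code))
  concordance <- NULL
  if (!is.null(assay)) {
    calls_raw <- resolve_calls(assay, impute_germline = FALSE)
    conf <- confusion_matrix(calls_raw)
    concordance <- diagnostic_report(conf, prevalence = prevalence)
  }
  if (is.null(probands)) {
    if (is.null(assay)) {
      stop("supply either resolved probands or an assay table", call. = FALSE)
    }
    calls <- resolve_calls(assay, impute_germline = impute_germline)
    probands <- tibble::tibble(
      person_id = calls$person_id,
      g_allele_carrier = calls$carrier
    )
  }
  n_genotyped <- nrow(probands)
  unresolved <- is.na(probands$g_allele_carrier)
  if (any(unresolved)) {
    message(sum(unresolved), " proband(s) with unresolved carrier status dropped")
    probands <- probands[!unresolved, , drop = FALSE]
  }
  eligible <- eligible_probands(probands, genealogy,
                                min_generations = min_generations)
  if (nrow(eligible) == 0) stop("no eligible probands", call. = FALSE)
  rates <- compute_rate_table(genealogy, registry, sites,
                              block_width = block_width,
                              exclude = probands$person_id)
  sir <- run_familial_risk(eligible, genealogy, registry, rates,
                           degree = c(1, 2), sites = attr(rates, "sites"),
                           mask_threshold = mask_threshold,
                           alpha_low = alpha_low, alpha_high = alpha_high,
                           exclude = probands$person_id)
  structure(
    list(
      sir = sir, concordance = concordance, rates = rates,
      probands = eligible,
      counts = list(
        n_genotyped = n_genotyped,
        n_resolved = n_genotyped - sum(unresolved),
        n_eligible = nrow(eligible),
        n_carrier = sum(eligible$g_allele_carrier),
        n_uncohortable = attr(rates, "n_uncohortable")
      )
    ),
    class = "familial_study"
  )
}

#' @export
print.familial_study <- function(x, ...) {
  cat("Familial cancer-risk study\n")
  cat(sprintf("  probands: %d genotyped, %d resolved, %d eligible (%d carriers)\n",
              x$counts$n_genotyped, x$counts$n_resolved,
              x$counts$n_eligible, x$counts$n_carrier))
  cat("  relative-risk table:\n")
  print(render_sir_table(x$sir), n = Inf)
  if (!is.null(x$concordance)) {
    cat("  somatic-vs-germline concordance:\n")
    print(tibble::as_tibble(unclass(x$concordance)))
  }
  invisible(x)
}

#' Write every study output to a directory
#'
#' Writes the masked relative-risk TSVs (one per group and degree, see
#' [write_sir_tables()]) and, when present, the concordance report as
#' `concordance.tsv` plus the 2x2 confusion block as `confusion.tsv`.
#'
#' @param study A `familial_study` from [run_familial_study()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_sir_tables(study$sir, dir)
  if (!is.null(study$concordance)) {
    cpath <- file.path(dir, "concordance.tsv")
    readr::write_tsv(tibble::as_tibble(unclass(study$concordance)), cpath)
    conf <- attr(study$concordance, "confusion")
    mpath <- file.path(dir, "confusion.tsv")
    readr::write_tsv(tibble::tibble(
      somatic = c("carrier", "noncarrier"),
      germline_carrier = c(conf$tp, conf$fn),
      germline_noncarrier = c(conf$fp, conf$tn)
    ), mpath)
    paths <- c(paths, cpath, mpath)
  }
  invisible(paths)
}
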