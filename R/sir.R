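#' Relative risk (standardized incidence ratio)
#'
#' Ratio of observed to expected cancer counts. Vectorized.
#'
#' @param obs Observed counts (non-negative integers).
#' @param exp Expected counts (positive numbers).
#' @return `obs / exp`.
#' @export
relative_risk <- function(obs, exp) {
  if (any(exp <= 0)) stop("expected count must be positive", call. = FALSE)
  if (any(obs < 0)) stop("observed count must be non-negative", call. = FALSE)
  obs / exp
}

#' One-sided exact Poisson p-value
#'
#' Tests the null `RR <= 1` against `RR > 1`, treating the observed count as
#' Poisson with mean equal to the expected count: for `obs >= 1` the upper
#' tail `P(X >= obs)`; for `obs = 0` the point probability
#' `P(X = 0) = exp(-exp)` is reported instead of the (trivially 1) upper
#' tail. The zero-count convention mirrors how published familial-risk
#' tables report their "one-tailed p" on zero-count rows and is flagged in
#' the column documentation of [run_familial_risk()].
#'
#' @inheritParams relative_risk
#' @return Numbers in (0, 1]. Vectorized.
#' @export
poisson_one_sided_p <- function(obs, exp) {
  if (any(obs < 0)) stop("observed count must be non-negative", call. = FALSE)
  if (any(exp <= 0)) stop("expected count must be positive", call. = FALSE)
  ifelse(obs == 0,
         exp(-exp),
         stats::ppois(obs - 1, exp, lower.tail = FALSE))
}

#' Exact Poisson confidence bounds for a relative risk
#'
#' Chi-square-quantile form of the exact Poisson limits, scaled by the
#' expected count so the bounds apply to the RR. The default mixed
#' convention — a one-sided lower bound at level `alpha_low` and an upper
#' bound at level `alpha_high` — is the one that reproduces published
#' familial standardized-incidence-ratio tables:
#' \deqn{low = \chi^2_{\alpha_L}(2\,obs) / (2\,exp), \quad
#'       high = \chi^2_{1-\alpha_H}(2(obs+1)) / (2\,exp)}
#' with `low = 0` and `high = -log(alpha_low)/exp` when `obs = 0`. The
#' bounds are the roots of the exact Poisson tail equations
#' `P(X >= obs | low*exp) = alpha_low` and
#' `P(X <= obs | high*exp) = alpha_high`.
#'
#' @inheritParams relative_risk
#' @param alpha_low Lower-tail level, default 0.05.
#' @param alpha_high Upper-tail level, default 0.025.
#' @return A tibble with columns `ci_low`, `ci_high`, one row per input.
#' @export
exact_poisson_ci <- function(obs, exp, alpha_low = 0.05, alpha_high = 0.025) {
  if (any(exp <= 0)) stop("expected count must be positive", call. = FALSE)
  if (any(obs < 0)) stop("observed count must be non-negative", call. = FALSE)
  low <- ifelse(obs == 0, 0, stats::qchisq(alpha_low, 2 * obs) / (2 * exp))
  high <- ifelse(obs == 0,
                 -log(alpha_low) / exp,
                 stats::qchisq(1 - alpha_high, 2 * (obs + 1)) / (2 * exp))
  tibble::tibble(ci_low = low, ci_high = high)
}

#' Exact Poisson inference for observed-vs-expected counts
#'
#' The vectorized workhorse behind [run_familial_risk()]: point estimate,
#' one-sided p and exact confidence bounds for each (obs, exp) pair.
#'
#' @inheritParams exact_poisson_ci
#' @return A tibble `obs, exp, rr, p_one_sided, ci_low, ci_high`.
#' @export
sir_exact <- function(obs, exp, alpha_low = 0.05, alpha_high = 0.025) {
  ci <- exact_poisson_ci(obs, exp, alpha_low, alpha_high)
  tibble::tibble(
    obs = as.integer(obs),
    exp = exp,
    rr = relative_risk(obs, exp),
    p_one_sided = poisson_one_sided_p(obs, exp),
    ci_low = ci$ci_low,
    ci_high = ci$ci_high
  )
}

#' Familial relative-risk table
#'
#' Runs the full observed/expected analysis for one relative degree: splits
#' probands by resolved carrier status, takes the deduplicated union of each
#' group's relative sets (probands themselves excluded), and computes the
#' standardized incidence ratio with exact Poisson inference for every site.
#'
#' @param probands Tibble with columns `person_id` and `g_allele_carrier`
#'   (logical); pass through [eligible_probands()] first to apply the
#'   generations filter.
#' @param ped Genealogy tibble.
#' @param registry Registry tibble.
#' @param rates A `rate_table` built from the same population (see
#'   [compute_rate_table()]).
#' @param degree 1, 2, or both (default `c(1, 2)`).
#' @param sites Site codes to report; defaults to the rate table's sites.
#' @param mask_threshold Rows with `obs <= mask_threshold` are flagged for
#'   masking in rendered output (default 5); inference columns are kept.
#' @param alpha_low,alpha_high Confidence-bound levels, see
#'   [exact_poisson_ci()].
#' @param exclude Person ids never counted as relatives; defaults to the
#'   probands passed in. Pass the full genotyped set when some probands were
#'   dropped by the eligibility filter, so no genotyped person is ever
#'   counted as a relative (they are also excluded from the rate
#'   denominators).
#' @return A tibble of class `fam_sir`: one row per (group, degree, site)
#'   with `group` (`carrier`/`noncarrier`), `degree`, `site`,
#'   `n_relatives`, `obs`, `exp`, `rr`, `p_one_sided`, `ci_low`, `ci_high`,
#'   `masked`. Zero-count rows report `p = exp(-exp)` (see
#'   [poisson_one_sided_p()]).
#' @export
run_familial_risk <- function(probands, ped, registry, rates,
                              degree = c(1, 2), sites = NULL,
                              mask_threshold = 5,
                              alpha_low = 0.05, alpha_high = 0.025,
                              exclude = probands$person_id) {
  stopifnot(all(degree %in% c(1, 2)))
  if (is.null(sites)) sites <- attr(rates, "sites")
  vocab <- setdiff(attr(rates, "sites"), "ANY")
  groups <- list(
    carrier = probands$person_id[probands$g_allele_carrier],
    noncarrier = probands$person_id[!probands$g_allele_carrier]
  )
  out <- purrr::map_dfr(c("carrier", "noncarrier"), function(g) {
    ids <- groups[[g]]
    purrr::map_dfr(degree, function(d) {
      rel <- relative_set(ped, ids, degree = d, exclude = exclude)
      purrr::map_dfr(sites, function(s) {
        o <- observed_count(rel, registry, s, sites = vocab)
        e <- expected_count(rel, ped, rates, s)
        res <- if (e > 0) {
          sir_exact(o, e, alpha_low, alpha_high)
        } else {
          tibble::tibble(obs = as.integer(o), exp = 0, rr = NA_real_,
                         p_one_sided = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_)
        }
        dplyr::bind_cols(
          tibble::tibble(group = g, degree = d, site = s,
                         n_relatives = length(rel)),
          res
        )
      })
    })
  })
  new_fam_sir(mask_small_counts(out, mask_threshold))
}

new_fam_sir <- function(x) {
  class(x) <- unique(c("fam_sir", class(x)))
  x
}

#' Flag small counts for disclosure masking
#'
#' Rows with observed counts at or below the threshold are flagged so that
#' rendered tables suppress the exact observed and expected values (the
#' "<=5*" convention of published registry tables); the RR, p-value and
#' confidence interval are retained.
#'
#' @param results A tibble with an `obs` column.
#' @param threshold Mask rows with `obs <= threshold`; default 5.
#' @return The input with a logical `masked` column.
#' @export
mask_small_counts <- function(results, threshold = 5) {
  stopifnot(threshold >= 0)
  results$masked <- results$obs <= threshold
  results
}

#' Render a familial-risk table for publication
#'
#' Formats a [run_familial_risk()] result the way registry reports print it:
#' RR and confidence bounds to 2 decimals, p to 3 decimals, expected counts
#' to 2 decimals, and masked rows showing `<=5*` in place of the observed
#' and expected counts.
#'
#' @param results A `fam_sir` tibble.
#' @param mask_label Replacement string for masked counts, default `"<=5*"`.
#' @return A tibble of character columns
#'   `group, degree, site, obs, exp, p_one_sided, rr, ci_95`.
#' @export
render_sir_table <- function(results, mask_label = "<=5*") {
  tibble::tibble(
    group = results$group,
    degree = as.character(results$degree),
    site = results$site,
    obs = ifelse(results$masked, mask_label, as.character(results$obs)),
    exp = ifelse(results$masked, mask_label, sprintf("%.2f", results$exp)),
    p_one_sided = sprintf("%.3f", results$p_one_sided),
    rr = sprintf("%.2f", results$rr),
    ci_95 = sprintf("%.2f-%.2f", results$ci_low, results$ci_high)
  )
}

#' Write masked familial-risk tables
#'
#' Writes one TSV per (group, degree) combination, rendered with
#' [render_sir_table()], into `dir` as `sir_<group>_degree<d>.tsv`.
#'
#' @param results A `fam_sir` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sir_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rendered <- render_sir_table(results)
  combos <- dplyr::distinct(rendered, .data$group, .data$degree)
  paths <- purrr::map2_chr(combos$group, combos$degree, function(g, d) {
    path <- file.path(dir, sprintf("sir_%s_degree%s.tsv", g, d))
    part <- rendered[rendered$group == g & rendered$degree == d,
                     c("site", "obs", "exp", "p_one_sided", "rr", "ci_95")]
    readr::write_tsv(part, path)
    path
  })
  invisible(paths)
}

#' @exportS3Method generics::tidy
tidy.fam_sir <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.fam_sir <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x),
    n_masked = sum(x$masked),
    min_p = min(x$p_one_sided, na.rm = TRUE),
    n_significant = sum(x$p_one_sided < 0.05, na.rm = TRUE)
  )
}

#' Forest plot of familial relative risks
#'
#' Plots the RR point estimates and exact confidence intervals per site,
#' faceted by relative degree and coloured by carrier group, with the null
#' RR = 1 marked. The RR axis is logarithmic: exact intervals on rare sites
#' are extremely wide.
#'
#' @param object A `fam_sir` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fam_sir <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df <- df[!is.na(df$rr) & df$ci_low > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr, y = .data$site,
                                   colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~degree, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "relative risk (log scale)", y = NULL,
                  colour = "proband group")
}
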