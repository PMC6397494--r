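#' Read a genotype assay file
#'
#' Assay CSV with header
#' `sample_id,person_id,source,replicate,run1_call,run2_call`; `source` is
#' `germline` (blood) or `somatic` (tumour), and each run call is one of
#' `AA`, `AG`, `GG`, `fail`. A person may have several samples and
#' replicates across both sources.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the six assay columns.
#' @export
read_assay <- function(path) {
  assay <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      person_id = readr::col_character(),
      source = readr::col_character(),
      replicate = readr::col_integer(),
      run1_call = readr::col_character(),
      run2_call = readr::col_character()
    ),
    na = ""
  )
  bad <- setdiff(unique(c(assay$run1_call, assay$run2_call)),
                 c("AA", "AG", "GG", "fail"))
  if (length(bad) > 0) {
    stop("unknown genotype call(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as_plain_tibble(assay)
}

G_CALLS <- c("AG", "GG")

#' Resolve a germline carrier call from replicate runs
#'
#' A person is a germline G-allele carrier when at least one replicate has
#' complete agreement between its two runs in detecting
#' heterozygote/homozygote status — both runs in `{AG, GG}`. With no such
#' replicate, the person is a noncarrier only if some replicate has both
#' runs `AA` (a fully concordant negative); replicates that are discordant
#' or failed are uninformative, and a person with only those is
#' `indeterminate`. The call is invariant to record order.
#'
#' @param run1,run2 Paired run calls for one person's germline replicates
#'   (`AA`, `AG`, `GG`, `fail`).
#' @return `"carrier"`, `"noncarrier"` or `"indeterminate"`.
#' @export
call_germline <- function(run1, run2) {
  if (length(run1) == 0) return("indeterminate")
  pos <- run1 %in% G_CALLS & run2 %in% G_CALLS
  if (any(pos)) return("carrier")
  neg <- run1 == "AA" & run2 == "AA"
  if (any(neg)) return("noncarrier")
  "indeterminate"
}

#' Resolve a somatic carrier call from replicate runs
#'
#' Tumour DNA is called positive for the G allele when any single run of any
#' somatic replicate detects it (call in `{AG, GG}`) — a deliberately
#' permissive rule, since tumour aneuploidy can distort one run. A
#' noncarrier call requires all non-failed runs to be `AA` with at least one
#' informative run; all-failed data is `indeterminate`.
#'
#' @inheritParams call_germline
#' @return `"carrier"`, `"noncarrier"` or `"indeterminate"`.
#' @export
call_somatic <- function(run1, run2) {
  runs <- c(run1, run2)
  runs <- runs[!is.na(runs)]
  if (any(runs %in% G_CALLS)) return("carrier")
  informative <- runs[runs != "fail"]
  if (length(informative) > 0 && all(informative == "AA")) return("noncarrier")
  "indeterminate"
}

#' Resolve per-person genotype calls from an assay table
#'
#' Applies [call_germline()] and [call_somatic()] per person over all their
#' replicates. Persons with only one source get `"none"` for the missing
#' one. With `impute_germline = TRUE`, persons with no germline call but a
#' determinate somatic call have their germline status imputed from the
#' somatic call (the downstream familial analysis then treats them like
#' directly genotyped probands); imputed rows are flagged.
#'
#' @param assay An assay tibble (see [read_assay()]).
#' @param impute_germline Impute missing germline calls from somatic calls,
#'   default `FALSE`.
#' @return A tibble `person_id, germline_call, somatic_call, carrier,
#'   imputed`: `carrier` is the resolved logical G-allele status from the
#'   germline call (or the imputed one), `NA` when indeterminate/absent.
#' @export
resolve_calls <- function(assay, impute_germline = FALSE) {
  per_person <- function(source, f) {
    sub <- assay[assay$source == source, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(person_id = character(0), call = character(0)))
    }
    sub |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(call = f(.data$run1_call, .data$run2_call),
                       .groups = "drop")
  }
  germ <- per_person("germline", call_germline)
  soma <- per_person("somatic", call_somatic)
  out <- dplyr::full_join(
    dplyr::rename(germ, germline_call = "call"),
    dplyr::rename(soma, somatic_call = "call"),
    by = "person_id"
  )
  out$germline_call[is.na(out$germline_call)] <- "none"
  out$somatic_call[is.na(out$somatic_call)] <- "none"
  out$imputed <- FALSE
  if (impute_germline) {
    idx <- out$germline_call %in% c("none", "indeterminate") &
      out$somatic_call %in% c("carrier", "noncarrier")
    out$germline_call[idx] <- out$somatic_call[idx]
    out$imputed <- idx
  }
  out$carrier <- dplyr::case_match(out$germline_call,
                                   "carrier" ~ TRUE,
                                   "noncarrier" ~ FALSE,
                                   .default = NA)
  dplyr::arrange(out[, c("person_id", "germline_call", "somatic_call",
                         "carrier", "imputed")], .data$person_id)
}

#' Somatic-vs-germline confusion matrix
#'
#' Builds the paired 2x2 table over persons with both calls resolved,
#' taking the germline call as truth (blood DNA is assumed to represent the
#' germline) and the somatic call as the test. Persons with an
#' indeterminate or missing call on either side are excluded, with a
#' message giving the count.
#'
#' @param calls A tibble from [resolve_calls()] (run without imputation).
#' @return An object of class `confusion`: list with `tp`, `fn`, `fp`, `tn`
#'   and `n_excluded`.
#' @export
confusion_matrix <- function(calls) {
  det <- c("carrier", "noncarrier")
  paired <- calls$germline_call %in% det & calls$somatic_call %in% det
  n_excluded <- sum(!paired)
  if (n_excluded > 0) {
    message(n_excluded,
            " person(s) without both calls excluded from concordance")
  }
  g <- calls$germline_call[paired] == "carrier"
  s <- calls$somatic_call[paired] == "carrier"
  structure(
    list(tp = sum(g & s), fn = sum(g & !s),
         fp = sum(!g & s), tn = sum(!g & !s),
         n_excluded = n_excluded),
    class = "confusion"
  )
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2,
              dimnames = list(somatic = c("carrier", "noncarrier"),
                              germline = c("carrier", "noncarrier")))
  cat("Somatic vs germline genotype calls (germline = truth)\n")
  print(m)
  cat("excluded (unpaired/indeterminate):", x$n_excluded, "\n")
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' The exact interval from inverted binomial tail tests, in beta-quantile
#' form: `low = qbeta(a/2, k, n-k+1)`, `high = qbeta(1-a/2, k+1, n-k)`,
#' with `low = 0` at `k = 0` and `high = 1` at `k = n`. Endpoints satisfy
#' the tail equations `P(Bin(n, low) >= k) = a/2` and
#' `P(Bin(n, high) <= k) = a/2` for interior `k`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param conf Confidence level, default 0.95.
#' @return A tibble with columns `ci_low`, `ci_high`. Vectorized over `k`
#'   and `n`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must be in [0, n]", call. = FALSE)
  a <- (1 - conf) / 2
  tibble::tibble(
    ci_low = ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1)),
    ci_high = ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
  )
}

#' Prevalence-adjusted predictive values
#'
#' Bayes-formula positive and negative predictive values at an externally
#' supplied prevalence, rather than the sample mix of the validation table:
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{(1-se)\pi + sp(1-\pi)}.}
#' With prevalence equal to the table's own positive fraction these reduce
#' to the raw `tp/(tp+fp)` and `tn/(tn+fn)`. Degenerate denominators
#' (e.g. prevalence 0 with perfect specificity) return the limit value with
#' a warning.
#'
#' @param sens,spec Sensitivity and specificity in `[0, 1]`.
#' @param prevalence Population prevalence of the condition in `[0, 1]`.
#' @return A tibble with columns `ppv`, `npv`.
#' @export
predictive_values <- function(sens, spec, prevalence) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1),
            all(prevalence >= 0 & prevalence <= 1))
  num_p <- sens * prevalence
  den_p <- num_p + (1 - spec) * (1 - prevalence)
  num_n <- spec * (1 - prevalence)
  den_n <- (1 - sens) * prevalence + num_n
  if (any(den_p == 0) || any(den_n == 0)) {
    warning("degenerate predictive-value denominator; limit value returned")
  }
  tibble::tibble(
    ppv = ifelse(den_p == 0, 1, num_p / den_p),
    npv = ifelse(den_n == 0, 1, num_n / den_n)
  )
}

#' Diagnostic accuracy report for somatic genotype calls
#'
#' Summarises a somatic-vs-germline confusion matrix as sensitivity,
#' specificity and accuracy with exact Clopper-Pearson intervals, plus
#' prevalence-adjusted predictive values. PPV/NPV confidence intervals are
#' deliberately not computed: they depend on the assumed prevalence, and no
#' standard exact method applies to the prevalence-adjusted estimates.
#'
#' @param conf A `confusion` object from [confusion_matrix()].
#' @param prevalence Prevalence used for PPV/NPV; default 0.40, the
#'   approximate germline G-allele carrier fraction among patients with
#'   IDH-mutant oligodendroglioma/astrocytoma.
#' @param conf_level Confidence level for the exact intervals, default 0.95.
#' @return A tibble of class `diag_report`: columns `metric`, `estimate`,
#'   `ci_low`, `ci_high`, `k`, `n`, with attribute `prevalence_used`.
#' @export
diagnostic_report <- function(conf, prevalence = 0.40, conf_level = 0.95) {
  stopifnot(inherits(conf, "confusion"))
  n_pos <- conf$tp + conf$fn
  n_neg <- conf$fp + conf$tn
  n_all <- n_pos + n_neg
  if (n_all < 1) stop("no paired persons in confusion matrix", call. = FALSE)
  ks <- c(conf$tp, conf$tn, conf$tp + conf$tn)
  ns <- c(n_pos, n_neg, n_all)
  est <- ifelse(ns > 0, ks / ns, NA_real_)
  ci <- clopper_pearson(pmax(ks, 0), pmax(ns, 1), conf_level)
  ci$ci_low[ns == 0] <- NA_real_
  ci$ci_high[ns == 0] <- NA_real_
  pv <- predictive_values(est[1], est[2], prevalence)
  out <- tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy", "ppv", "npv"),
    estimate = c(est, pv$ppv, pv$npv),
    ci_low = c(ci$ci_low, NA, NA),
    ci_high = c(ci$ci_high, NA, NA),
    k = c(ks, NA, NA),
    n = c(ns, NA, NA)
  )
  structure(out, class = c("diag_report", class(out)),
            prevalence_used = prevalence, confusion = conf)
}

#' @exportS3Method generics::tidy
tidy.diag_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.diag_report <- function(x, ...) {
  est <- stats::setNames(x$estimate, x$metric)
  conf <- attr(x, "confusion")
  tibble::tibble(
    sensitivity = est[["sensitivity"]],
    specificity = est[["specificity"]],
    accuracy = est[["accuracy"]],
    ppv = est[["ppv"]],
    npv = est[["npv"]],
    prevalence_used = attr(x, "prevalence_used"),
    n_paired = conf$tp + conf$fn + conf$fp + conf$tn
  )
}

#' Plot a diagnostic accuracy report
#'
#' Point estimates with exact confidence intervals for each accuracy
#' metric (PPV/NPV have no interval; see [diagnostic_report()]).
#'
#' @param object A `diag_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.diag_report <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$metric <- factor(df$metric, levels = rev(df$metric))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$metric)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)
    ) +
    ggplot2::scale_x_continuous(limits = c(0, 1),
                                labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "estimate (exact 95% CI where available)", y = NULL)
}
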