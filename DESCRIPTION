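Package: kinrisk
Title: Familial Cancer Risk from Genealogies with Exact Poisson Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating familial cancer risk from population
    genealogies linked to a cancer registry. Enumerates first- and
    second-degree relatives of genotyped probands, computes expected cancer
    counts by indirect standardization over sex, birth-state and 5-year
    birth-cohort strata, and estimates standardized incidence ratios
    (relative risks) with exact Poisson one-sided tests and confidence
    intervals, including small-count masking for disclosure control. Also
    resolves replicate genotype assay calls, measures somatic-versus-germline
    genotype concordance with exact binomial confidence intervals and
    prevalence-adjusted predictive values, and simulates multi-generation
    pedigrees with Mendelian transmission of a biallelic risk variant,
    cohort-structured cancer incidence and planted familial relative risks,
    so the whole pipeline can be exercised without restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
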