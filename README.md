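# kinrisk

Familial cancer-risk estimation from population genealogies, with exact
Poisson inference and somatic-vs-germline genotype concordance.

## The problem

Studies of inherited cancer risk in population genealogy databases ask a
simple question with several technical layers: are the relatives of index
patients (probands) who carry a germline risk variant diagnosed with cancer
more often than the general population would predict? Answering it requires

1. **pedigree traversal** — enumerating each proband's first-degree
   (parents, full siblings, children) and second-degree relatives
   (grandparents, grandchildren, full aunts/uncles, nieces/nephews,
   half-siblings) in a large, incomplete genealogy;
2. **indirect standardization** — an expected cancer count for a relative
   set, built from cohort-specific reference rates where a cohort is a
   (sex, birth-state, 5-year birth block) stratum:
   `E = Σ_c n_c · r_c`, with `n_c` relatives in cohort `c` and `r_c` the
   cohort's cumulative incidence proportion for the cancer site;
3. **exact Poisson inference** — the standardized incidence ratio
   `RR = O / E`, a one-sided test of `RR ≤ 1` treating `O ~ Poisson(E)`,
   and exact confidence bounds from chi-square quantiles:
   `low = χ²_{0.05}(2O)/(2E)`, `high = χ²_{0.975}(2(O+1))/(2E)`;
4. **genotype call resolution** — deciding each proband's carrier status
   from replicate assay runs on blood and/or tumour DNA, and quantifying
   how well tumour DNA predicts the germline genotype (sensitivity,
   specificity and accuracy with exact Clopper–Pearson intervals, plus
   prevalence-adjusted predictive values via Bayes' formula).

Because real genealogy-registry resources are access-restricted, the
package also ships a forward-time simulator: multi-generation pedigrees,
Mendelian transmission of a biallelic SNP (default tuned so 8% of the
population carries the risk allele), cohort-structured baseline cancer
incidence with optional planted familial risks, and a replicate genotype
assay with configurable error rates. Every pipeline stage is testable
end-to-end without restricted data.

## Worked example

The exact-Poisson engine, on an observed count of 13 against an expected
7.56:

```r
library(kinrisk)
sir_exact(13, 7.56)
#>     obs   exp    rr p_one_sided ci_low ci_high
#> 1    13  7.56  1.72      0.0449   1.02    2.94
```

Read: the relatives experienced 1.72 times the expected number of cancers;
under the Poisson null the chance of 13 or more events is 0.045; the exact
95% interval for the ratio is 1.02–2.94, excluding 1.

A complete simulated study — genealogy, registry, genotype assay — analysed
end to end:

```r
sim   <- simulate_study(sim_config(seed = 1))
study <- run_familial_study(sim$genealogy, sim$registry, sim$assay)

render_sir_table(study$sir) |> dplyr::filter(group == "carrier", degree == "1")
#>  group degree       site  obs  exp p_one_sided   rr       ci_95
#> carrier      1        ANY <=5* <=5*       0.544 1.03   0.35-2.63
#> carrier      1      BRAIN <=5* <=5*       0.973 0.00 0.00-109.04
#> carrier      1 COLORECTAL <=5* <=5*       0.698 0.00   0.00-8.33
#> carrier      1      OTHER <=5* <=5*       0.526 1.08   0.29-3.15
#> carrier      1   PROSTATE <=5* <=5*       0.502 1.43   0.07-7.98
#> carrier      1    THYROID <=5* <=5*       0.218 4.07  0.21-22.70
```

Observed/expected counts of five or fewer are masked (`<=5*`) the way
registry reports suppress small cells; the RR, p and CI stay visible. At
this study scale (41 eligible probands, 18 carriers) no planted-free site
shows an excess, as expected under the null.

The concordance module, on the same simulated assay:

```r
glance(study$concordance)
#>   sensitivity specificity accuracy   ppv   npv prevalence_used n_paired
#> 1         0.8           1    0.903     1 0.882             0.4       31
```

`tidy()` on the report adds the exact binomial intervals; `autoplot()`
draws the metric dot-and-interval plot, and `autoplot(study$sir)` a forest
plot of the relative risks.

## Acceptance script

`scripts/acceptance.R` regenerates the default simulated scenario from a
seed, runs the full pipeline (call resolution → eligibility → cohort rates
→ exact-Poisson relative risks → concordance report), writes the rendered
tables next to the JSON output, and exits 0 on success:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
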