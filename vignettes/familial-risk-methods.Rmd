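---
title: "Familial cancer risk from genealogies: models, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial cancer risk from genealogies: models, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinrisk)
```

## The estimand

For a set of probands genotyped at a germline risk locus, the package
estimates the relative risk of cancer in their first- and second-degree
relatives as a standardized incidence ratio: the observed number of
relatives with a registry record of a cancer site, divided by the number
expected if those relatives experienced the reference population's
cohort-specific rates. Cohorts are (sex, birth-state flag, 5-year birth
block) strata; the expected count is

$$E = \sum_c n_c \, r_c,$$

where $n_c$ is the number of relatives in cohort $c$ and $r_c$ the
cohort's cumulative incidence proportion for the site. Note the rates are
*per-person lifetime proportions* (cases/persons), not person-year rates:
the expected count multiplies relative counts, not follow-up time. This
matches how genealogy-database familial studies are usually standardized,
and it is why `expected_count()` is linear in both the relative set and
the rate table. The cost of this convention is that it ignores differential
follow-up (deaths, migration, registry windows); see Limitations.

## Relationship degree

Degree is minimal genetic kinship: first degree covers parents, children
and full siblings; second degree covers grandparents, grandchildren, full
aunts/uncles, nieces/nephews and half-siblings. Three conventions needed
fixing where genealogy data is incomplete:

* full siblings require both parents recorded and shared; sharing exactly
  one recorded parent makes a half-sibling (second degree);
* missing parents terminate traversal silently — genealogies are
  incomplete by nature, and a person with one recorded parent is traversed
  through that parent only;
* when both a first- and a second-degree path exist, the closer degree
  wins, so the two sets are disjoint by construction.

Spouses are never relatives (no genetic path). Within one analysis group a
person related to several probands is counted once, and genotyped probands
are excluded both from all relative sets and from the reference-rate
denominators, so the same person never contributes to both sides of the
ratio. The test suite checks the traversal against an independent
kinship-coefficient recursion ($\phi = 1/4$ exactly for first degree,
$1/8$ for second, in outbred pedigrees) on a thousand random pedigrees.

Eligibility follows the linked-genealogy depth rule: a proband qualifies
when the deepest recorded ancestor chain, counting the proband, spans at
least `min_generations` (default 3). We read "three generations" as
ancestor depth — self, parent, grandparent — rather than any lineal chain
through descendants; the threshold and the definition sit behind
`generations_linked()`/`eligible_probands()` so other readings are one
argument away.

## Exact Poisson inference

Under the null the observed count is Poisson with mean equal to the
expected count. For $O \ge 1$ the one-sided p-value is the upper tail
$P(X \ge O)$. For $O = 0$ the upper tail is identically 1; published
familial-risk tables nevertheless print a value on zero-count rows, and
the value they print is the point probability $P(X=0) = e^{-E}$. We
implement that convention as observed rather than rationalize it, and flag
it in the documentation: a zero-count "p" of 0.77 is not a tail
probability.

The confidence bounds use the chi-square quantile form, scaled by $E$ so
they bound the ratio rather than the mean:

$$\mathrm{low} = \frac{\chi^2_{\alpha_L}(2O)}{2E}, \qquad
  \mathrm{high} = \frac{\chi^2_{1-\alpha_H}(2(O+1))}{2E},$$

with $\mathrm{low}=0$ and $\mathrm{high} = -\ln(\alpha_L)/E$ at $O=0$. The
defaults are deliberately asymmetric — $\alpha_L = 0.05$ (a one-sided 95%
lower bound) and $\alpha_H = 0.025$ (a two-sided 97.5% upper bound) —
because that mixed convention is the one that reproduces published
familial standardized-incidence-ratio tables row for row, including
zero-count and single-count rows. Both levels are exposed as arguments;
symmetric 95% intervals are `alpha_low = 0.025`. The bounds are exact in
the root sense: $P(X \ge O \mid \lambda = \mathrm{low}\cdot E) = \alpha_L$
and $P(X \le O \mid \lambda = \mathrm{high}\cdot E) = \alpha_H$, which the
tests verify to $10^{-8}$ by direct tail summation for $O \le 50$.

Small-count masking (`obs <= 5` by default) only affects rendering: the
observed and expected counts print as `<=5*` while RR, p and CI remain,
mirroring registry disclosure-control practice. No multiple-testing
adjustment is applied; the tables report raw one-sided p-values.

## Genotype calls and concordance

Replicate assay runs resolve to person-level calls asymmetrically, because
the two DNA sources err differently:

* **germline (blood)**: carrier only if some replicate has *both* runs
  detecting the risk allele (complete two-run agreement); noncarrier
  requires at least one fully concordant negative replicate; anything else
  is indeterminate. The negative rule is our symmetric completion of the
  published positive rule, chosen conservatively so that discordant-only
  data never produces a definite call.
* **somatic (tumour)**: carrier if *any single run* detects the allele — a
  permissive rule reflecting that tumour aneuploidy can suppress signal in
  one run; noncarrier requires all informative runs negative.

Concordance takes the germline call as truth and the somatic call as test.
Sensitivity, specificity and accuracy carry exact Clopper–Pearson
intervals (root-checked against the binomial tail equations). Predictive
values use Bayes' formula at an externally supplied prevalence (default
0.40, the approximate carrier fraction among patients with IDH-mutant
oligodendroglioma/astrocytoma) rather than the validation sample's mix,
since the sample is not prevalence-representative. No confidence intervals
are emitted for PPV/NPV: they are functions of an assumed prevalence, and
none of the standard methods (exact on the raw table, logit/Mercaldo,
endpoint propagation) corresponds to a defensible interval for the
prevalence-adjusted quantity here, so we decline to print one rather than
print one without a method.

Probands with tumour DNA only can have germline status imputed from the
somatic call (`impute_germline = TRUE`), justified by the measured
concordance; imputed rows are flagged so downstream analyses can be run
with and without them.

## The simulator: what it emulates, and what it does not

`simulate_study()` generates every input the pipeline reads. Design
choices, fixed once:

* **Pedigree**: discrete non-overlapping generations; founder couples plus
  spouses who marry in as new unrelated individuals, so the population is
  outbred and degree classification is unambiguous. Defaults: 40 founder
  couples, 4 generations, Poisson(2.8) offspring per couple, 27-year
  generation gap with 3-year jitter, Gaussian lifespans (78 ± 12 y) —
  a mid-20th-century American-West demographic sketch, not a projection.
* **Genotypes**: founders Hardy–Weinberg at allele frequency
  $f = 1-\sqrt{0.92} \approx 0.0408$, chosen so the carrier fraction
  $2f(1-f)+f^2$ is exactly the 8% population carrier frequency the
  scenario states; children inherit one allele from each parent.
* **Probands**: 102 genotyped; sampling is stratified so that ~40% link to
  three or more generations (emulating record-linkage failure) and ~44%
  carry the risk allele (emulating disease-based ascertainment of a
  variant enriched in the disease), reproducing the 102/41/18 shape of a
  realistic study without copying any person-level data.
* **Registry**: each person develops each site independently with
  probability baseline rate × planted multipliers. Baselines put an
  any-site cumulative incidence near 7% with prostate restricted to males
  and oligodendroglioma at order $10^{-4}$. Risk is planted directly on
  *group membership* (relatives of carrier probands, by degree), not
  through a mechanistic penetrance model: the planted multiplier is then
  exactly the quantity the pipeline estimates, which makes recovery tests
  sharp rather than approximate.
* **Assay**: the 43/21/38 somatic-only/germline-only/both source mix;
  somatic calls err at the person level (false-negative 0.143,
  false-positive 0.042, matching 85.7% sensitivity and 95.8% specificity);
  germline replicates discord at 5% per replicate, a typical plate-assay
  replicate failure rate (no published value constrains it).

What a green simulation test establishes is calibration and recovery
*under this stated world*: the one-sided test rejects at or below its
nominal rate with no planted risk, and a planted first-degree relative
risk of 1.7 is recovered to within 0.15 once relative sets reach a couple
of thousand persons. What it does not establish: robustness to overlapping
generations, consanguinity, migration, secular incidence trends,
differential registry coverage, or genotyping batch effects — none of
which the generator models.

Two scale notes on the shipped calibration tests. The null check runs 500
replicates at deliberately reduced scale (10 founder couples, 10 probands)
with the allele frequency raised to 0.2 so that tiny proband samples still
contain carriers; null calibration is invariant to the allele frequency,
which only controls how many replicates contribute. The recovery check
uses a ~37,000-person population with 1,100 probands so the planted group
stays a small fraction of the reference population: expected counts are
estimated from the same simulated population, so a planted group that is
a large fraction of it would inflate the reference rates and bias the
ratio toward 1 — visible in the arithmetic of $E$, and the reason the
real design needs a population database many times larger than any one
family cluster.

## Numerical and degenerate-input conventions

* Rates with an empty cohort cell are stored as 0 with denominator 0 and a
  warning; relatives whose cohort is absent from the rate table contribute
  0 to the expected count, with a warning.
* Individuals without a birth year are uncohortable: excluded from rate
  denominators, numerators and expected counts, with logged counts.
* `exp = 0` makes the ratio undefined: `run_familial_risk()` reports `NA`
  inference columns for such rows rather than failing the whole table.
* Rendering rounds RR and CI bounds to 2 decimals, p to 3, expected counts
  to 2 — the precision of published tables; full precision is kept
  internally and in `tidy()` output.
* All generator randomness flows from one config seed; a fixed seed
  reproduces every output file byte for byte.

## Limitations

Rates are lifetime proportions with no person-year denominator, so the
expected counts inherit any differential mortality or registry-window
censoring present in the data; the package surfaces but does not model
them. Kinship stops at degree 2; no kinship coefficients beyond the
oracle used in tests, no consanguinity metrics, no probabilistic record
linkage. The masked-cell convention protects small counts in rendered
output only — the underlying tibbles retain exact values, as they must for
downstream computation, so disclosure control is the caller's
responsibility at publication time.
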