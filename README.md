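# alriscore

Validation machinery for point-based clinical severity scores in pediatric
acute lower respiratory tract infection (ALRI). The package is aimed at
epidemiologists and clinical researchers who need to compute published
pneumonia/bronchiolitis risk scores on admission-level data and evaluate how
well they discriminate in-hospital mortality — the workflow used in external
validation studies of the RISC, mRISC, RISC-Malawi, PERCH, PREPARE and
ReSVinet scores in East African hospital cohorts, including a
nutrition-augmented ReSVinet variant.

Because the hospital surveillance data behind such studies are not publicly
deposited, the package ships a seeded synthetic cohort generator that
emulates the published cohort's categorical structure (a 2–24-month
admission cohort with a 7.0% in-hospital case fatality rate), so every
pipeline stage is fully testable from code alone.

## What it computes

**Scores.** Each score is a declarative table of components; a component maps
an admission record through a named *extractor* (e.g. `spo2_lt90`,
`muac_band`, `resp_rate_band`) to a category, and each category to integer
points. The total is the sum over components. Components the record schema
cannot assess (e.g. ReSVinet's apnea item) are declared unavailable and
contribute 0, matching partial-score evaluation practice. The eight bundled
definitions are reconstructions from the original score publications,
adapted to the fields of this package's admission record (see the methods
vignette for caveats).

**Discrimination.** For score total *S* and outcome *D* (death), the AUROC is
the Mann–Whitney probability

    A = P(S_death > S_discharge) + 0.5 · P(S_death = S_discharge)

estimated over all (death, discharge) pairs via midranks. Variance and the
covariance of correlated AUROCs use the DeLong placement-value
decomposition, giving Wald 95% CIs (truncated to [0, 1]) and two-sided
paired z-tests, `z = (A_a − A_b)/√(v_a + v_b − 2c_ab)`. Threshold sweeps
report sensitivity, specificity, Youden J (= sens + spec − 1), the
proportion classed high-risk (score ≥ cutoff), and the observed case
fatality rate among the high-risk; the optimal cutoff maximizes J.

**Descriptives.** Outcome-stratified counts/percentages with crude odds
ratios (2×2 cross-product, Woolf log-scale CI) and age/sex-adjusted odds
ratios from per-exposure logistic fits.

**Synthetic cohorts.** Covariates are drawn from configurable category
prevalences (defaults: the published cohort margins); the outcome follows a
logistic model whose coefficients are exactly the conditional odds ratios
the descriptive machinery should recover, with the intercept calibrated by
bisection to the target case fatality rate.

## Worked example

```r
library(alriscore)

records <- generate_flowchart_fixture(20150101L)          # 2261 admissions
flt <- apply_cohort_filter(records, cohort_spec("A"),
                           default_required_fields())
flt$tally
#> age_out_of_range       no_alri_dx     missing_data    other_outcome
#>                0                0               60               19
#>    date_excluded         included
#>                0             2182

cohort <- flt$included
mean(cohort$outcome == "died")                            # 0.0697 -> CFR 7.0%

m <- compute_score_matrix(cohort, load_score_definitions())
ra <- delong_ci(m$risc_malawi_muac, cohort$outcome == "died",
                score_id = "risc_malawi_muac")
sprintf("AUROC %.3f (%.3f-%.3f), %s", ra$auroc, ra$ci_low, ra$ci_high, ra$band)
#> "AUROC 0.795 (0.758-0.832), acceptable"

optimal_cutoff(threshold_table(m$risc_malawi_muac, cohort$outcome == "died"))
#>   cutoff sensitivity specificity youden_j proportion_high_risk observed_cfr_high_risk
#> 1      6       0.763       0.698    0.461                0.335                  0.159
```

The filter tally is the inclusion flow chart: of 2261 eligible admissions,
60 are excluded for missing score fields and 19 for absconding/transfer,
leaving the 2182-admission primary cohort with 152 deaths. On this
synthetic cohort the MUAC variant of RISC-Malawi discriminates best, and a
score of ≥ 6 is the Youden-optimal high-risk cutoff (score values are
definition-dependent; see the vignette).

Crude odds ratios recomputed from the published stratified counts of the
real cohort:

```r
ors <- published_crude_ors()
subset(ors, variable == "muac_cat" & category == "severe")
#>   variable category odds_ratio   ci_low  ci_high
#> 8 muac_cat   severe   7.843828 5.247196 11.72543   # printed as 7.8 (5.2-11.7)
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline and write
their tables under `results/`:

1. `01_simulate_cohorts.R` — inclusion-flow fixture + 20 000-admission cohort
2. `02_cohort_flow.R` — exclusion tallies for cohorts A–F
3. `03_scores.R` — admission × score matrices (complete-case and skip-missing)
4. `04_descriptives.R` — descriptive table, crude/adjusted ORs
5. `05_discrimination.R` — AUROCs, pairwise DeLong matrix, threshold tables,
   age-stratified AUROCs, nutrition-modification comparison

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

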