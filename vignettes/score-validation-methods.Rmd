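---
title: "Methods: severity-score validation for pediatric ALRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity-score validation for pediatric ALRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children admitted to hospital with acute lower respiratory tract
infections (ALRI — pneumonia and bronchiolitis) in low-resource settings
face substantial in-hospital mortality. Several point-based risk scores
have been proposed to triage them: each converts bedside observations
(oxygen saturation, chest indrawing, consciousness, nutritional status,
respiratory rate, and similar) into integer points whose sum is meant to
rank children by mortality risk. External validation of such scores asks
one question above all: how well does the total *discriminate*, i.e. rank
the children who will die above those who will survive? This package
implements that validation workflow end to end — cohort construction,
score computation, discrimination analysis, and descriptive
epidemiology — together with a synthetic cohort generator, since the
hospital surveillance data such studies draw on are typically not
publicly deposited.

## Admission records and cohorts

An admission record carries age in months (1–59), sex, admission date,
outcome (died, discharged, absconded, transferred), respiratory rate,
SpO2, a five-level conscious-level scale, three malnutrition measures
(MUAC in cm, weight-for-age and weight-for-length z-scores), sixteen
binary clinical signs each coded present/absent/missing, and two flags
(ALRI discharge diagnosis; severe presentation at admission). CSV I/O
uses `NA` sentinels and ISO dates and round-trips exactly.

Six cohort specifications mirror the usual primary-plus-sensitivity
design: A (2–24 months, ALRI diagnosis, complete cases — the primary
cohort), B (no diagnosis requirement), C (2–59 months), D (missing data
retained), E (excluding the first pandemic year, 13 March 2020 – 13
March 2021), and F (admissions strictly before 13 March 2020). Design
choices that the validation literature leaves implicit are fixed here
deterministically:

* **Exclusion precedence** is age → diagnosis → missing data → outcome →
  date; each record is tallied under the first criterion it fails, so the
  flow-chart accounting is reproducible and the tally always sums to the
  input count.
* **Cohort E's window is closed on both ends**; cohort F keeps strictly
  pre-window admissions. A record dated on the boundary is excluded by
  both.
* **The complete-case field set is a parameter**, not a constant: it
  defaults to the union of fields used by the bundled scores' assessable
  components plus the three malnutrition measures
  (`default_required_fields()`), which is what cohort D's skip-missing
  semantics reuse. This avoids guessing which fields a given study
  checked.
* **Age is whole months with inclusive bounds** (2–24 means 2 ≤ age ≤ 24),
  matching month-labeled reporting bands.

## Anthropometry and vital-sign thresholds

All thresholds use a strict less-than on the lower side, following how
they are written clinically: MUAC < 11.5 cm severe, < 12.5 cm moderate;
z-scores < −3 severe, < −2 moderate (so z = −2 exactly is *normal*).
The WHO fast-breathing cutoff is 40 breaths/min at 2–11 months and
50 breaths/min from 12 months; the 50 bpm cutoff is extended through 59
months for the wider-age cohort, since the guideline bands do not change
again below 5 years. Rates are banded by their excess over the cutoff
(<0, 0–9, 10–19, ≥20). The nutrition component added to the
bronchiolitis score awards 0/2/3 points for normal/moderate/severe
malnutrition, graded like the score's other items.

## The declarative scoring engine

Score weights are data, not code. A definition file lists, per score,
its components; each component names an *extractor* (a deterministic
mapping from record fields to a small category vocabulary) and a
category → points table. The engine validates definitions on load
(unique component ids, every extractor category priced, declared
theoretical range equal to the component-wise sums) and evaluates them
uniformly, so transcription of a new score is auditable and needs no
code change.

Two kinds of "absent" are distinguished deliberately:

* **Structurally unavailable components** (not collected by the record
  schema at all — e.g. the bronchiolitis score's apnea and
  medical-intervention items, the PERCH grunting and illness-duration
  items, the mRISC night-sweats and malaria items) are declared in the
  definition and always contribute 0. Totals are therefore partial
  scores, as in real-world validation against routine data.
* **Missing fields** (collected but absent for a record) follow a policy:
  `fail` (complete-case analysis; the default) errors naming the
  component and field, while `skip` contributes 0 and reports the
  component in `components_skipped_missing` — the semantics used when
  sensitivity-testing with incomplete records. With complete data the two
  policies agree exactly, which is tested.

**Provenance caveat.** The eight bundled definitions (RISC HIV-negative,
mRISC, the MUAC and weight-for-age variants of RISC-Malawi, PERCH,
PREPARE, ReSVinet, and the nutrition-augmented ReSVinet) are
*reconstructions* assembled from the original development publications
and adapted to this record schema; they are not verbatim copies of any
single published weight table, and individual weights may differ from a
given study's operational transcription. The engine, the tests and the
discrimination machinery are all weight-agnostic — tests read point gaps
from the definition file rather than hard-coding them — so replacing the
JSON file with an exact transcription changes no code. The graded
bronchiolitis items are encoded algorithmically (feeding intolerance
from the unable-to-drink flag; respiratory difficulty from indrawing /
deep breathing / head nodding; general condition from the conscious
scale; respiratory frequency from the rate band); presentations the
schema cannot distinguish from normal map to the lowest category. The
fever item is also declared unavailable because the record schema
carries no temperature.

The nutrition modification appends one component (MUAC, WAZ or WLZ band
at 0/2/3 points) to the base definition; the three variants differ only
there, and the modified-minus-base difference is by construction in
{0, 2, 3}.

## Discrimination analysis

The AUROC is computed as the Mann–Whitney statistic with midrank tie
handling — the mean over all (death, discharge) pairs of 1, ½ or 0 —
implemented via ranks in O(n log n), with an O(n²) exhaustive-pair
oracle retained in the test suite. Variances use the DeLong structural
components: per-death and per-discharge placement values whose sample
variances give `var(A) = S10/m + S01/n`, and whose covariances give the
paired two-sided z-test between correlated AUROCs. Conventions:

* The 95% CI is Wald on the AUROC scale, truncated to [0, 1]; a
  logit-scale interval is available as an option. No continuity or
  small-sample correction is applied.
* A paired test of a score against itself is exactly z = 0, p = 1; a
  degenerate pooled variance with unequal AUROCs raises rather than
  silently dividing by zero.
* No multiple-testing correction is applied across pairwise comparisons;
  the significance flag uses p < .01.
* Threshold tables sweep the distinct observed score values (scores are
  integer-valued), classifying score ≥ cutoff as high risk; the optimal
  cutoff maximizes Youden J with ties broken toward the smaller cutoff
  (the more sensitive rule).
* Interpretation bands follow the Hosmer–Lemeshow convention
  (< 0.50 none, 0.50–0.69 poor, 0.70–0.79 acceptable, 0.80–0.89 good,
  ≥ 0.90 excellent) applied to the *unrounded* AUROC.
* Stratified analysis (by age band) skips, with an explicit reason, any
  stratum lacking at least two records of each outcome class instead of
  erroring.

Calibration is intentionally out of scope: most source publications omit
the model intercept, so predicted probabilities cannot be reconstructed.

## Descriptive statistics

Crude odds ratios are 2×2 cross-products with Woolf (log-scale normal)
intervals, which reproduces published interval bounds to the printed
decimal. Zero cells fail loudly by default; the Haldane–Anscombe +0.5
correction is opt-in. Adjusted odds ratios come from one logistic fit
per exposure (`outcome ~ exposure + age band + sex`, age referenced to
2–5 months, sex to female) — not a joint model over all exposures —
because per-variable adjusted columns are the standard presentation.
Age enters as the descriptive band rather than continuous months; this
is an assumption, made because the band is the unit in which such tables
are reported. Fitting is maximum likelihood via IRLS (deviance tolerance
1e−8, at most 25 iterations) with three distinct failure modes:
rank-deficient designs error naming the collinear columns, complete
separation is reported as its own error, and constant covariates are
dropped with a warning (so a degenerate adjustment collapses to the
crude estimate, which is tested). Reported tables round half away from
zero to 1 decimal; unrounded values are retained internally.

## The synthetic cohort generator

The generator emulates the *categorical structure* of a published
admission cohort: each variable (age band, sex, respiratory-rate band,
three malnutrition bands, conscious level, SpO2 band, sixteen signs) is
drawn independently from configured prevalences — defaulting to the
published cohort's overall margins — and continuous measurements are
then drawn uniformly within the sampled band, so categorization recovers
the sampled category exactly. The outcome is Bernoulli from a logistic
model linear in the sampled categories; default coefficients are the
logs of the published age/sex-adjusted odds ratios. The intercept is
calibrated by bisection (CFR tolerance 1e−6) so the expected case
fatality rate over the generated covariates equals the target (default
7.0%). Missingness is injected completely at random per field, at
configured rates, because no missingness mechanism is published; MCAR is
the neutral default. Every output is a pure function of the
configuration, including its seed.

Because the outcome model is logistic *in the categories*, generator
coefficients are exactly the conditional odds ratios that a logistic fit
on all model covariates should recover — an exact, testable contract
(recovery within 15% at n = 50 000 is asserted). Two consequences are
worth stating plainly:

* Odds ratios adjusted for age and sex only will sit *below* the
  generator coefficient for strong exposures: with several strong risk
  factors marginalized out, the collapsed odds ratio is attenuated
  (non-collapsibility). The recovery tests therefore condition on the
  full covariate set, and a dedicated test demonstrates
  confounding-versus-conditional behavior with an age-confounded
  construction.
* Covariate blocks are independent by default; the real joint
  distribution (e.g. MUAC–WAZ correlation, sign co-occurrence) is
  unknowable from published margins. Synthetic AUROCs are therefore
  *not* estimates of the published real-data AUROCs and should not be
  compared to them numerically — they exercise the machinery and
  reproduce qualitative patterns (the MUAC-based score discriminating
  best; the nutrition modification improving the bronchiolitis score),
  nothing more.

A deterministic inclusion-flow fixture complements the stochastic
generator: 2261 eligible admissions of which exactly 60 carry missing
score fields (4 missing both weight-derived z-scores, 16 missing
weight-for-age only, 38 missing weight-for-length only, 2 missing the
vomits-everything flag) and 19 a non-death/non-discharge outcome
(5 absconded, 14 transferred), leaving 2182 complete died/discharged
records with exactly 152 deaths (CFR 7.0%). Outcomes follow the logistic
model, with the death count pinned by flipping the records closest to
the decision boundary; the fixture is byte-stable through CSV
round-trips.

A separate Monte-Carlo oracle, `model_implied_auroc()`, draws covariates
only and evaluates the implied AUROC *exactly over the outcome
distribution* (probability-weighted pair comparison), avoiding outcome
sampling noise; empirical AUROCs on generated cohorts are tested to
agree with it within 0.02 at n = 20 000 vs 200 000 oracle draws.

## Problem sizes and runtime choices

The test suite uses n = 100 000 for calibration/marginal-fidelity checks,
n = 50 000 for odds-ratio recovery, n = 20 000 for AUROC recovery and
null-model recovery, n ≤ 200 for exhaustive-oracle equivalence, and
10–20-observation fixtures for the hand-checkable DeLong and Newton
oracles. These sizes keep each property statistically sharp (binomial
standard errors well inside the asserted tolerances) while the whole
suite runs in well under a minute. The brute-force oracles are O(n²) and
live only in the tests.

## Known limitations

* Score weights are reconstructions (above); absolute totals and
  optimal-cutoff values are definition-dependent and should not be read
  as validated clinical cutoffs.
* WAZ/WLZ are inputs; computing them from raw weight/length via WHO
  growth-standard LMS tables is out of scope.
* The generator models no seasonality, no epidemic structure, and no
  covariate dependence unless configured.
* Calibration of the scores is not assessed, only discrimination.
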