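---
title: "Methods: disproportionality analysis, time-to-onset, and risk modelling in faerspv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis, time-to-onset, and risk modelling in faerspv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`faerspv` implements the analysis chain used in spontaneous-report
pharmacovigilance studies — case cleaning, disproportionality signal
detection, time-to-onset characterisation, and logistic risk-factor
modelling — together with a synthetic report generator that provides ground
truth for all of it. This vignette is the package's account of the
statistical choices involved: what is computed, under which conventions,
with which defaults, and where the design was genuinely open.

## The data model

A raw extract consists of four `$`-delimited tables keyed by
`PRIMARYID`/`CASEID`: one demographic row per report *version* (`DEMO`),
drug entries with reporter-assigned role codes PS/SS/C/I (`DRUG`),
reaction preferred terms (`REAC`), and therapy episodes with start dates
(`THER`). The same patient case may appear as several versions — follow-ups
or resubmissions share a `CASEID` under distinct `PRIMARYID`s.

**Deduplication.** One version per case is kept: the latest `FDA_DT`, ties
broken by the highest `PRIMARYID`. Partial dates (`YYYYMM`, `YYYY`)
participate in this ordering at their available precision with missing
components treated as earliest; this gives a total order, so deduplication
is idempotent and invariant to input row order. Time-to-onset has its own,
stricter validity rule (below) and never uses padded dates.

**Drug matching** is exact-synonym: the verbatim string is trimmed,
internal whitespace collapsed, lower-cased, and looked up in a user-supplied
dictionary of generic and brand spellings. Substring matching is
deliberately not offered — combination-product strings ("X olamine tablet")
would otherwise create false exposures; the dictionary can enumerate the
variants that should match.

**Role policy.** A case counts as exposed only if at least one
dictionary-drug entry carries an allowed role; the default is primary
suspect (`PS`) only, with `c("PS","SS")` available by configuration. The
narrower default reduces misattribution from concomitant therapy at the
cost of discarding secondary-suspect reports; because published analyses
are ambiguous between the two conventions, the choice is recorded in the
run manifest. Cases excluded by role (and cases with no dictionary drug)
remain in the dataset as comparator background.

**Event mapping.** Reaction PTs are mapped to SMQ-style categories through
a user-supplied two-column table with a narrow/broad scope flag; the
default scope keeps narrow-scope terms only. The bundled
`tpora_smq_map_synthetic.csv` covers 45 thromboembolic PTs assigned to
three categories (venous, arterial, mixed/other embolic). The licensed
MedDRA dictionary does not name these groupings for redistribution, so the
bundled assignment is the package's own and the file is flagged synthetic;
any real analysis should substitute its licensed mapping.

**Unit normalisation.** Age codes YR/DEC/MON/WK/DY convert by 1, 10, 1/12,
1/52.1775 and 1/365.25 respectively; weights KG/LBS by 1 and 0.45359237.
Results outside (0, 120] years or (0, 500] kg, and unknown unit codes,
become missing with a summary warning — spontaneous reports contain enough
unit errors that silent acceptance would corrupt the covariate bins.

**Binning conventions.** The covariate bins are printed with overlapping
labels in the literature ("18-65" / "65-85"), so one convention must be
declared: age is half-open lower-inclusive `[0,18) [18,65) [65,85)
[85,Inf)`; weight `(0,50) [50,100] (100,Inf)` kg; therapy duration
`[0,365) [365,730] (730,Inf)` days. The convention is echoed into the run
manifest so that any downstream table is unambiguous.

**Missing data.** Descriptive tables use available-case denominators with
an explicit `NA` row (percentages over all cases of the drug, so categories
plus `NA` sum to 100%); univariable fits use available cases per covariate;
the multivariable fit is complete-case over the selected covariates.

## Disproportionality statistics

For a (drug, event) pair the 2×2 table counts deduplicated cases: `a`
exposed with the event, `b` exposed without, `c` background with, `d`
background without. A case contributes at most 1 to `a` regardless of
repeated PT rows. The comparator is every case in the loaded dataset whose
matched suspect drug is not the target ("all other drugs in the dataset");
against a full-database extract this is the usual all-other-drugs
background, but the choice is logged because a restricted load changes its
meaning.

- **ROR** `= ad/bc` with Wald CI
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Any zero cell leaves the
  statistic undefined and the flag negative; no Haldane 0.5 correction is
  applied by default, since the signal gate requires `a ≥ 3` and a
  correction could only manufacture spurious definedness.
- **PRR** `= [a/(a+b)]/[c/(c+d)]` with its Wald CI, plus the Pearson χ² of
  the table (1 df). The Yates continuity correction is off by default and
  available by flag.
- **BCPNN.** The information component `IC = log₂ p₁₁/(p₁p₂)` is treated
  in the standard one-layer Bayesian fashion with Beta priors α₁ = β₁ = 1
  on the margins, α = β = 2, γ₁₁ = 1 on the joint cell, and the joint
  prior weight γ calibrated to independence,
  `γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁))`. The package reports the
  closed-form expectation

  `E(IC) = log₂ [(a+γ₁₁)(N+α)(N+β)] / [(N+γ)(a+b+α₁)(a+c+β₁)]`

  its variance `V(IC)` (the standard three-term form), and
  `E(IC) − 2√V(IC)`. `E(IC)` is the log of a ratio of posterior means;
  the posterior mean of the log differs by a Jensen term of order `1/a`.
  `sample_bcpnn_posterior()` draws from the three Beta posteriors and
  serves as the in-repo oracle: for cells of a few dozen reports the two
  agree to ~0.01 bits (the acceptance script measures this on 50 random
  tables with 10⁶ draws each).
- **Tiers.** `E(IC) ≤ 0` → `-`; `(0,1.5]` → `+`; `(1.5,3]` → `++`;
  `>3` → `+++` (inclusive upper bounds).
- **Association test.** When any expected cell count under independence is
  below 5, a two-sided Fisher exact p is computed by hypergeometric
  enumeration (summing all tables with the observed margins whose point
  probability does not exceed the observed one, with the customary 1e-7
  relative tie slack); otherwise the Pearson χ² p on 1 df. The method used
  is recorded. The exact and asymptotic p-values converge as the table
  fills; at minimum expected counts near 50 the two-sided conventions can
  still differ by a few hundredths, dropping below 0.02 only for
  well-filled tables — the property suite checks convergence on tables
  with expected counts in the hundreds.

**The signal gate.** A pair is a suspected signal when all three methods
are positive: `a ≥ 3` with ROR lower CI > 1, `a ≥ 3` with PRR lower CI > 1,
and a positive information component. For the BCPNN criterion the package
defaults to `E(IC) > 0`, matching the tier-threshold presentation common in
published signal tables. This default is *not* a calibrated test: under
independence the shrunk observed/expected ratio exceeds 1 with substantial
probability, so the `E(IC) > 0` flag alone fires far more often than the
2.5% one-sided rate of the CI-based rules. The conservative convention
`IC − 2SD > 0` (`bcpnn_gate = "ic2sd"`) is the calibrated choice and is the
one used by the package's own null-calibration and recovery analyses; the
joint gate is dominated by the CI rules either way.

## Time-to-onset

`TTO = event onset date − therapy start date` in whole days, evaluated only
when both dates are complete (year, month, day) and parseable. Negative
intervals are excluded as implausible sequences; partial dates and missing
dates are excluded under their own statuses, so
`included + excluded_* = input` always holds. When a case has several
therapy rows for the target drug, the earliest complete start date is used
(therapy *initiation*). Same-day onset (`t = 0`) is a valid inclusion.

Bins are upper-inclusive integer-day intervals (0–30, 31–60, 61–90,
91–120, 121–150, 151–180, 181–360, >360), which partition the integers
exactly. Quartiles use linear interpolation between order statistics
(`quantile` type 7) — the quantile convention behind published quartile
summaries is rarely stated, so the package picks the most common default
and records the method name in the summary object.

## Logistic risk models

The model dataset has one row per exposed case with outcome `y = 1` when
the case reports at least one mapped event PT. Covariates are categorical:
age group, weight group, sex, therapy-duration group, and drug (reference
levels: first factor level; for the bundled reference table these are
`<18`, `<50`, `Female`, `<365`, `Avatrombopag`). The duration covariate is
computed from therapy start to event onset — of the readings of "treatment
duration" available in the schema, this is the computable one.

Univariable fits are available-case maximum-likelihood logistic
regressions (IRLS via `stats::glm`, relative-deviance tolerance 1e-8, at
most 100 iterations). For a one-way layout the fitted odds ratio per level
equals the closed-form cross-product ratio against the reference — an
algebraic identity the test suite verifies to 1e-6 relative. Covariates
with any non-reference Wald p < 0.05 enter the multivariable complete-case
fit; a warning is raised when complete cases fall below ten per estimated
coefficient, and non-convergence is an error rather than a silently wrong
table. CIs and p-values are Wald (`exp(β̂ ± 1.96·SE)`); profile-likelihood
intervals are deliberately not offered, because the reference tables the
package reproduces print point ORs exactly recomputable from counts while
their CI convention is unknown — the tests therefore pin point estimates
and require only overlap for intervals. A zero cell against the reference
level marks that level non-estimable (separation) instead of reporting a
diverged coefficient.

Multivariable odds ratios from published *marginal* count tables are out of
reach by design: marginals do not determine the joint covariate
distribution. The multivariable machinery is instead validated by
parameter recovery on synthetic joint data (planted coefficients
`log 5, log 1.5, log 0.3` at n = 50,000; nominal 95% Wald coverage over
200 replicates).

## The synthetic generator

`faers_sim_config()` defines the study conditions; its defaults are fixed,
not tuned. Per report: a suspect drug drawn by market share from a panel of
three TPO-RAs (with brand-name synonyms) plus five background agents; a
role code (PS 0.78, SS 0.10, C 0.10, I 0.02); independent Bernoulli
reactions over a 16-PT panel (7 thromboembolic terms with background
probabilities 0.0008–0.012, 9 common non-thromboembolic terms) where a
planted signal multiplies the pair's probability; demographics with ~30%
missing age, ~70% missing weight, ~11% missing sex, elderly-skewed ages,
US-led country mix and physician-led reporter mix, ages emitted in
YR/MON/DY/DEC units and weights in KG/LBS; a therapy start date in
2009–2024; a true onset day drawn lognormal(meanlog = log 81,
sdlog = 1.74) — median 81 days with quartiles ≈25 and ≈263 days, the onset
profile reported for this drug class (the matching mean is not
simultaneously attainable in a two-parameter lognormal and was not
targeted); an FDA receipt date shortly after onset. 12% of dates lose day
or month precision, 15% of onset dates are absent, 15% of therapy rows are
never emitted, and 15% of cases emit 2–4 versions with non-decreasing FDA
dates in which non-final versions may mutate weight and reporter fields.
Reports where no panel PT fired receive a dedicated filler PT ("Drug
ineffective") rather than a redraw, so the realised panel-PT probabilities
are exactly background × multiplier for every drug — the planted rate
ratio is the exact oracle for downstream estimates.

What the generator does *not* emulate: the MedDRA hierarchy beyond a flat
PT list, indication-related confounding and channelling, notoriety or
stimulated reporting waves, duplicate cases that differ in `CASEID`, and
correlated reaction co-occurrence. Passing tests on synthetic data
therefore demonstrate correctness of the pipeline's bookkeeping and the
calibration of its statistics under independence — not robustness to the
biases of real spontaneous-report data, which no simulator of this kind
certifies.

Two scenario presets are exported. `demo_scenario()` plants a mix of
strong and moderate signals for demonstration. `recovery_scenario()` is
the validation condition: multiplier 8 on (Avatrombopag, Embolism
arterial), a pair chosen for its low background probability so the odds
ratio and the planted rate ratio essentially coincide, with a PS-only role
mix so that every exposed report is analysable under the default role
policy — sized (30,000 cases) for an expected exposed-event count of ~24.
Under it, all three methods flag the planted pair in ≥95% of seeds and the
ROR Wald CI covers the planted ratio at roughly its nominal rate; under
the all-multipliers-1 null at the default size (5,000 cases), per-method
flag rates stay in the low single digits (percent). These are the rates
the acceptance script re-measures on every run.

## Problem sizes and determinism

The test suite uses 200 null-calibration replicates at 5,000 cases, 100
recovery replicates at 30,000 cases, and 200 coefficient-recovery
replicates at 50,000 rows — sizes at which Monte-Carlo error is small
relative to the asserted margins while the whole suite completes in a few
minutes on one core. All randomness flows through explicit seeds
(`withr::with_seed` internally); identical configuration plus seed gives
byte-identical tables, and `run_pipeline()` writes a manifest whose hash
is embedded in every output file, so two bundles are comparable at a
glance.

## Known limitations

Disproportionality measures are reporting associations within a reporting
database: no denominators, no incidence, no causal contrast, and the
comparator mass depends on what was loaded. The bundled SMQ map is a
synthetic stand-in. Exact-synonym drug matching will miss spellings not
enumerated in the dictionary. Fisher enumeration is exact but O(min
margin) per table, intended for the small-expected-count branch rather
than for scanning millions of pairs. The multivariable model assumes
additive log-odds with no interactions, matching the workflow it
reproduces rather than any stronger claim about the data-generating
process.
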