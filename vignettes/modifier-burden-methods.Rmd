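---
title: "Modifier-gene burden analysis: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modifier-gene burden analysis: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modburden)
```

# The scientific problem

Pathogenic variants in *SCN1A*, which encodes the Nav1.1 sodium-channel
alpha-subunit, cause epilepsy phenotypes ranging from mild familial febrile
seizures (GEFS+) to Dravet syndrome. Patients carrying the *same* pathogenic
variant can differ dramatically in outcome, which points at modifying
factors — among them variants in other epilepsy-related genes. `modburden`
implements a burden-style analysis for this setting: does a cohort of
*SCN1A* patients carry more qualifying variants in an epilepsy gene panel
than expected, are the excesses concentrated in patients with extreme
(unexpectedly mild or severe) outcomes, and which individual genes and
variants drive them?

# The reference-ratio burden statistic

Absolute variant counts cannot be compared directly between a locally
sequenced cohort and a public reference database (ExAC/gnomAD): capture
kits, coverage and calling differ. Within either resource, however, the
*ratio* of counts between two gene panels is largely platform-independent,
because both panels pass through the same pipeline. The core statistic
therefore works on ratios:

$$E[n_{\mathrm{target}}^{\mathrm{cohort}}] \;=\;
  \frac{n_{\mathrm{target}}^{\mathrm{ref}}}{n_{\mathrm{control}}^{\mathrm{ref}}}
  \times n_{\mathrm{control}}^{\mathrm{cohort}},$$

and the reported burden is the observed count as a rounded percentage of
this expectation, minus 100 (`+22` means 122% of the expected count was
observed). Significance comes from a two-sided Fisher exact test on

$$\begin{pmatrix}
  n_{\mathrm{target}}^{\mathrm{cohort}} & n_{\mathrm{control}}^{\mathrm{cohort}}\\
  n_{\mathrm{target}}^{\mathrm{ref}}    & n_{\mathrm{control}}^{\mathrm{ref}}
\end{pmatrix},$$

with a Bonferroni threshold of $0.05 / n_{\mathrm{tests}}$ over the grid of
(target panel × control configuration × frequency category × patient
group) comparisons.

Assumptions worth stating: the ratio-cancellation argument requires
roughly homogeneous coverage *within* each resource across the compared
panels; the Fisher test treats the four counts as independent draws, which
ignores that one patient can contribute several variants; and the
reference counts are consumed as given aggregates — the package never
re-derives them from site-level data.

## Fisher convention

The two-sided p-value follows the minimum-likelihood convention (the sum
of probabilities of all tables, at fixed margins, no more probable than
the observed one), computed in log space with `lchoose` so that margins in
the millions remain exact; the support sweep is bounded by the much
smaller cohort margin, so no large-sample approximation is ever
substituted. Probability ties are detected at a relative tolerance of
1e-7, the same rule `stats::fisher.test` uses. A doubling convention
(twice the smaller tail) is available via `conv = "double"`, but on the
bundled replication fixture the minimum-likelihood convention matches the
published p-values decisively better (105 of 108 cells within print
tolerance, versus 82).

## Rounding and display

Percentages are rounded to integers with ties away from zero (125.5% is
reported as +26, not +25 through round-half-even); p-values are kept at
full precision in machine output and conventionally displayed at three
decimals. The replication fixture keeps the published display values,
including three cells we believe to be misprints (a dropped minus sign on
one percentage and two garbled p-values); `cmd_replicate_paper()` reports
these cells in its diff rather than silently adjusting either side.

## Number of tests

The published grid has 108 cells but its stated threshold (.0003968)
corresponds to 126 tests; the discrepancy is not reconcilable from the
published material. `n_tests` is therefore a parameter: the default is the
number of cells actually computed, and the replication configuration pins
it to 126 to match the published threshold.

# Variant categories

Qualifying variants are PASS calls with a protein-altering consequence
(frameshift, stop gain/loss, start loss, in-frame indel, splice
donor/acceptor, missense), excluding each patient's known pathogenic
*SCN1A* variant. Categories are nested by population frequency and
CADD-PHRED deleteriousness: A (MAF < 0.01, CADD > 20), B (MAF < 0.01,
CADD > 10), C (MAF < 0.01), D (MAF < 0.05), E (MAF < 0.1). Three
conventions matter and are tested:

* "below the threshold in both exomes and genomes" is implemented as
  `max(af_exome, af_genome) < threshold`; a variant absent from one
  resource contributes 0 there (absence cannot exceed a threshold);
* inequalities are strict on both scales, exactly as the category
  definitions state them;
* a missing CADD score disqualifies only A and B — frequency-only
  categories are unaffected.

Categories A and B have no reference-database analogue (the aggregate
reference counts carry no CADD filter), so the burden grid runs on C, D
and E only; A and B appear in the within-cohort group comparisons and the
descriptive reports.

# Severity classification

Disease severity is cognitive outcome at age six: IQ/DQ assessments taken
at different ages are interpolated by ordinary least squares (via
`stats::lm`) and the fitted line is evaluated at age 6, without
extrapolation caps — the decline is steepest in the first disease years,
which is precisely why a fixed early age is used. A single assessment is
used as-is (a regression is undefined on one point); several assessments
at one identical age fall back to their mean with a warning. Scores above
70 are mild, below 50 severe, and 50–70 inclusive intermediate — the
boundary values belong to the intermediate band because the band is
defined inclusively while the outer rules are strict. Patients under six
are unclassified unless already below 50, and patients without usable
assessments stay unclassified via an explicit flag rather than a guessed
"reliability" rule.

The mild group used in comparisons is restricted to patients whose
*SCN1A* variant is LoF-class or previously described in Dravet syndrome:
a mild outcome despite such a variant is the strongest available signal
of ameliorating modifiers. Mild-restricted and severe patients together
form the "extreme" group. Family-relative severity labels (used by the
family reports) are taken from the phenotype table as supplied — they
encode qualitative judgments (different syndromes, large seizure-frequency
differences) that the package does not attempt to compute.

# Allele-scale group comparisons

Within the epilepsy panel, group variant loads are normalised to an
allele denominator: the number of genes with at least one qualifying
variant of the category in *any* compared group, times two alleles, times
the group's patient count, minus one allele per X-linked gene per male.
The gene universe is category-specific — each column of the resulting
summary is then internally consistent — and deliberately spans all
compared groups so that the denominators of two groups differ only
through patient counts and sex composition, never through which genes
happened to be hit. Zygosity is ignored on the numerator side (each
variant row counts once) while the denominator uses 2N; this convention
is documented rather than hidden because homozygous calls are rare at
these frequencies.

Pairwise group differences use the same exact Fisher core as the burden
grid (`compare_group_fractions` delegates to `fisher_ratio_test`), and
the per-gene mild-vs-severe ranking applies the identical test per gene
with per-gene allele totals.

## Power calculation

`required_fraction_for_power` inverts a pooled-variance normal-
approximation two-proportion power function by bisection (tolerance 1e-6
on the fraction), returning the smallest detectable fraction above a
baseline. The published "more than six times as many variant alleles
(25% vs 4.03%)" figure is reproduced (p2 = 0.23, ratio 5.7) only when
the calculation is run on the *patient* scale with 50 per group at
alpha 0.05; on the allele scale, with denominators in the tens of
thousands, the detectable ratio drops to about 1.2. The function itself
is scale-agnostic — callers choose the denominators — and the test suite
anchors the patient-scale case qualitatively, since the original
calculation names no method.

# Descriptive reports

Family reports list type-A variants (gene + HGVS identity) carried only
by relatively severe members (candidate aggravating modifiers) or only by
relatively mild members (candidate protective modifiers); variants shared
across the severity labels are excluded from both lists, and carrier ids
are listed per variant so nested sharing within larger families remains
visible without a hard-coded stratification. Extreme-patient reports pick
the highest-CADD type-A variant per gene class (established diagnostic
epilepsy genes vs candidate genes); when that variant sits in a recessive
gene and a dominant-gene variant exists in the class, the dominant one is
reported with a substitution flag. CADD ties break deterministically by
lower frequency, then alphabetical gene symbol — the published tables
never face a tie, so the rule is a package convention, stated and tested.
The severe-side inclusion cutoff (interpolated score < 30) is a
configurable default.

# The synthetic cohort generator

`generate_cohort` emulates the study conditions so every stage is
testable without any data download: 87 patients (29 mild / 22 severe /
18 intermediate / 18 unclassified, 10 of the mild LoF-flagged — giving
the 10/22/18 comparison groups), equal sex odds, per-patient-per-gene
variant counts `Poisson(rate x enrichment(set, group))` with a default
rate of 0.084, X-linked genes at half rate in males, and one flagged
known-*SCN1A* row per patient to exercise the exclusion rule. Frequency
strata {absent, (0, 0.01), [0.01, 0.05), [0.05, 0.1), [0.1, 0.5]} carry
default weights (0.08, 0.20, 0.33, 0.19, 0.20), chosen once so the
cohort's C:D:E count proportions (~35%, ~76% of E) match the study's
published totals at its cohort size; CADD-PHRED scores are gamma(7, 3),
placing roughly half the mass above 20 — threshold coverage, not a claim
of realism. IQ/DQ trajectories are noiseless declining lines constructed
through the assigned score at age six, so the severity classifier must
recover every band exactly; this validates the classification logic, not
its robustness to assessment noise. Reference counts are Poisson draws
from the same stratum weights scaled by 500 expected variants per gene,
large enough that reference-ratio noise is negligible against cohort
sampling noise.

What the generator deliberately omits — linkage disequilibrium,
site-level variant sharing between patients, trio structure, assessment
noise, coverage heterogeneity — bounds what green tests mean: they
demonstrate that the statistics recover what was planted under the
model's own assumptions, not that the model captures every property of
real exome data.

All randomness flows from a single seed through one stream with a fixed
patient-major draw order, so identical configurations are byte-identical
and results cannot depend on patient ordering.

# Validation design

The test suite runs three kinds of checks. Exact oracles: the Fisher
implementation is compared against a brute-force hypergeometric
enumeration over every nondegenerate 2x2 table with margins up to 12
(relative agreement 1e-12) and against `stats::fisher.test` on random
tables; OLS interpolation is checked against the closed-form solution.
Replication: the bundled aggregate-count fixture must reproduce the
published grid — percentages exactly, p-values within ±0.01 — with the
documented misprints as the only exceptions. Calibration: 200 synthetic
cohorts with a planted 1.2-fold epilepsy-panel enrichment in extreme
patients must recover a mean overrepresentation of +20 within ±3 points,
and 200 null cohorts must flag at most 1% of grid cells at the Bonferroni
threshold. Replicate counts and cohort sizes match the study conditions
(n = 87); the calibration arm completes in a few minutes on one core.

# Known limitations

* Reference counts are trusted aggregates; whether they represent
  distinct sites or allele counts is the provider's contract.
* The bundled gene lists are synthetic stand-ins with the study's panel
  sizes (the real panels are not published in full); analyses of real
  cohorts must supply their own lists and metadata.
* No gene-length or mutability normalisation is applied anywhere — the
  reference-ratio construction absorbs these only to the extent they are
  shared between cohort and reference.
* The Fisher tests ignore within-patient correlation of variant counts;
  with ~87 patients contributing thousands of variants, mild
  anti-conservatism cannot be excluded for the smallest p-values.
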