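---
title: "Cleaning multi-center pharmacy-record extracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning multi-center pharmacy-record extracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eprflow)
```

## The problem

Hospital electronic pharmacy records (EPRs) are filled in by physicians and
pharmacists during routine prescription, dispensation and administration of
injectable cancer drugs. Pooled across many centers they are a rich source of
real-world evidence on drug use, but the raw extracts are messy in
predictable ways: free-text drug names in many dialects (brand names, INNs,
mixed case, accents), histories truncated by software changes, same-day
duplicate codings, occasional concomitant second primaries, and —
crucially — disease stage and treatment line recorded at the clinician's
discretion, so substantially incomplete.

`eprflow` implements a reproducible data-management pipeline for such
extracts: **codify** free text onto fixed vocabularies, **exclude** patients
whose histories cannot support analysis, **infer** missing stage and line
from the administration history itself, **assess** the resulting cohort
(completeness, coverage, representativeness against a national reference),
and **quality-control** the inference rules by sampling patients and scoring
them with exact binomial intervals. A synthetic extract generator with
retained ground truth makes every stage testable end-to-end.

## Data model

One row per drug administration. The patient identifier is only unique
within a center (there is no national patient key in this setting, and the
pipeline deliberately never links patients across centers), so the patient
key is the (center, patient) pair. Within a patient, records are ordered by
administration date, then INN (lexical), then cycle number, then input row
order — a fully deterministic order that all downstream rules rely on.

Files are UTF-8 CSV with ISO-8601 dates and empty cells for missing values;
the full column dictionary ships as `extdata/data_dictionary.csv`. Loading
never silently drops a row: an unparseable date or a non-positive dose keeps
the row, sets the field missing and logs an entry in the load report.

A *regimen block* is a maximal run of administration days sharing the same
INN set, split additionally at treatment-free gaps longer than `gap_days`
(default 60 — one cycle-frequency of slack over typical 21–28-day cycles).
Regimen blocks drive truncation detection and line numbering.

## Exclusion rules

Patients are removed, with disjoint flow-chart accounting, when they show:

1. **R1 truncated start** — the earliest regimen block's recorded cycle
   numbers start above 1, so the beginning of the drug history is missing
   and treatment lines cannot be anchored. If no cycle number is recorded at
   all, truncation is not asserted (conservative default).
2. **R2 name mismatch** — a record whose brand name resolves to a different
   INN than the recorded drug name (a coding error that makes the drug
   identity untrustworthy).
3. **R3 duplicate injection** — two administrations of the same INN on the
   same day.
4. **R4 multiple primaries** — two or more distinct primary diagnoses across
   the patient's records.
5. **R5 other-cancer drug** — administration of a drug on the catalog's
   other-cancer list (drugs essentially specific to cancers outside the
   cohort; the shipped list is a synthetic seed assembled for testing, and
   is a plain editable CSV).

Precedence is the listing order; a patient violating several rules is
counted once, under the first. This makes per-rule counts disjoint, which is
what a flow chart reports. A sixth count, **R6 stage unresolved**, is added
after inference for patients whose stage could not be completed.

## Stage and line inference

The published programs this pipeline emulates use larger per-indication rule
sets (on the order of a dozen algorithms per cancer); their item-level
content is proprietary. `eprflow` instantiates the same three-step framework
— retrieve from other entries, check consistency over time, extract features
— as six pluggable rules, each with a stable id so alternative rule sets can
replace them and be audited identically:

* **S1** fill a missing stage from the nearest record of the same regimen
  block (backward first, then forward);
* **S2** if a block is entirely unlabelled, take the stage implied by
  regimen-label keywords (`extdata/regimen_keywords.csv`);
* **S3** severity ratchet: stage is corrected upward to the running maximum
  (early < locally advanced < metastatic), since a recorded regression of
  stage is a data error in this coarse vocabulary;
* **L1** fill a missing line from the regimen block's recorded line;
* **L2** number the blocks that have no recorded line at all by continuing
  from the last known line of the disease phase (1 at phase start),
  incrementing at each block boundary. After L1 every block is either fully
  labelled or fully missing, so L2 is what guarantees 100% line completion
  among retained patients. Numbering restarts at the metastatic transition —
  the standard oncology convention;
* **L3** lines are forced non-decreasing within a phase.

Every changed value gets exactly one audit entry (patient, record, rule id,
before, after); the audit is both the QC sampling frame and the
reviewability contract. Line inference runs only for stage-resolved
patients: phases are derived from stages, so line numbers for a patient
about to be excluded under R6 would be meaningless and would contaminate the
QC populations.

Inference is idempotent, stages are non-decreasing over time afterwards, and
stage/line completion among retained patients is exactly 100% — these are
tested properties, not aspirations.

## Assessment

* **Completeness**: per-variable completion rates; `patient`-level variables
  count a patient as complete when any record carries a value,
  `record`-level variables are counted per record. Variables under 70%
  completion are flagged unusable and never imputed.
* **Coverage**: platform patient counts over national counts, per stratum
  (center category × region) with per-cancer totals. Displayed as whole
  percents, rounded half away from zero; full precision is kept underneath.
* **Representativeness**: platform vs national distribution across strata;
  per-stratum absolute differences in percentage points, flagged above
  `flag_threshold_pp` (default 4, chosen so that gaps a reader of the
  published category tables would call discrepancies flag, while 3-point
  gaps do not), plus a supplementary chi-square goodness-of-fit that is
  reported descriptively and never gates a run. Displayed shares use one
  decimal by default and whole percents with `share_digits = 0`, matching
  the two conventions in published tables; the displayed gap is the
  difference of the displayed shares, as a reader would compute it.

Patients are attributed to the center of their first administration.

## Quality control

For each inference rule, the population is the set of patients the rule
touched. The review sample size is the finite-population-corrected

$$n = \frac{z^2 p (1-p) / e^2}{1 + z^2 p (1-p) / (e^2 N)},$$

rounded up (the conservative reading of "approximately"), with defaults
$e = 0.10$, $z = 1.65$, $p = 0.50$ — the most unfavorable planning
proportion. With these defaults $n$ is about 60 for populations of a few
hundred and tends to 68 as $N \to \infty$ (the ceiling of the uncorrected
68.0625). The estimated correct-application proportion gets an exact
Clopper–Pearson interval from Beta quantiles; exactness matters because the
observed proportions sit near 1, where normal approximations fail. In a
production program the review is a human chart review against source
records; here the synthetic generator's ground truth plays that role — the
sampling and estimation machinery is identical by design.

## The synthetic generator

`generate_extract()` emulates the structure of a large multi-center
assessment: centers stratified by category × region; a breast/lung mix of
0.835; 1–4 sequential regimens per patient, each a fixed INN set (always
containing a cohort drug of interest) given every 21 days for 4–8 cycles,
with inter-regimen gaps of 7–45 days and consecutive regimens always
differing in composition; stage trajectories that move only upward and only
at regimen boundaries. Default masking rates reproduce the pre-inference
completion rates of the emulated assessment: stage 93%/77% and line 80%/70%
for breast/lung. Masked patients split (default 50/50) between *partial*
masking — isolated records inside regimens, recoverable exactly by S1/L1 —
and *full* masking, recoverable by S2 only when regimen labels carry a stage
keyword (default rate 0.8), otherwise ending in R6.

Error modes are drawn per patient, mutually exclusive by default so per-rule
exclusion counts are exact in tests (a flag allows overlaps for
precedence testing). Default prevalences are anchored on the published
flow-chart: truncation 1,134/30,730 ≈ 0.037; the remaining four modes split
the residual 683/30,730 evenly, ≈ 0.006 each (per-rule splits beyond the two
published counts are not public, so this is a modelling choice made once).

What the generator does **not** model: survival, toxicity, dosing
pharmacology, cross-center patient movement, real vocabulary drift beyond
the shipped synonym seeds, and inference-resistant inconsistencies other
than the ones its masking scheme creates. Passing tests therefore show the
pipeline's rules are implemented correctly and are exact on recoverable
corruption; they do not certify recovery rates on real clinical data, where
the recoverability assumptions (stage constant within a regimen, lines
incrementing at regimen changes) hold only approximately.

## Numerical and design choices

* Rounding for display is half-away-from-zero (base R's `round()` is
  half-to-even, which disagrees with how published percentage tables are
  rounded); underlying reports always carry full precision.
* The stage vocabulary is fixed to early / locally_advanced / metastatic
  with that severity order; synonym tables (French and English seeds) map
  free text onto it and are data files, editable without code changes.
  Matching is exact after normalization (case, whitespace, diacritics) —
  no fuzzy distance, so unknowns surface in reports instead of being
  silently miscoded.
* Ties on the same day are broken by INN then cycle number then input
  order, making every rule deterministic.
* Degenerate inputs: empty files load as empty extracts; an empty analyzable
  population skips assessment with an explicit warning; a zero national
  count yields undefined coverage with a warning rather than an infinity.
* Test and simulation scale: property suites run on cohorts of a few
  hundred to a few thousand synthetic patients (5,000 for binomial
  parameter-recovery checks, 1,000 extracts for conservation, 2,500
  replicates for interval coverage) — sizes at which the binomial bounds
  being tested are sharp. The parameter-recovery tests use full masking
  (partial share 0) so that the per-patient masking rate is identified by
  the patient-level completion rule; with partial masking the patient-level
  rule would intentionally still count the patient as complete.

## Known limitations

* The inference rule set is a documented instantiation of a three-step
  framework, not a reconstruction of any proprietary rule set; real
  deployments should review and extend it per indication.
* R6 here means "still missing" only: ratchet conflicts are always corrected
  rather than treated as unresolvable inconsistencies.
* The other-cancer drug list and synonym tables are seeds; production use
  requires clinically validated versions.
* Coverage and representativeness are only as good as the national
  reference table supplied; reference-period mismatches between platform
  and national counts propagate directly into the ratios.
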