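---
title: "Rule-based structuring of narrative breast-pathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based structuring of narrative breast-pathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrex)
```

## The problem

Breast-cancer treatment decisions hinge on a handful of prognostic
parameters — oestrogen and progesterone receptor status (ER, PR), HER2,
the Ki67 proliferation index, Nottingham grade, histologic type,
laterality and age — but in many health systems these sit buried in
free-text, narrative pathology reports rather than synoptic checklists.
`pathrex` structures such reports with a deterministic, rule-based
cascade of regular-expression passes, derives molecular subtypes from the
receptor statuses, quantifies agreement with gold annotation, and runs
the downstream univariable association analysis. Because real report
corpora are protected health data, the package also ships a synthetic
generator that reproduces the reporting heterogeneity the extractor must
survive, with known ground truth.

## Retrieval and preprocessing

Cases enter the pipeline through their SNOMED morphology code. A code
such as `M-85203` splits into a four-digit morphology (`8520`) and a
final behaviour digit; behaviours 2 (in situ), 3 (malignant primary) and
6 (metastatic) define the malignancy class retained for analysis.
Missing codes are excluded with reason `no_code` and malformed codes
with `bad_code` — flagged, never silently dropped — so the kept and
excluded sets always partition the corpus. Codes longer than five digits
are tolerated (first four digits as morphology, last digit as behaviour)
with a warning, since registry exports occasionally pad codes.

`clean_text()` collapses whitespace and removes asterisks, colons and
parentheses — the characters decorating scores in narrative reports —
while preserving every digit, `%`, `/`, `-`, `+` and `.`, the characters
values are made of. Parenthesised *content* is kept; only the bracket
characters go. Case is untouched (all downstream matching is
case-insensitive), so excerpts in error listings remain readable. The
function is idempotent, which the suite property-tests on random
strings.

## The extraction cascade

Extraction for each parameter runs up to four canonical passes:

1. **Summarise** (`summarize()`): every occurrence of a keyword variant —
   e.g. the twelve observed HER2 spellings from `HER2NUE` to
   `C-erb2/HER2` — yields a mention with a window of 60 characters each
   side. Matching is case-insensitive with word boundaries (no
   alphanumeric flanking), so `ER` never fires inside "receptor"; at a
   shared start offset the longest variant wins, and a match contained
   in a longer one is dropped.
2. **Narrow** (`narrow()`): the window shrinks to a fixed number of
   characters *after* the keyword end — 17 for Ki67 — because values
   follow parameter names in narrative reporting. The direction is a
   design choice: every worked example we model has the value trailing
   the name, so a trailing window maximises signal per character.
3. **Numeric capture** (`capture_numeric()`): the first digit run of
   length 1–4 in the narrowed window, optionally followed by `%`, or an
   `x/y` fraction (Allred `8/8`, Nottingham `5/9`). Runs longer than
   four digits are skipped as non-values (accession numbers). "0–4
   digits" is read as runs of length one to four; a zero-length match is
   vacuous.
4. **Categorical capture** (`capture_categorical()`): where the
   pathologist pre-categorised ("positive", "negative", "low", "high"),
   the earliest lexicon token wins. A minimal negation rule turns
   "positive" preceded within three tokens by "not"/"no" into negative;
   this is an extension beyond plain token capture, on by default and
   configurable.

`synthesize()` combines per-mention captures with numeric-before-
categorical precedence (value capture is attempted before the
pre-categorised fallback). When a parameter is mentioned more than once,
the numeric candidate nearest the start of the report wins — the first
clinical statement — with the others retained in provenance; conflicting
categorical captures yield status `ambiguous` rather than a guess. Age
and race prefer the structured sidecar fields when present and fall back
to text capture, so both paths exist and can be validated against each
other.

Rule sets are declarative (`parameter_rules()`), ship with defaults for
all nine parameters (`default_rulesets()`), and round-trip through YAML
so site-specific spellings — including common misspellings added as
literal variants after error review — can be maintained without touching
code. There is deliberately no fuzzy matching by default: fuzzy rules
trade silent false positives for recall, and the recoding workflow
(inspect failures, add variants) keeps the cascade auditable.

## Harmonisation and subtyping

Raw captures are normalised by IHC convention: Allred fractions `x/8`
are positive at x ≥ 3 and percentages at ≥ 1% (both cutoffs
configurable); HER2 IHC 0/1 is negative, 3 positive, and the equivocal
2+ maps to missing — the data model is strictly binary with no reflex
FISH available; Nottingham sums map 3–5/6–7/8–9 to grades I/II/III; Ki67
dichotomises at 14% (< 14 low, ≥ 14 high). Subtype derivation follows
the four-class receptor scheme: ER+ cases are Luminal A (HER2−) or
Luminal B (HER2+) regardless of PR; ER−/PR− cases are HER2-overexpressing
(HER2+) or triple negative (HER2−). ER−/PR+ falls outside the scheme and
is flagged unclassifiable rather than forced into a class; any missing
input yields a missing subtype.

Eligibility is applied in a fixed order — empty report, male case,
duplicate episode, missing subtype — with every exclusion logged and
counts conserved. Duplicate episodes keep the copy with the most
non-missing parameters (ties favour the earlier report) after a
field-wise merge preferring non-missing values, so a duplicate pair
carrying disparate information repairs its counterpart's gaps.

## The synthetic corpus

The generator draws patients i.i.d. from configurable marginals whose
defaults are presets shaped like a South African national-laboratory
case mix: subtype weights ≈ 52/16/9/22%, a high-Ki67 fraction of 0.74
among non-missing values, race missing ≈ 42%, grade missing ≈ 30%.
ER/PR/HER2 are drawn jointly through the subtype so receptor
combinations remain coherent; Allred scores and Ki67 percentages are
then drawn consistently with the drawn status. Noise is explicit and
separately dialable: per-parameter mention dropout, single-character
typos restricted to parameter-name tokens (spelling errors affect names,
not values), duplicate episodes, conflicting duplicates (default ≈ 0.2%
of patients: one optional field blanked in the first copy, intact in the
second), empty reports and male cases.

Rendering emits exactly one mention per non-missing parameter, each as a
name variant plus a value in one of the observed styles (Allred
fraction, percentage, bare IHC digit, pre-categorised label, Nottingham
fraction or Roman numeral), interleaved with clutter boilerplate. The
clutter pool is digit-free and avoids every keyword and lexicon token,
for two reasons: it makes the exactly-one-mention invariant checkable by
direct string search, and it guarantees that a narrowed window spilling
past a short mention ("HER2 negative.") lands in inert text rather than
in a neighbouring value. What the generator does *not* emulate: OCR
noise, multi-specimen reports, free-form sentence structure around
values (values always trail names), negated findings, or
institution-specific templates. Perfect recovery on this corpus
therefore demonstrates the cascade's mechanics — windowing, capture,
precedence, harmonisation — not performance on arbitrary real-world
text, where variant lists must be curated per site.

## Validation metrics

Agreement between machine and gold annotation uses Cohen's kappa
(κ = (P0 − Pe)/(1 − Pe)), one-vs-rest precision/recall/F1 per category,
and, for age, the two-way mixed, absolute-agreement, average-measures
intraclass correlation ICC(A,k) = (MSB − MSE)/(MSB + (MSR − MSE)/n).
Multi-level parameters report per-category P/R/F1 plus one
multi-category kappa. Interval methods are stated because they are a
choice: Wilson score intervals for precision and recall, seeded
bootstrap percentile intervals (2000 resamples by default) for F1 and
kappa, and F-distribution bounds for the ICC (single-measures agreement
bounds mapped to average measures via Spearman–Brown). The test suite
checks every metric against an independent brute-force implementation —
direct counting loops for kappa and P/R/F1, `stats::aov` mean squares
for the ICC — on random inputs.

## Imputation and association

Missingness in the analysis table is handled by an iterative
random-forest scheme for mixed data: mean/mode initialisation, columns
visited in ascending missingness, each regressed on all others with a
100-tree forest (√p candidate features per split, seeded), iterating
until the between-iteration change statistic — normalised squared
difference for numeric, mismatch proportion for categorical — first
increases for every variable type present, then returning the previous
iteration. Out-of-bag error is reported as NRMSE (numeric) and PFC
(categorical). On planted MCAR holes in synthetic data the scheme beats
the mean/mode baselines, which is the package's calibration check.

Associations are univariable by design. The multinomial model with
Luminal A as the reference outcome factorises, for a single categorical
covariate, into separate binary logistic fits of each subtype against
the reference; `pathrex` fits each contrast by IRLS (tolerance 1e-8, at
most 100 iterations) and reports odds ratios with Wald 95% intervals
exp(β ± 1.96·SE). For one categorical covariate the fitted ORs equal the
contingency cross-product ratios — the identity the tests exploit as an
internal oracle on random tables. Zero cells make a contrast
non-estimable and are flagged, never reported as infinite. The bundled
published contingency counts (`subtype_assoc_counts()`,
`ki67_assoc_counts()`) let the layer be exercised against reported
cohort odds ratios; reproducing the printed HER2 interval (2.01–2.65)
from its counts confirms the Wald construction.

## Numerical and scale choices

Problem sizes in the tests and acceptance script are chosen for
desk-scale runtimes at stable statistics: 1000 reports for end-to-end
recovery, 10 000 draws for marginal-recovery checks (3 binomial standard
errors), 100 random inputs for metric-oracle equality, 50 random tables
for the cross-product identity, and ~500 patients with 20% MCAR holes
for the imputation calibration. All randomness is seed-controlled;
identical seeds give byte-identical corpora, extractions and
imputations.

## Known limitations

Fixed-direction narrowing misses the rare value-before-name phrasing;
negation handling is a three-token look-behind, not a scope parser;
HER2 2+ cases are lost to subtyping without FISH; ER−/PR+ cases are
excluded as unclassifiable rather than resolved; and the association
layer is univariable only — no adjustment, no survival outcomes.
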