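---
title: "Identifying hospitalizations of people who use drugs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying hospitalizations of people who use drugs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwudflag)
```

## The problem

Hospital encounters of people who use drugs (PWUD) are the natural unit
for tracking care quality in this population, but identifying them in the
EHR is hard: there is no ICD-10 code for injection drug use, surrogate
code lists have sensitivities reported anywhere between roughly 10 % and
65 %, and manual chart review does not scale. `pwudflag` implements a
rule-based text-mining pipeline that augments ICD-10 code flags with
lexicon matches in clinical notes, plus the statistics used to decide
whether the augmentation helps.

The pipeline is deliberately simple — regular-expression matching with
assertion rules, not a learned model — because simplicity is what makes
it cheap to run over an entire hospital's admissions and easy for a
clinical team to audit term by term.

## Matching and assertion

**Terms.** A lexicon holds patterns in three categories: actions
("injects drugs"), person descriptors ("intravenous drug user", "IVDU"),
and drug names ("heroin", "fentanyl"). Matching is case-insensitive and
word-boundary-anchored; internal whitespace in a pattern matches any run
of whitespace or hyphens, so "intravenous-drug user" is still found.
Offsets are 0-based, half-open, in Unicode code points. The shipped
`default_lexicon()` is a starting point seeded from the category
exemplars above; a production deployment should substitute the
institution's curated list (the term list is data, not algorithm).

**Negation.** A match is negated when a negation cue ("no", "denies",
"negative for", ...) ends within 30 characters before the match without
an intervening sentence boundary (`.`, `;`, `!`, `?`, newline). The
30-character window covers the common clinical constructions while the
sentence bound prevents a "no" in a previous clause from cancelling an
assertion it does not govern. Both the cue list and the window are
lexicon data; cues with `direction: after` are supported for
constructions like "IVDU: denied", though the default set is
preceding-only because following-position negation is rare and riskier.

**False triggers.** A lexically positive match can be clinically
irrelevant: "fentanyl gtt" documents a fentanyl infusion administered as
treatment, not drug use. False-trigger rules are term-specific adjacency
patterns — by default, administration vocabulary ("gtt", "drip", "patch",
"mcg", "infusion") within 15 characters after a drug-name term. A match
is a *true hit* iff it is neither negated nor a false trigger.

**History.** The ConText-style annotator (`system = "context"`, emulating
the outputs of heavyweight clinical-NLP toolkits: snippet, term, negation
flag, history flag) additionally marks matches in scope of a history cue
("history of", "prior", ...). Historical mentions still count as positive
by default — a documented history of drug use is evidence the encounter
belongs to a PWUD — with `count_historical = FALSE` available because the
opposite convention is also defensible.

**Snippets.** For human review, each match carries the matched span plus
100 characters of context on each side, truncated at note boundaries
without padding.

## From notes to encounter signals

For each encounter the per-note flags are reduced to: the count of linked
notes, the count with at least one true hit, their fraction, the `any`
flag, and inclusive threshold flags at fractions ≥ 0.10, 0.25, 0.50.
Inclusivity follows the "present in at least 10 % of notes" reading; it
also makes the 2-of-4 = 50 % boundary case positive. By construction the
flags nest (`ge50 ⇒ ge25 ⇒ ge10 ⇒ any`), which implies that raising the
threshold can only lower sensitivity and raise specificity downstream —
a property the test suite asserts on generated corpora.

Two deliberate choices here were genuinely open:

* **Denominator.** All notes linked to the admission count in the
  fraction's denominator, whatever their type; `note_types =` restricts
  both numerator and denominator to the three reviewed types (emergency,
  HPI, discharge) when a deployment only trusts those.
* **Zero-note encounters** are retained (they exist in admission tables)
  with fraction 0 and all text flags FALSE: an encounter without text
  cannot be text-identified.

ICD-10 flags are computed separately for the visit scope (the top 5 codes
attached to the encounter) and the history scope (all codes on the
patient's chart). Comparison is prefix-based on canonicalized codes
(upper case, dot stripped), because published substance-use code lists
are typically category-level ("F11" should match "F11.20"). The default
list covers F11–F16, F18, F19 and narcotic/psychostimulant poisoning
(T40.0–T40.6, T43.6).

## The classifier registry

`builtin_registry()` holds the 15 evaluated combinations: each signal
alone, OR/AND pairings of the ICD flag with each text flag, the three-way
combinations, and OR/AND variants at each threshold. Models are pure
boolean expressions over the signal vector, so two orderings hold by
construction and are asserted as tests: pointwise dominance
(`A∧B ⇒ A ⇒ A∨B`, hence sensitivity ordered one way and specificity the
other on any cohort), and, for NRI against the `icd_only` baseline,
OR-augmentation never reclassifies downward (`NRI_e ≥ 0`, `NRI_ne ≤ 0`)
while AND-restriction never reclassifies upward. The default ICD scope
for all models is `visit`, matching the baseline used in the NRI
comparisons; it is selectable per run.

## Evaluation statistics

Gold-standard adjudication: an encounter is positive when at least 2 of
the 3 reviewed chart types describe drug use; when two independent
reviewer labels disagree, a tiebreaker label decides (its absence is an
error, not a silent default).

From the confusion matrix the package reports sensitivity, specificity,
and per-class F1. The F1 for the non-drug-use class is defined as the F1
of the complement-labelled problem (treating TN as that class's true
positives). A zero-denominator F1 is reported as 0 by convention; an
undefined sensitivity or specificity (no events, or no nonevents) is an
error rather than a NaN.

The weighted net reclassification index is
`wNRI = ρ·NRI_e + (1 − ρ)·NRI_ne` with
`NRI_e = P(up|event) − P(down|event)` and
`NRI_ne = P(down|nonevent) − P(up|nonevent)`; `ρ` defaults to the
observed prevalence in the evaluated cohort and is overridable, since a
deployment may want the design prevalence instead. The identity is exact
by construction and asserted bitwise in the tests.

## McNemar test and power

`mcnemar_test()` counts discordant pairs and uses the exact two-sided
binomial p-value when `b + c < 25`, otherwise the asymptotic
`(b−c)²/(b+c)` chi-square without continuity correction; `b + c = 0`
yields statistic 0 and p = 1 by convention. Restricting to gold-positive
encounters turns it into a paired comparison of sensitivities.

`mcnemar_power()` implements the conditional normal-approximation power
formula with effective paired sample size `n_eff = round(n·ρ₀)` (the
comparison lives on the gold positives; rounding to the nearest integer
is documented rather than hidden). At the design point used throughout
the package's checks — n = 790, ρ₀ = 0.10, d = 0.15, ψ = 0.22,
α = 0.05 — it returns 0.824.

`simulate_mcnemar_power()` is the honest Monte-Carlo companion: it
simulates the discordant counts of the 79 effective pairs and applies the
package's own test rule to each replicate. Because the real test is
discrete, its simulated power at this small `n_eff` (≈ 0.80 with the
exact rule) sits slightly *below* the smooth normal-approximation value,
while an uncorrected asymptotic rule would land above it. Both the
analytic and the simulated value satisfy the ≥ 80 % power the design
aims for. We keep the exact rule as the default because it matches what
`mcnemar_test()` would actually do at these counts; the residual
analytic-vs-simulated gap is the approximation error of the closed-form
formula, not Monte-Carlo noise, and shrinks as the effective sample
grows.

## The synthetic-data generator

`generator_config()` defines the study conditions the package is
exercised under. Defaults are a stylized emulation of a chart-review
cohort: 790 encounters, PWUD prevalence 0.067, notes per encounter
Poisson(3) truncated below at 1 (medians of about 3 notes are typical;
the Poisson choice is a stand-in, as no distributional detail beyond the
median is available), note types mixed 20/25/20/35 across
emergency/HPI/discharge/other. Per-note event rates: a PWUD encounter's
note contains a true drug-use phrase with `p_mention = 0.30` — chosen so
the closed-form encounter-level sensitivity
`1 − E[(1−p)^K] ≈ 0.61` sits in the range reported for single-system
text search — and any note (either class) carries a negated phrase with
probability 0.10 and a false trigger with probability 0.05, reflecting
how often clinicians document denials and infusions. Visit ICD codes are
assigned at sensitivity 0.434 / specificity 0.995 (the accuracy regime
of code-only identification); history codes are a superset of visit
codes plus an extra code at rate 0.15 (a drug-use code for true PWUD,
a neutral chronic-disease code otherwise), so history flags fire at
least as often as visit flags.

Notes are composed of neutral filler sentences plus injected phrase
sentences; each injected phrase occupies its own sentence so events do
not interfere. The phrase bank is validated against the lexicon at build
time: positives must flag, negated templates must match-but-not-flag,
false-trigger templates must be excluded, fillers must not match at all.
A truth sidecar records every injection and code-assignment event; no
pipeline stage reads it (the pipeline consumes only the notes, codes and
labels tables).

**What the generator does not emulate.** All non-PWUD text is negated,
false-triggered, or neutral, so the matcher's specificity on synthetic
corpora is essentially 1 — unlike real notes, where counseling mentions,
family history and template text produce genuine false positives. The
generator also makes no attempt at realistic prose, temporal structure,
or correlated notes. Passing the parameter-recovery tests therefore shows
the pipeline is *internally correct* (it measures what the generator put
in), not that any particular operating point will transfer to real EHR
data; the threshold and combination *orderings*, by contrast, are
logical properties that transfer.

## Validation scale and numerical choices

Parameter recovery runs on a 5000-encounter corpus generated at
prevalence 0.5: a balanced validation corpus gives each arm about 2500
encounters, so the ±0.03 recovery tolerance sits at roughly three
binomial standard errors for every recovered quantity. The power
simulation uses 100 000 replicates (Monte-Carlo standard error about
0.0013). Dominance and identity properties are checked over 100+
randomized toy cohorts under fixed seeds. A single integer seed drives
every sampling step of the generator, so identical configurations
regenerate byte-identical corpora.

Other conventions, collected: thresholds are inclusive; effective paired
n rounds to nearest; report tables render at 3 decimals while machine
outputs keep full precision; tie-order of matches at the same offset
follows lexicon term order; unknown note types are coerced to `other`
with a warning and every silently-coerced record is warned about.

## Known limitations

Negation handling is window-based, not parse-based: long-range negation
("the patient has never, at any point, used heroin") and scoped
conjunctions will be missed. False-trigger rules are adjacency patterns;
a drug name and its administration context split across a line break
defeats them. The ConText-style annotator emulates the *outputs* of
UIMA-based clinical NLP toolkits, not their internals, so it should not
be cited as a reimplementation of any of them. Real-data operating
points (sensitivities near 0.74 / specificities near 0.87 for
threshold-OR models) cannot be reproduced from synthetic corpora and are
not claimed.
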