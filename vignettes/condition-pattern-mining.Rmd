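---
title: "Mining temporal condition patterns around incident pediatric obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining temporal condition patterns around incident pediatric obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condseq)
library(dplyr)
```

## The question and the design

When a child's BMI first crosses the obesity threshold (age- and
sex-standardized z-score at or above 1.6449, the 95th percentile), which
diagnoses tend to precede, accompany, or follow that moment? condseq
implements a matched case-control design over longitudinal EHR-style
visit data that answers this with frequent-sequence mining rather than a
prespecified hypothesis:

1. **Index-visit phenotyping.** Each case's *index visit* is the first
   visit with a plausible obese BMI z-score at a face-to-face encounter,
   at age 2-18 years, carrying at least one clinical finding. The nearest
   condition-bearing visits before and after become the *pre-index* and
   *post-index* visits. The three visits define timing classes 1, 2 and 3,
   and every diagnosis is reduced to a class-tagged condition-group item
   such as `1-Asthma`.
2. **Matched controls.** Each case is paired with one control patient who
   only ever had healthy BMI measurements (5th-84th percentile band),
   matched on sex, prior healthcare utilization (visits with a clinical
   finding) and age within a 60-day caliper, youngest cases first, without
   replacement.
3. **SPADE mining.** Frequent class-tagged condition sequences are mined
   from the case population at a relative support floor of 0.01.
4. **Matched-pair testing.** Each retained pattern's prevalence is
   compared across pairs with McNemar's test; the effect size is the odds
   ratio among discordant pairs, reported in the enriched direction.

Every stage takes and returns plain tibbles, so the pipeline can be run
end to end with `run_pipeline()` or stage by stage.

## The miner

SPADE operates on a vertical database: each item (a class-tagged condition
group) owns an id-list of (sequence id, event id) occurrences, with the
event id being the timing class. Frequent 1-patterns seed a depth-first
search in which a pattern is extended only by items later in the canonical
order (timing class, then byte-wise condition name). An extension with the
same timing class is an itemset join (same event id); a later class is a
sequence join (later event id). Because each timing class occurs at most
once per subject, both joins reduce to intersections of sorted sequence-id
sets, which keeps the miner exact and fast: tens of thousands of sparse
sequences mine in about a second at the 0.01 floor.

Two laws follow from counting and are enforced by tests on every fuzzed
instance: a superpattern never exceeds any subpattern's support
(anti-monotonicity), and every subpattern of a frequent pattern is itself
frequent (apriori consistency). A separate brute-force oracle — full
enumeration of class-tagged patterns up to length four with a
presence-matrix subset test — must agree exactly with the miner on pattern
sets, counts, and supports.

Subjects lacking a post-index visit stay in the support denominator and
simply cannot exhibit class-3 patterns. This mirrors how the design treats
missing follow-up as "pattern absent", and it matters for interpretation:
if controls have post-index visits more often than cases, class-3 patterns
tilt toward controls for structural rather than clinical reasons.

## The test and its conventions

For a pattern with matched-pair cells (n11, n10, n01, n00), the default
test statistic is the uncorrected McNemar chi-square
\((n_{10}-n_{01})^2/(n_{10}+n_{01})\) on one degree of freedom. The
continuity-corrected variant and the exact binomial test are available via
`method=`; the uncorrected form is the default because the conventional
reporting of borderline matched-pair tables (for example 695 vs 623
discordant pairs, p ≈ 0.047) grades as significant only without the
correction, and the corrected variant would contradict that convention at
the 0.05 boundary. With no discordant pairs the statistic is 0 and p = 1.

The effect size is `max(n10, n01) / min(n10, n01)` with an explicit
`direction` field, so a control-enriched pattern with cells 569/2251
reports 3.96 toward controls rather than 0.25. One empty discordant cell
yields an infinite ratio; two empty cells yield `NA` with direction
`none`. Raw p-values are reported by default (the design screens
hypotheses rather than confirms them); Benjamini-Hochberg adjustment is
available through `p_adjust = "BH"`.

Significance stars follow the usual ladder: `*` p < 0.05, `**` p ≤ 0.01,
`***` p ≤ 0.001, `****` p ≤ 0.0001.

## What the generator emulates

`simulate_ehr()` produces the four relational tables of a minimal
longitudinal EHR with known ground truth:

- **Visit streams.** Documented visits per patient are 2 plus a negative
  binomial draw (default mean 6, dispersion 1.2), giving the overdispersed
  utilization that matching must cope with; inter-visit gaps are gamma
  (mean ≈ 120 days), consistent with median pre-index spacings of a few
  months in pediatric primary care.
- **BMI trajectories as z-scores.** Cases follow a random walk with upward
  drift that first reaches 1.6449 at a face-to-face visit preceded by at
  least one earlier visit; non-cases fluctuate inside the healthy band,
  with a configurable fraction receiving one overweight value so the
  control-pool screen has work to do. Simulating z-scores directly (rather
  than heights and weights through growth-chart LMS tables) matches what
  the analysis consumes: percentile classifications.
- **Diagnoses.** Per-visit condition presence is Bernoulli at catalog
  baseline prevalences. A planted effect multiplies the presence *odds*
  for eventual cases at the visit occupying its timing class (the visits
  flanking the threshold crossing). Defaults mirror the headline
  associations of pediatric obesity incidence: asthma (OR 1.31 pre-index,
  1.73 at index), allergic rhinitis (1.51 at index) and sleep apnea (2.80,
  2.37, 2.33 across the three classes). A fraction (default 14.3%) of
  case index visits also carries a formal obesity code, reflecting how
  rarely incident obesity is formally diagnosed.
- **Coding completeness.** "Preventive care" is present at every visit by
  default. The analysis design only admits visits carrying at least one
  clinical finding, so fully coded visits make the planted odds ratio
  coincide exactly with the discordant-pair odds ratio the pipeline
  estimates; lowering the prevalence below 1 deliberately creates
  partially coded visits and exercises the exclusion and pair-rejection
  paths, at the cost of a small, quantifiable attenuation of planted
  effects (the index visit can shift off the planted visit, and
  conditioning on "at least one finding" scales the two arms' prevalences
  unequally).
- **Optional knobs.** `code_fanout` emits granular codes that must be
  grouped through a mapping table; `pair_dependence` couples the first two
  catalog conditions to emulate comorbidity (asthma-rhinitis style);
  both default off, and conditions are otherwise independent given
  case status — real comorbidity structure is richer than this.

What passing tests on this generator do **not** show: robustness to coding
drift across calendar time, informative missingness of BMI measurements,
care-setting-specific coding styles, or realistic ICD code frequency
distributions. The generator is a harness for the pipeline's logic and
statistical calibration, not a clinical simulacrum.

## Numerical and procedural choices

- **Plausibility screen.** A configurable z-score band, default [−5, 8],
  stands in for registry-specific implausibility rules; cleaning keeps
  one BMI value per patient-date, resolving same-date conflicts to the
  most recently recorded row.
- **Index selection.** The index is the first visit satisfying the *full*
  predicate, so an obese measurement at age 1.5 years does not disqualify
  a patient whose first qualifying visit comes at age 3; same-day ties go
  to the lower visit id, everywhere.
- **Prior-visit rule.** The default requires a prior visit without an
  obese BMI record (a visit with no BMI at all qualifies); a stricter
  switch, `prior_visit_rule = "recorded_non_obese"`, demands an actually
  recorded non-obese value. The weaker reading is the default because a
  third or more of real incident-obesity cases have no earlier BMI in the
  record at all, and the stricter rule would silently drop them.
- **Calendar windows.** Index and flank windows are unbounded by default:
  simulated data carry no meaningful calendar. When analyzing real
  extracts the windows accept visit ordinals (e.g. days since an epoch).
- **Matching distance.** `|age diff|/caliper + |prior-visit diff|/(1 +
  prior-visit spread)`, ties broken by smaller age difference, then lower
  control patient id, then visit id. The reference tooling for this kind
  of matching does not document its metric; a transparent normalized sum
  with deterministic tie-breaks makes pairings reproducible, at the price
  that individual pairings (not population-level statistics) may differ
  from other implementations. Unmatched cases are reported, never
  silently dropped.
- **Exclusion policy.** Patterns containing obesity groups (informative
  only for cases by construction) or non-informative groups
  (administrative, preventive, nonspecific) are removed before testing,
  by group name across all timing classes.
- **Unmapped codes** route to a counted sidecar with a warning rather
  than vanishing.

## Problem sizes in the test suite

The suite validates the miner against its brute-force oracle on 200+
random instances of up to 50 sequences over up to 8 condition groups;
checks null calibration of the McNemar machinery on 200 replicates of
10,000 matched pairs (rejection rate at alpha 0.05 within [0.03, 0.07]);
and recovers a planted index-visit odds ratio of 2.5 through the complete
simulate-phenotype-match-mine-test pipeline on 50 replicates of 20,000
patients, requiring 95% Wald intervals on the discordant ratio to cover
the truth in at least 90% of replicates and the pattern to land in the
significant-case partition. Matching guarantees (exact sex, 60-day
caliper, control uniqueness, median age gap of zero days) are asserted on
a 10,000-patient run.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(
  sim = sim_config(n_patients = 20000,
                   planted_effects = tibble::tibble(
                     condition = "Asthma", timing_class = 2L,
                     odds_ratio = 2.5)),
  seed = 1)
run <- run_pipeline(cfg)
run
run$tests %>% filter(pattern == "2-Asthma")
autoplot(run$tests)
```

## Limitations

Associations surfaced by this design are descriptive; matching on sex,
age and utilization does not license causal claims. Sequences are limited
to three fixed timing classes around the index event (the miner itself is
general over event ids, but the cohort construction is not). Effect sizes
are discordant-pair ratios without confidence intervals in the standard
output (the Wald interval is one line of arithmetic from the reported
cells). The shipped condition mapping is a small synthetic demonstration
table; real deployments should supply their own grouper in the same
two-column shape.
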