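---
title: "Modelling post-polypectomy follow-up strategies for low-risk adenomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-polypectomy follow-up strategies for low-risk adenomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lrasim` compares two follow-up policies for people who have 1–2 low-risk
adenomas (LRAs) removed at colonoscopy within a FIT-based colorectal cancer
screening program: a surveillance colonoscopy 5 years after polypectomy
(status quo), or return to routine FIT screening 5 years after polypectomy
(new strategy). This vignette is the package's account of the model, its
assumptions, the choices made where the design was genuinely open, and what
the test suite does and does not establish.

## The simulated world

Time advances in discrete one-year cycles. Within a year, events happen in a
fixed order: (1) natural-history update, (2) scheduled follow-up events,
(3) routine screening, (4) non-CRC mortality and entry of newly eligible
50-year-olds. Annual cycling is the coarsest granularity consistent with
reporting annual outcomes; the fixed order makes runs reproducible and gives
the compliance rule ("every positive FIT is followed by a colonoscopy in the
same year") a precise meaning.

**Demography.** The cohort starts as `round(total_eligible_population ×
scale_factor)` persons aged 50–74, ages drawn from a configurable
distribution (default: mildly declining with age). Each subsequent year a
configurable fraction of the initial cohort (default 0.045) enters at age
50, approximately offsetting ageing out of the 50–74 band, so the eligible
population stays near its initial size across the horizon. Non-CRC mortality
follows a Gompertz-shaped synthetic life table,
`q(a) = min(1, 0.004 e^{0.085 (a - 50)})` over ages 50–110 (about 0.4% at
50, 3.1% at 74), replaceable by any per-age table. People stop routine FIT
at 75 but remain simulated — with scheduled surveillance still honoured —
until death. Migration and sex structure are deliberately absent: the
outcomes of interest are not reported by sex, and a stationary synthetic
population is the point of the generator.

**Natural history.** Each person carries a set of adenomas in three size
classes (0–5, 6–9, ≥ 10 mm). Annually, an adenoma grows one class, reverts
to normal mucosa, progresses to preclinical cancer, or stays; one class per
year is the simplest dynamic consistent with "adenomas grow in size".
Progression probabilities are strictly positive in every class and ordered
(≥ 10 > 6–9 ≥ 0–5), encoding the assumption that *all* adenomas carry some
malignant potential. New adenomas arise at most one per person-year at rate
`0.045 e^{0.035 (age - 50)}`; 8% are villous and 4% of sub-10 mm adenomas
carry dysplasia, fixed at onset (histology does not mutate in the model, and
reverted adenomas may be replaced by new onsets in later years). Preclinical
cancer persists for a geometric sojourn (mean 4 years, support ≥ 1 year) and
then presents symptomatically; a geometric law was chosen because the annual
cycle makes a memoryless dwell time the natural default and nothing in the
modelled setting pins down a shape. Clinical cancer carries an annual CRC
death probability of 0.06. Cancer is reduced to the two phases
preclinical/clinical with a single death hazard and a flat annual management
cost: no stage-specific outputs are produced, so stage structure would add
parameters without adding observable behaviour.

**Screening.** 42% of the population are lifetime screening participants
(the alternative reading — 42% attendance per round — is available as
`participation_mode = "per_round"`); participants split 50/50 between annual
and biennial screening, with biennial screening years staggered uniformly so
rounds do not synchronise. FIT positivity is keyed to the person's most
advanced lesion; the 75 ng/mL preset uses sensitivities 0.07 / 0.18 / 0.50 /
0.85 for 0–5 mm / 6–9 mm / ≥ 10 mm / preclinical CRC and a false-positive
rate of 0.075. The large-adenoma and CRC values sit in the range systematic
reviews report for quantitative FIT; the sub-10 mm values and the
false-positive rate are synthetic stand-ins calibrated (below). The
100 ng/mL preset lowers the sub-10 mm sensitivities and the false-positive
rate, mirroring how a stricter threshold mainly costs sensitivity for small
lesions. A configurable 1.35%/year of the eligible population receives a
primary screening colonoscopy without FIT (e.g. significant family history).

**Colonoscopy pathways.** Each adenoma is independently detected with
per-size-class sensitivity (defaults 0.85 / 0.95 / 1.0 — small lesions are
the ones endoscopists miss); detected adenomas are removed, making the
procedure operative. Findings are classified: `cancer` overrides everything;
any villous adenoma, any tubular adenoma ≥ 10 mm, or more than 2 LRAs is
`high_risk`; 1–2 removed adenomas that are all tubular, sub-10 mm and
non-dysplastic are `lra_1_2`; nothing removed is `normal`. One boundary case
is not covered by the literal high-risk triad: a sub-10 mm *dysplastic*
tubular adenoma is by definition not an LRA, and the package classifies it
`high_risk`, as advanced histology is managed intensively in practice.
Follow-up: normal → FIT in 10 years; `lra_1_2` → per strategy, with the
new-strategy rule gated on the index colonoscopy year being ≥ 2023 (earlier
index procedures follow the status quo); `high_risk` → colonoscopy at 3
years then 5 years — a normal finding at the 3-year check still receives the
second 5-year colonoscopy, a repeat high-risk finding restarts the 3-year
interval, and an `lra_1_2` finding at any surveillance colonoscopy is
re-classified under the active strategy (the rules are applied recursively;
nothing in the modelled policies forbids it). Diagnosed cancer triggers
annual surveillance colonoscopy for 5 years — a configurable stub whose
volume, not rule, is reported. Complications are sampled independently per
procedure (defaults 0.3 and 1.7 per 1000; procedural mortality 0).

**Costs.** Undiscounted 2021 CAD throughout. Per FIT screen: \$26.13 kit +
\$38.03 result-discussion visit. Colonoscopy: \$866.43 diagnostic /
\$1036.43 operative, plus \$3864.74 per major bleed and \$37,779.83 per
perforation. The \$146.03 positive-test consultation is attached to the
colonoscopy that follows a positive FIT and sits in the screening group;
surveillance colonoscopies have no preceding FIT, so they carry no
consultation fee. Costs aggregate into three groups — screening (all FIT
costs, consults, screening and post-FIT colonoscopies), clinical diagnosis
(symptomatic and post-adenoma surveillance colonoscopies), cancer management
(post-cancer surveillance plus a flat \$12,000 annual management cost per
person in the first five years after diagnosis). The management cost is a
synthetic stand-in so the three-group report is complete; its absolute level
is not derived from a fee schedule and group totals should be read
relatively, not absolutely.

## Calibration of the synthetic defaults

The defaults were tuned once, before any comparison was run, to two study
conditions: (a) about 26 of every 100 colonoscopies following a positive FIT
find 1–2 LRAs, and (b) full-scale annual CRC cases of the order of a
provincial screening-eligible population (a few thousand per year). At a
100,000-person desk scale the frozen defaults give an LRA yield of ~26 per
100 FIT-positive colonoscopies, ~8.7% FIT positivity, and full-scale
equivalents of roughly 2650 CRC cases and 850 CRC deaths per year; the test
suite re-verifies the yield condition (within 23–29 per 100) on every run of
the desk-scale comparison. No attempt is made to reproduce absolute
published volumes or costs — those depend on a proprietary registry
calibration that is out of scope — so the package's comparisons are
*directional and structural*: category partitions, cost-group additivity,
the sign and timing of incremental outcomes.

## The experiment design

`run_replicates()` builds a fresh cohort per replicate and runs both
strategies on it from a 2008 burn-in (so screening histories, surveillance
queues and the adenoma pool are in quasi-steady state by 2023) through 2042.
Outcomes are averaged over the 20 horizon years per run; incremental
outcomes are the per-replicate differences, summarised by their mean and a
two-sided 95% Student-t interval (`qt(0.975, n - 1)`), with a degenerate
`(mean, mean)` interval when the differences have zero variance. Derived
complication increments multiply the incremental colonoscopy count by the
per-1000 rates and are displayed rounded to integers. Common random numbers
are the default: both arms of a replicate start from the same seed, so their
event streams are draw-for-draw identical until the first behavioural
divergence. With a 2023 policy start and a 5-year LRA interval that
divergence occurs in 2028, which is why the per-year incremental colonoscopy
series is *exactly* zero for 2023–2027 and strictly negative afterwards —
the model's realisation of savings beginning five years after the switch. An
independent-streams mode reproduces the noisier unpaired design.

Display conventions: counts round to integers, costs to the dollar,
percentages to one decimal; internal arithmetic is double precision and the
ledger identity `total = screening + clinical_diagnosis + cancer_management`
holds exactly.

## What the tests establish — and what they do not

The suite verifies the transition law against exact multinomial
probabilities at 10⁵ adenoma-steps, binomial recovery of mortality,
participation, FIT-sensitivity and complication rates, conservation and
seed-determinism of the population, the full classification/scheduling rule
table including the policy gate, cost-ledger additivity against brute-force
per-event summation, t-interval coverage on known normal draws, exact null
equivalence of the two strategies when LRA findings are made impossible
(every adenoma villous), and the desk-scale directional comparison (50,000
persons, 12 replicates: fewer surveillance colonoscopies, more FIT screens,
lower total cost, 5-year lag). Problem sizes were chosen so the whole suite
runs in minutes on one CPU: 10⁵ draws for rate recovery, 1500–5000 persons
for behavioural properties, 50,000 × 12 for the comparison.

Passing these tests shows the machinery is faithful to its own rules and
calibrated conditions. It does not show that real post-polypectomy cohorts
behave this way: the generator omits serrated-pathway lesions, anatomical
site, stage-shift survival, migration, screening no-shows and lab
variability, fixes histology at onset, and uses synthetic FIT sensitivities
for small lesions. Conclusions about magnitudes in a real program require a
registry-calibrated model; what this package offers is a transparent,
fully-testable reimplementation of the comparison's structure.

## Known limitations

* Absolute outcome levels (volumes, costs) are not calibrated to any
  registry; only their structure and direction are meaningful.
* One adenoma onset per person-year caps lesion multiplicity; with the
  default onset rates multi-adenoma carriage arises over time, but extreme
  polyp burdens are under-represented.
* The cancer-management cost is a flat stand-in confined to a five-year
  window; real management costs are stage- and phase-dependent.
* The high-risk 3-then-5-year sequence repeats its 3-year interval on
  repeated high-risk findings indefinitely; guidelines vary here and the
  intervals are configurable but the repetition rule is fixed.
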