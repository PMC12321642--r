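---
title: "Methods: NAT scoring, BAL concordance and de-escalation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NAT scoring, BAL concordance and de-escalation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balsteward)
```

## The measurement problem

Critically ill patients with suspected pneumonia are started on broad
empiric antibiotics, and the decision to narrow therapy hinges on the
results of the episode-defining BAL: a multiplex PCR panel that returns
within hours, and quantitative cultures that finalize over days. This
package quantifies that narrowing day by day with the Narrow Antibiotic
Therapy (NAT) score, classifies how PCR and culture agree, and compares
outcomes across episode etiologies. Everything operates on four plain
tabular inputs (patient-day regimens, adjudicated episodes, paired BAL
results, patient outcomes), so the same pipeline runs on a real extract or
on the package's own synthetic cohorts.

## The NAT scale and its tier logic

The scale is anchored at five interpretable levels: −2 no antibiotics,
−1 narrow monotherapy, 0 empiric CAP coverage (the ceftriaxone +
azithromycin backbone), 1 targeted broad coverage, 2 empiric HAP/VAP
coverage, escalating to +4. Only those anchors are defined textually in the
stewardship literature the scale comes from; the complete regimen-to-score
table is institution-specific. `score_day()` therefore implements a
*rule-based tier system* over agent spectrum classes, with the shipped
default formulary reproducing the five anchors exactly and every parameter
(formulary, cap) externally configurable.

The broad-tier arithmetic is: base 1 for any broad coverage, base 2 when
gram-negative antipseudomonal coverage is combined with an anti-MRSA agent,
plus 1 when a carbapenem/MDR-active agent accompanies other broad coverage,
plus 1 per gram-negative agent beyond the first, capped at +4. This exact
formulation was chosen to satisfy two structural requirements
simultaneously, which the test suite enforces as properties:

* **Monotonicity** — adding an agent can never lower the score. This is why
  a second narrow agent scores 0 rather than −1 (−1 is reserved for strict
  narrow *monotherapy*), and why broad-tier scores are computed from
  coverage indicators rather than agent counts alone.
* **Single-agent range** — no single agent reaches empiric HAP/VAP breadth,
  so every monotherapy scores in {−1, 0, 1}. A carbapenem alone is targeted
  broad coverage (1); the carbapenem escalation point applies only when it
  rides on top of other broad coverage.

Two further choices: ceftriaxone or azithromycin *alone* score 0, not −1,
because they are the CAP guideline backbone rather than narrow agents; and
antivirals/antifungals are outside the formulary entirely — the score
measures antibacterial spectrum, and a viral pneumonia patient on
remdesivir alone is genuinely at NAT −2. Unknown agents raise an error
instead of defaulting to narrow, since silent misclassification would bias
every trajectory downward.

## Trajectories, de-escalation and cessation

Trajectories re-index daily scores to the BAL day (day 0) over a −2…+7
window, keep in-hospital alive days only, and impute −2 for in-window
hospital days with no administration rows (an absent row *is* the
observation "no antibiotics"). The average NAT covers post-BAL days 1–7
truncated at death/discharge; day 0 and pre-BAL days never contribute.
Per-day summaries report median and quartiles with the linear-interpolation
convention (`quantile` type 7), cross-checked in the tests against a
hand-rolled sort-based oracle.

Two event definitions required interpretation, and the package fixes them
as follows:

* **De-escalation by day k**: the running minimum of post-BAL scores over
  days 1..k falls *strictly below the day-0 score*. Comparing to day 0
  (not the pre-BAL maximum) is the minimal reading of "de-escalation on
  day 1"; strictness makes flat trajectories non-events. The definition is
  monotone in k by construction.
* **Cessation by day k**: the score reaches −2 on some day in 1..k *and
  remains −2 through day k* — equivalently, the day-k score is −2. A
  transient antibiotic-free day followed by resumption is not cessation;
  we read "cessation by day 5" as a state at day 5, not a transient.

Timeline analyses (share de-escalated by day 1, by day 4) are restricted to
episodes lasting at least four days post-BAL; `deescalated_by()` refuses
trajectories that do not cover the required days rather than guessing.
Patients with several adjudicated episodes keep one window per episode;
windows may overlap, and only outcome analysis requires the
exactly-one-episode restriction.

## Resistance and concordance

An episode is resistant if any PCR resistance gene (mecA/C, MREJ, CTX-M,
KPC, NDM, IMP, VIM, OXA-48-like) or any resistant culture phenotype (MRSA,
ESBL, CRE, other) is present — a logical OR, monotone in added markers.

Concordance compares the culture item set (significant organisms plus
phenotypes) with the PCR item set (detected organisms plus genes mapped to
phenotype equivalents). Parameters a user may want to change:

* **Significance threshold** — culture growth below 10⁴ CFU/mL (a
  conventional BAL cutoff) is excluded; unquantified growth counts as
  significant. Configurable per call.
* **Gene-phenotype equivalence** — mecA/C or MREJ on a staphylococcal
  target ≡ MRSA; CTX-M ≡ ESBL; any carbapenemase ≡ CRE. Without such a
  mapping "agreement in organisms and resistance" is undefined.
* **Panel definition** — the shipped default lists the published bacterial
  targets of the commercial multiplex pneumonia panel (editable JSON);
  off-panel logic needs an explicit target list.
* **Candida albicans** is excluded from concordance sets as not clinically
  significant in BAL.

Two deliberate readings of underspecified corners: gene positivity counts
toward the PCR side even when the organism call is negative, and a
culture-only discrepancy is flagged off-panel only when at least one
*organism* (not merely a resistance marker) outside the panel drives it.
The classifier demands `pcr_performed = TRUE` — concordance over unpaired
samples would be meaningless — and the four categories are mutually
exclusive and exhaustive by construction (culture-only and PCR-only require
the other side's difference to be empty; both non-empty is discordant).

## Statistics

The comparison statistics are implemented in the package rather than
wrapped, because their exact conventions are part of what the pipeline
asserts; `stats::fisher.test`, `stats::wilcox.test` and independently coded
enumeration oracles appear in the tests as cross-checks only.

* **Sample odds ratio** `(a·d)/(b·c)` — the cross-product form, which is
  what reproduces the published outcome-table values from their counts (the
  conditional-MLE variant from Fisher's test does not). Any zero cell
  triggers the Haldane–Anscombe +0.5 correction with a `corrected` flag.
* **Fisher's exact test** — two-sided p by summing `dhyper` probabilities
  of all tables with the observed margins whose probability does not exceed
  the observed one, with a 1e−7 *relative* tolerance so that
  floating-point noise cannot drop a genuinely tied table from the sum.
  Degenerate margins return p = 1 with a flag. The suite verifies equality
  with an lchoose-based enumeration for every table with total ≤ 30
  (46,376 tables).
* **Mann–Whitney U** — U from midranks; exact two-sided p from the null
  distribution of U counted by the lattice recursion
  N(m, n, u) = N(m−1, n, u−n) + N(m, n−1, u) whenever the samples are
  tie-free and m·n ≤ 400 (beyond that the count table grows needlessly —
  the normal approximation is already accurate well below it); otherwise a
  tie-corrected normal approximation with 0.5 continuity correction.
  `U_x + U_y = m·n` always. No multiple-testing correction is applied
  anywhere; all p-values are reported raw, matching how such outcome tables
  are conventionally presented, and the manifest says so implicitly by
  carrying the raw values only.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions the pipeline
targets: the five-etiology mix at proportions 288/176/198/151/114, a
resistant fraction of 104/486 among bacteria-containing episodes, day-0 NAT
distributions centred at 2 (bacterial, microbiology-negative, control) or 1
(viral, mixed), a viral cessation probability of 0.44 by post-BAL day 5,
per-group unfavorable-outcome rates around 0.41–0.46, concordance weights
390/158/61/26 with 139/158 of culture-only discrepancies off-panel, a
paired-testing rate of 635/657, and log-normal ICU durations with median
12 days. Where the generative mechanism itself had to be invented, the
simplest model reproducing the described patterns was used and frozen:

* Post-BAL dynamics: episodes flagged for cessation (per-group probability)
  step down one NAT level per day until −2 and stay; all others drop one
  level per day with a per-group hazard, floored at −1 so that the
  cessation probability remains identifiable. Resistant-bacterial episodes
  get a near-zero hazard — they are the one group that does not de-escalate.
  The susceptible-bacterial and microbiology-negative hazards (0.129,
  0.149) and cessation probabilities (0.239, 0.188) are the values implied
  by inverting day-1 ≈ 34%/31% and day-4 ≈ 56%/57% de-escalation
  proportions under this model.
* End of stay is geometric, calibrated so 15% of windows truncate before
  day +7, exercising the truncation logic; only a patient's last episode
  can end the stay.
* Regimens are emitted as the representative agent set for each score
  (e.g. 2 → cefepime + vancomycin), so scoring the generated table
  round-trips to the generated trajectory exactly.
* One root seed; episodes, trajectories, microbiology and outcomes each
  draw from a stream derived from it by a fixed offset, so enlarging one
  component does not perturb the others.

What the generator does **not** emulate: within-day dose timing,
antibiotic-specific substitution patterns (a score level always maps to the
same representative regimen), correlation between trajectory truncation and
the outcome table's durations, SARS-CoV-2 wave structure, comorbidity, or
adjudication noise. Passing tests therefore demonstrate that the pipeline
recovers known parameters from data *of this structure* — not that the
clinical findings themselves generalize.

Exact-count fixtures (`make_fixture()`) are constructed, never sampled:
the 657-BAL concordance set (390/139+19/61/26 with 22 unpaired), the
205- and 136-episode de-escalation timelines (69→115 and 42→78
de-escalators), and the 534-patient outcome table with its published group
sizes and unfavorable counts.

## Problem sizes and numerical conventions in the tests

The suite runs the statistics oracles at full enumeration scale (all 2×2
tables with total ≤ 30; permutation enumeration up to 6+6), parameter
recovery on cohorts of 1,650–9,500 patients (pooling a 10-seed grid for
the de-escalation hazard, and sizing the cessation check so about 2,000
viral episodes contribute), and everything else on cohorts of 60–300
patients. Dates are ISO-8601 calendar days throughout; relative-day
arithmetic is pure date difference with no time-of-day.

## Known limitations

* The regimen→score table beyond the five anchors is a package default, not
  a published standard; institutions should review the formulary CSV before
  interpreting absolute scores above 1.
* Concordance treats organism identity as exact string equality on
  canonical lowercase names; synonym resolution is the caller's job.
* The generator's independence assumptions (outcome rate independent of
  trajectory, truncation independent of dynamics) make it unsuitable for
  studying effect estimates between those components; it is a test harness,
  not an epidemiological simulator.
* `average_nat` returns NA with a warning for episodes whose stay ends on
  the BAL day — there is no post-BAL day to average.
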