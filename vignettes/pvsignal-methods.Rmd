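---
title: "Signal detection for checkpoint-inhibitor aseptic meningitis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection for checkpoint-inhibitor aseptic meningitis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Immune checkpoint inhibitors (ICIs) — the CTLA-4 blocker ipilimumab, the
PD-1 blockers nivolumab, pembrolizumab and cemiplimab, and the PD-L1
blockers atezolizumab, durvalumab and avelumab — can trigger immune-related
neurological adverse events. Aseptic meningitis is a rare but serious one.
Spontaneous-report databases such as FAERS are the main source of
population-level evidence for such rare events, but they support only
*disproportionality* analysis: comparing how often an event is reported
under a suspect exposure against the database background, via a 2×2
cross-classification of reports. `pvsignal` implements that analysis as a
tested pipeline — case selection, four disproportionality algorithms with a
concordance rule, stratified descriptives and time-to-onset summaries —
together with a synthetic report generator so every stage can be validated
against known ground truth.

## Data model

A report database (`icsr_db`) mirrors the relational layout of
spontaneous-report archives: a demographics table (one row per case: event
date, age, sex, reporter country and derived continent, reporter type,
indication, receipt year), plus drug, reaction and outcome tables linked by
case id. Two on-disk dialects are supported: `'$'`-delimited
quarterly-archive-style text and RFC-4180 CSV, with files for the
DEMO/DRUG/REAC/OUTC/THER roles. The loader is total: unparseable ages,
dates or sex codes become missing values and are tallied in a load summary,
never raised as errors, and orphan drug or reaction rows are attached to
skeleton reports with a warning.

Dates follow the archive convention of partial precision (`YYYYMMDD`,
`YYYYMM`, `YYYY`). Partial dates are retained with day/month imputed as the
1st so interval arithmetic stays possible, and the original precision is
carried along; onset intervals that rest on an imputed date are flagged and
excluded from time-to-onset summaries by default. Drug names are
lowercased, trimmed and mapped to active moieties through an editable
synonym table; countries map to continents through an editable table, with
unmapped values becoming `unknown`.

## Case selection

Selection proceeds in a fixed order, and every stage logs its counts so
input = retained + removed can be audited:

1. **Suspect-ICI restriction** — keep reports with at least one suspect
   drug in the ICI catalog.
2. **Event flagging** — a report is a case when at least one reaction
   matches the meningitis preferred-term set (an editable surrogate for the
   licensed noninfectious-meningitis standardized query; eight terms:
   meningitis, meningitis aseptic, meningitis noninfective, meningeal
   disorder, meningism, arachnoiditis, meningoradiculitis,
   pachymeningitis), case-insensitively by default. The per-term match
   index is kept: a report with several matching terms appears under each,
   which is why term-level Ns can sum to more than the distinct case count.
3. **Deduplication** — two reports are duplicates when they agree on at
   least 3 of the 4 linkage fields {event date, age, sex, reporter
   country}. A missing value on either side never counts as agreement:
   treating shared missingness as identity would collapse sparse databases.
   Reports are swept in (receipt year, case id) order (byte order, so the
   result is platform-independent) and dropped when they match any already
   retained report; the first of each cluster survives, which makes the
   operation idempotent. The rule is deliberately coarse — with age, sex
   and country all present, three-field coincidences between genuinely
   distinct reports are possible, and the tests construct their
   exact-removal checks so that the sharp event-date field is required.
4. **Temporal plausibility** — a case is removed when its earliest suspect
   ICI start date is strictly after the reaction onset date. Day-0 onsets
   are plausible and retained; missing dates cannot prove implausibility,
   so those reports are retained.
5. **Regimen classification** — the suspect-ICI set determines the
   stratum: one drug gives that monotherapy; exactly
   {ipilimumab, nivolumab} gives the combination stratum; any other
   multi-ICI set is `other_ici_combination`, counted but excluded from the
   analysis strata; no ICI gives `non_ici`. Time to onset is the floored
   whole-day gap from earliest suspect ICI start to onset.

Whether "event date" should be the reaction onset date or the receipt date
is not fixed by convention; the package uses the onset date, and the field
set is confined to `dedup_key_matrix()` so the choice is easy to revisit.

## The four algorithms

For a 2×2 table with cells *a* (exposed, event), *b* (exposed, other
events), *c* (other exposures, event), *d* (neither), N = a and
n = a+b+c+d:

* **ROR** = ad/bc, with the Woolf interval
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)). Positive when the lower bound
  exceeds 1 and N ≥ 2.
* **PRR** = a(c+d) / (c(a+b)), supported by the Pearson χ² of the table
  without continuity correction. Positive when PRR ≥ 2, χ² ≥ 4 and N ≥ 3.
* **IC** = log₂(a·n / ((a+c)(a+b))), the information component. Positive
  when IC025 > 0.
* **EBGM** = a·n / ((a+c)(a+b)) — the relative reporting ratio, the same
  kernel as IC on the natural scale (so IC = log₂ EBGM identically). Its
  one-sided 5% lower bound is EBGM05 = exp(ln EBGM − 1.64·√(1/a+…+1/d)).
  Positive when EBGM05 > 2 and N > 0. No gamma-Poisson mixture shrinkage
  is applied; this is the closed-form ratio, not the full MGPS posterior.

A **validated signal** requires at least two algorithms positive at once
(configurable through `signal_criteria()`).

### The printed IC025 and the canonical variant

The interval formula this implementation reproduces for IC025 is
exp(ln(IC) − 1.96·√(1/a+1/b+1/c+1/d)): it applies exp/ln to the statistic
itself rather than to a log-scale standard error. That form is faithful to
its source but has two consequences: it is undefined for IC ≤ 0 (the
package then reports IC025 as undefined and the flag false — an IC ≤ 0
pair could never be signal-positive under "IC025 > 0" in any reading), and
it is not the conventional BCPNN bound. The conventional delta-method bound
on the log₂ scale, IC − 1.96·√(1/a+1/b+1/c+1/d)/ln 2, is available via
`formula_variant = "canonical"`. The default is the printed form because
faithfulness comes first; both variants are oracle-tested.

### Zero cells and other numerical choices

Any zero cell makes the statistics undefined; they are reported as `NA`
with a `zero_cell` reason code and count as flag-negative. A
Haldane–Anscombe +0.5 correction is available as an explicit switch,
default off, because the reference analysis never reports a zero-cell
signal. Cells are held as doubles before multiplication (the χ²
denominator overflows 32-bit integers already at moderate database sizes).

## Analysis strata

The regimen screen evaluates, against the full-database background: each
monotherapy, the ipilimumab+nivolumab combination, the drug classes, and a
pooled Total (any ICI suspect). A class stratum (Anti-PD-1, Anti-PD-L1)
contains the reports whose suspect ICI set is non-empty and lies *wholly
within* the class's drugs. This containment rule is the only reading
consistent with the published class counts, where the Anti-PD-1 N equals
the sum of its member monotherapy Ns and excludes the combination (whose
suspect set spans two classes): a report contributes once per class no
matter how many same-class suspects it carries, and class Ns add over
member monotherapies whenever no report carries two same-class suspects.

The head-to-head comparison (combination vs. nivolumab monotherapy) uses a
comparator-restricted background: c and d count only the comparator's
reports, so the ROR contrasts the two regimens directly. The term-level
screen evaluates each (preferred term, regimen) pair with at least
`min_n = 2` co-occurring reports — the smallest N the reference tables
display; the per-regimen "Total" there is the sum of term-row Ns, which
can exceed the distinct case count because a report may carry several
matching terms.

## Descriptive summaries

Outcome codes can be multiple per report while a descriptive table needs a
partition, so the most severe code wins: death > life-threatening >
disability > hospitalization > other serious > non-serious; a report with
no outcome code counts as non-serious. The serious fraction is the share
of reports above non-serious. Medians use the mean-of-middle-two
convention (half-day medians such as 36.5 in the reference table prove
that convention was used). Percentages are reported to one decimal with
half-up rounding against the stratum size. Free-text indications map to
organ-system buckets through an editable table. Annual counts are
zero-filled over the configured receipt-year span (2011–2024 by default).

## The synthetic generator

`generate_database()` draws `n_reports` independent reports:

* **Exposures** are independent Bernoulli draws per catalog drug, with the
  ipilimumab+nivolumab pair forced jointly at `combo_rate`; any report
  left with no drug receives a fallback background drug, since a report
  without a suspect drug cannot exist.
* **Events** are Bernoulli per catalog term at baseline probability q,
  tilted for exposed reports so that the population odds ratio equals the
  planted value: p = q·OR / (1 − q + q·OR). When several planted exposure
  keys apply to one report their odds ratios multiply. This logistic
  tilting is the whole dependence structure — the four algorithms all
  consume the same 2×2 cross-classification, and nothing deeper is assumed
  by the method under test. Reports with no sampled reaction receive the
  last catalog term as filler, because a well-formed report has at least
  one reaction.
* **Onset delays** are log-normal per regimen (right-skewed medians and
  very long upper ranges in the reference summaries motivate the family),
  realized as the gap between a therapy start date and the event date;
  the per-regimen medians default to the published ones (e.g. 81 days for
  nivolumab monotherapy, 32 for the combination, 10 for atezolizumab).
* **Demographics** default to a 64 ± 12 year age profile clipped to
  20–90, a mild female excess, a country mix dominated by Asia,
  North America and Europe, 90% healthcare-professional reporters, and
  outcome-category probabilities matching the published Total column.
  Per-field missingness defaults (age 0.2, sex 0.12, country 0.05, event
  date 0.3, start date 0.35) make the onset delay computable for roughly
  45% of reports, matching the published 225-of-498 completeness.
* **Near-duplicates**: `floor(rate · n)` reports are cloned under fresh
  ids that sort after their source. Each clone preserves at least three
  present linkage fields and perturbs at most one — exactly the structure
  the deduplication rule removes. The ground truth records the realized
  2×2 cells of every planted pair before duplicate injection, which is the
  oracle the table builder is tested against.

The generator is a deterministic function of its config (one seed, one RNG
stream), so two runs serialize byte-identically.

What it does **not** emulate: reporting dynamics over time (Weber effect),
drug–drug interactions, true masking/competition bias (although a strong
planted association visibly dilutes the background of the others — the
demo analysis shows this), MedDRA coding noise, and duplicate records that
disagree on more than one field. Passing the calibration and recovery
checks therefore shows the pipeline is correct *under the generative
model*, not that real FAERS signals are unbiased.

## Calibration and recovery conditions

Two stochastic properties anchor the validation, with problem sizes chosen
to give adequate expected cell counts while keeping the suite fast:

* **Calibration**: 500 replicate null databases of 1,200 reports
  (no planted associations); the validated-signal rate for a designated
  null drug–event pair must stay at or below 7.5% (the nominal one-sided
  level of the dominant ROR criterion plus Monte-Carlo slack).
* **Recovery**: 200 replicate databases of 2,600 reports with a planted
  odds ratio of 5 and exposure/baseline probabilities (0.12 / 0.11) sized
  so the expected signal cell exceeds 30; the estimated ROR must fall in
  [3.5, 7.0] in at least 90% of replicates and the pair must be validated
  (≥ 2 concordant algorithms) in at least 95%.

## Known limitations

* The reference analysis's regimen-level ROR/PRR values are not exactly
  reproducible by anyone without the underlying database extraction: the
  background cells b, c, d are not published. The package therefore treats
  those values as plausibility references and anchors its acceptance on
  count arithmetic that *is* fully determined by the published tables,
  plus formula oracles and synthetic ground truth.
* The published regimen-level IC/IC025 and EBGM columns are not consistent
  with any reading of the printed formulas (values like 63.32 are far off
  the log₂ scale of the other statistics); they are not reproduction
  targets.
* The deduplication rule is field-equality based; probabilistic record
  linkage is out of scope.
* The term set is a flat surrogate for a licensed MedDRA query; hierarchy
  rollups are out of scope.
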