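# pvsignal

Disproportionality-based safety-signal detection for spontaneous adverse
event reports, built around immune-checkpoint-inhibitor (ICI) associated
aseptic meningitis in FAERS-style databases. It is written for
pharmacovigilance analysts and methods researchers who need the full
chain — case selection, deduplication, regimen classification, four
signal-detection algorithms with a concordance rule, stratified
descriptives and time-to-onset analysis — as tested, reusable code rather
than a spreadsheet, and who need a synthetic report generator with planted
ground truth to validate every stage.

## The statistics at the core

Each drug–event pair is cross-classified over unique reports into the 2×2
table (a, b, c, d): a = reports with the suspect event and the exposure,
b = other events under the exposure, c = the event under all other
exposures, d = neither. With N = a and n = a+b+c+d the four algorithms
and their positivity criteria are

| Algorithm | Statistic | Signal-positive when |
|---|---|---|
| ROR  | ad/bc, Woolf CI exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)) | CI lower > 1, N ≥ 2 |
| PRR  | a(c+d)/(c(a+b)), Pearson χ² (no continuity correction) | PRR ≥ 2, χ² ≥ 4, N ≥ 3 |
| BCPNN | IC = log₂(a·n/((a+c)(a+b))) | IC025 > 0 |
| MGPS | EBGM = a·n/((a+c)(a+b)), EBGM05 = exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d)) | EBGM05 > 2, N > 0 |

A **validated signal** needs at least two algorithms positive at once.
The IC025 interval follows its source formula literally
(exp(ln(IC) − 1.96·√(1/a+1/b+1/c+1/d)), undefined for IC ≤ 0); the
conventional log₂-scale bound is available with
`formula_variant = "canonical"`. Zero cells make statistics undefined
(flag-negative) unless the optional Haldane–Anscombe 0.5 correction is
switched on. See the methods vignette
(`vignettes/pvsignal-methods.Rmd`) for derivations and design rationale.

## Worked example

Simulate a reporting database with a planted five-fold reporting odds
ratio for pembrolizumab × "Meningitis aseptic", build the pair's table and
evaluate it:

```r
library(pvsignal)

g <- generate_database(synthetic_config(
  n_reports = 20000, duplicate_rate = 0,
  planted_or = list(pembrolizumab = list("Meningitis aseptic" = 5)),
  seed = 7))

exposed <- unique(g$db$drugs$case_id[g$db$drugs$drug_name == "pembrolizumab"])
event   <- unique(g$db$reactions$case_id[g$db$reactions$pt == "Meningitis aseptic"])
tab <- build_table(g$db, exposed, event,
                   exposure_label = "pembrolizumab",
                   event_label = "Meningitis aseptic")
tab
#> <2x2 table> pembrolizumab x Meningitis aseptic (full_database)
#>   a=15 b=1216 c=53 d=18716
evaluate_signal(signal_statistics(tab))
#> <signal> pembrolizumab x Meningitis aseptic: N=15 ROR=4.36 (2.45, 7.75) PRR=4.32 chi2=29.9 IC=1.84 EBGM=3.58
#>   flags: ror+prr+bcpnn+mgps -> VALIDATED
```

Fifteen exposed event reports give an estimated ROR of 4.36 with interval
(2.45, 7.75) — consistent with the planted value of 5 — and all four
algorithms cross their thresholds, so the pair is a validated signal.
`select_cases()` runs the full selection chain (term query → dedup →
temporal filter → regimen classification) with a per-stage count audit,
`regimen_screen()` / `pt_level_screen()` / `head_to_head()` produce the
regimen-, term- and comparison-level signal tables, and `run_pipeline()`
writes all artifacts plus a manifest in one call.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write their tables under `results/`:

1. `01_simulate.R` — a 60,000-report database with planted per-drug odds
   ratios at the reported monotherapy magnitudes (the
   ipilimumab+nivolumab combination composes multiplicatively).
2. `02_select_cases.R` — case selection with the stage-count audit.
3. `03_descriptives.R` — stratified descriptive tables, time-to-onset
   summaries, annual trend.
4. `04_signals.R` — regimen/term-level screens and the
   combination-vs-nivolumab head-to-head, checked against planted truth.
5. `05_published_counts.R` — the one-command pipeline on a case series
   rebuilt from the published stratified counts, embedded in a synthetic
   background.

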