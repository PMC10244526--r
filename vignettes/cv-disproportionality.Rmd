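---
title: "Cardiovascular disproportionality analysis of spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiovascular disproportionality analysis of spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse event (AE) reporting systems such as FAERS receive
reports in which a reporter names one or more drugs, one or more MedDRA
preferred terms (PTs) describing the events, outcome codes, indications and
demographics. The data are messy in well-known ways: a case accumulates
several report *versions* (duplicates from different senders, follow-ups
with updated information); drugs appear as free text under generic names,
brand names, research codes and misspellings; and a drug may be reported as
the *suspect* cause, or merely as *concomitant* or *interacting*.

`faersignal` answers a case–noncase question on such data: do patients
exposed to immune checkpoint inhibitors (ICIs), angiogenesis inhibitors
(AGIs), or both classes together over-report cardiovascular AEs relative to
the rest of the database? The package provides the cleaning, the event
grouping, the disproportionality statistics with their interval formulas,
the signal rule, and severity profiling — plus a synthetic report-stream
generator so each claim the pipeline makes can be tested against exact
ground truth.

## Cleaning model

Cleaning proceeds in three fixed steps, each a separate, testable function:

1. **Deduplication** (`dedup_reports()`). Exactly one report version per
   case id survives: the maximal one under a configurable version key,
   default FDA receipt date with the lexicographically largest report id as
   tiebreak. The source data do not carry an explicit "latest version"
   marker, so the key is exposed as a parameter. The operation is
   idempotent.
2. **Suspect-role filtering** (`filter_suspect()`). Only *suspect* drug
   mentions classify exposure; concomitant and interacting mentions are
   removed, and reports with no suspect drug at all are dropped (they
   cannot be assigned an exposure group).
3. **Exposure classification** (`classify_exposure()`). Suspect drug names
   are normalised (Unicode case-fold, trim, collapse internal whitespace —
   no fuzzy spell correction; curated misspellings belong in the archive as
   alias rows) and matched against a drug-name archive mapping every
   variant to `ICI` or `AGI`. The exposure group is then a pure function of
   the classes present: `{ICI}`→ICI alone, `{AGI}`→AGI alone,
   `{ICI,AGI}`→combination, `{}`→neither. Unmatched names are simply
   non-study drugs.

Every stage logs records in / kept / dropped, and `run_faers()` writes
these into a manifest in which counts reconcile exactly.

## Event grouping

Cardiovascular AEs are defined by nine narrow-scope Standardised MedDRA
Queries (SMQs): cardiac arrhythmias (20000049), cardiac failure (20000004),
cardiomyopathy (20000150), embolic and thrombotic events (20000081),
hypertension (20000147), ischaemic heart disease (20000043), noninfectious
myocarditis/pericarditis (20000239), pulmonary hypertension (20000130) and
torsade de pointes/QT prolongation (20000001). MedDRA is licensed, so the
member PT lists are supplied by the user as a TSV; `as_smq_map()` validates
them against this nine-code catalogue, keeps narrow-scope rows only, and
warns about unknown codes or empty categories. The package ships a clearly
labelled *synthetic* membership table (`smq_map_synthetic.tsv`) with
plausible members for examples and tests. A PT may belong to several SMQs
and participates in each SMQ's analysis independently.

## Counting unit and comparator

The unit entering the 2×2 tables is the **report**, operationalised as a
distinct (case, PT) pair — a case reporting myocarditis and pericarditis
contributes two cardiovascular reports but one cardiovascular case. At SMQ
level the default (`counting = "per_smq_once"`) counts a case at most once
per SMQ on the target side, so within-case PT multiplicity inside one SMQ
cannot inflate that SMQ's signal; `counting = "per_pt"` counts every member
pair instead. Both modes are exposed because the choice is not dictated by
the data model; the oracle-equivalence tests cover both.

The comparator supplying the c/d cells defaults to the reports of the
`neither` group — the database without either study class — with
`other_reports` (all reports outside the target group) as the alternative.

## Statistics

For a target (exposure group, event) pair, with `a` observed target
reports, margins `N_drug = a+b`, `N_event = a+c`, `N_total = a+b+c+d`, and
`N_expected = N_drug·N_event/N_total`, the package computes the
shrinkage-transformed estimates

$$\mathrm{ROR} = \frac{N_{obs}+0.5}{N_{exp}+0.5}, \qquad
\mathrm{IC} = \log_2 \frac{N_{obs}+0.5}{N_{exp}+0.5},$$

so that IC ≡ log₂(ROR) identically — both share the shrunk
observed/expected core, and the +0.5 keeps them defined for empty cells
while pulling small-count estimates towards the null. Note this "ROR" is an
observed/expected ratio, not the classic odds ratio
`(a·d)/(b·c)`; the latter is available via `estimate = "classic"` for
comparison. Intervals:

$$IC_{025} = IC - 3.3\,(N_{obs}+0.5)^{-1/2} - 2\,(N_{obs}+0.5)^{-3/2},$$
$$IC_{975} = IC + 2.4\,(N_{obs}+0.5)^{-1/2} - 0.5\,(N_{obs}+0.5)^{-3/2},$$

the standard closed-form approximation to the IC credibility interval
(asymmetric around IC; width → 0 as the observed count grows; in some
published texts the upper bound is typeset "IC075" — it is the upper 95%
bound), and the classic Wald interval
$\exp[\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}]$ centred on the
shrunk point estimate. With any zero cell the Wald standard error is
undefined: the bounds are reported as `NA` (no additional continuity
correction is applied beyond the shrinkage in the point estimate) while the
point estimates remain defined.

**Signal rule.** `ROR025 > 1` or `IC025 > 0`, each with at least
`min_reports = 3` observed reports; inequalities strict, `NA` bounds never
flag, and the two criteria are reported separately. No multiple-testing
adjustment is applied — thresholds are per-signal, which is the
field-standard practice for these statistics but means the PT-level signal
*count* grows with the PT universe; treat it as hypothesis generation.

Reported statistics are displayed at 3 decimals (the conventional printed
precision); all computation and the TSV exports keep full precision unless
a display precision is requested.

## Outcome severity

Outcome codes arrive per report (death, life-threatening, hospitalisation,
disability, congenital anomaly, other serious; absence = unknown). Severity
tabulations assign each case exactly one category so that column
percentages sum to 100; because a case may carry several codes, a
precedence is required, and the data model does not prescribe one. The
default — death > life-threatening > disability > congenital anomaly >
hospitalisation > other serious > unknown — puts fatal outcomes first and
is overridable. Percentages use the stratum case count as denominator and
are rounded to 1 decimal; `combined_death_lt()` adds the two rounded
percentages, matching how such figures are quoted.

## The synthetic generator

`synth_generate()` emulates the features of a FAERS extract that the
pipeline must survive: case versions (final version complete, earlier
versions thinned), suspect/concomitant/interacting roles, archive name
variants with cosmetic mangling, per-group outcome and indication mixes,
demographics and receipt years. Defaults are a desk-scale database of
~37,000 cases keeping the real-world proportions between the exposure
groups (ICI : AGI : combination ≈ 19 : 47 : 4 against a dominant
background), with outcome and indication mixes per group taken from the
observed severity profiles of these drug classes.

**Reaction model.** A case in group $g$ includes PT $j$ with probability
$p_{gj} = \min(1, f_j\,\rho_{gj})$, independently across PTs ("Bernoulli
inclusion"), where $f_j$ is the PT's baseline rate and $\rho_{gj}$ a
relative reporting rate composed of an SMQ-level factor and an optional
PT-level factor. We chose this over drawing a Poisson number of PTs from a
tilted frequency table because (i) per-case PT sets are distinct by
construction, matching the analysis unit, and (ii) every expected
contingency cell is exactly linear in $\rho$ and available in closed form
(`expected_table()`), so tests can compare pipeline output against exact
expectations rather than approximations.

What the generator does **not** emulate: probabilistic near-duplicates
across manufacturers (dedup ground truth is key-based), real marginal PT
frequencies, country/reporter correlation structure, or chronological
reporting trends. Passing tests therefore demonstrate correctness of the
machinery on a faithful-but-idealised stream, not calibration to the real
database's magnitudes.

## Design of the recovery experiment

The shrunk observed/expected ROR estimates an injected rate ratio $\rho$
only in the rare-event, small-group regime. Two finite-size effects bias it
towards the null otherwise:

* **contamination** — the target group's own reports sit in the comparator
  margins, giving a factor $\approx (1+r)/(1+\rho r)$ with
  $r = n_g/n_0$ the exposed-to-background size ratio;
* **margin dilution** — the planted excess inflates the exposed group's own
  report margin $N_{drug}$, giving a factor
  $\approx S_0/(S_0 + f(\rho-1))$ where $S_0$ is the per-case expected
  report count and $f$ the target PT's baseline rate.

The package's recovery experiment (see the acceptance test) therefore uses
a small exposed group against a large background ($n_g = 600$ vs
$n_0 = 150{,}000$, planted $\rho \in \{2, 4\}$ on one PT with expected
observed counts ≥ 100), and holds the total per-case reporting rate
constant across groups by down-weighting the filler PT load in the exposed
group by exactly the planted excess — a balanced-load design under which
the estimator's estimand equals $\rho$ up to a residual contamination bias
of ~1%. Twenty fixed-seed replicates per $\rho$ keep the Monte-Carlo error
of the mean near 1%. Without the balanced-load design the same experiment
measures $\rho \cdot S_0/(S_0+f(\rho-1))$ — a property of the estimator,
not a defect of the pipeline, and the reason signal *strengths* from
disproportionality statistics are comparative, not causal effect sizes.

A null calibration (500 PTs, all $\rho = 1$, one group of 5,000 cases vs
50,000 background) checks that the `IC025 > 0` rule flags at most a few
percent of events; with its asymmetric penalty of
$3.3(a+0.5)^{-1/2}$ the rule is conservative at small counts, and the
observed false-signal fraction is well under 5%.

## Numerical and degenerate-input choices

* `N_total = 0` is an undefined-input error; `N_expected = 0` (empty drug
  or event margin) is fine and yields ROR = 1, IC = 0 via the shrinkage.
* Ages parse as non-negative numbers, anything else is missing; unmapped
  sex/reporter/country codes read as `"unknown"`; an unmapped drug role is
  a format error because the role drives the analysis.
* Dedup ties on the receipt date break by report id, so the ordering is
  total and reruns are byte-identical.
* The generator is a deterministic function of its config (single seed;
  same config ⇒ byte-identical files).
* An empty outcome stratum is kept with denominator 0 and `NA`
  percentages rather than dropped.

## Problem sizes used in the test suite

Unit and property tests run on streams of a few hundred to a few thousand
cases; the oracle-equivalence check enumerates every (group, PT) and
(group, SMQ) table by brute force on a ~2,800-version batch; the recovery
experiment runs 40 replicates of a ~151,000-case stream; the whole suite
completes in a few minutes on one CPU. These sizes were chosen so that
Monte-Carlo error, not runtime, is the binding constraint.

## Known limitations

* Deduplication merges on the case id only; near-duplicates submitted
  under different case ids (e.g. by different manufacturers) are not
  linked.
* The indication restriction is a case-insensitive substring match against
  a term list — adequate for the seven cancer indications it targets, not
  a general indication coder.
* Signal counts under the two criteria are reported without multiplicity
  control, as is standard for these statistics.
* The shipped SMQ membership table is synthetic; real analyses must supply
  licensed MedDRA narrow-scope member lists.
* Database-scale quantities (absolute case counts, numbers of signalled
  PTs) depend on the real extract and are out of scope for the synthetic
  conditions; the tests verify formulas, counting and recovery behaviour,
  not real-world magnitudes.
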