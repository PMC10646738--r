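---
title: "Auditing blood ordering and deriving an MSBOS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing blood ordering and deriving an MSBOS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbos)
```

## The problem

Elective surgical services routinely crossmatch — reserve and
compatibility-test — more red-blood-cell (RBC) units than they transfuse.
Every unnecessarily reserved unit ties up inventory, laboratory time and
money, and increases the chance a unit expires unused. Blood-bank practice
has converged on a small set of utilization indices for auditing this, and
on the *Maximum Surgical Blood Order Schedule* (MSBOS): a per-procedure
table stating how many units to crossmatch preoperatively, or that a type
and screen (T&S) suffices.

This package implements that audit for patient-level transfusion records.
One row is one patient-procedure episode with the units crossmatched and
transfused (plus optional issue and wastage data). Records flagged as
excluded — conventionally massive transfusions and transfusion reactions,
which would distort an ordering audit — are dropped from every aggregate.

## The indices

For a cohort of $n$ crossmatched patients, of whom $n_T$ were transfused,
with $X$ units crossmatched, $T$ units transfused, $I$ issued and $W$
wasted:

* **CTR** $= X/T$, the cross-match-to-transfusion ratio. 1 is ideal;
  $\le 2.5$ is the usual efficiency recommendation, with a stricter school
  using 2.0.
* **T%** $= 100\, n_T/n$, the transfusion probability; $\ge 30\%$
  indicates blood was genuinely needed.
* **TI** $= T/n$, the transfusion index — mean units per crossmatched
  patient; $\ge 0.5$ indicates meaningful utilization.
* **NUP** $= (X-T)/X$, the non-usage probability. Whenever $T>0$,
  $\mathrm{NUP} = 1 - 1/\mathrm{CTR}$, an identity the test suite checks
  to $10^{-12}$.
* **WAPI** $= 100\,W/I$, wastage as a percentage of issue, with wastage
  events categorized into the four standard areas (expired after issue,
  improper storage/transport, late return, other).

Degenerate denominators are kept honest: a procedure with crossmatched
units but no transfusions has an *undefined* CTR (stored as `NA`), not an
infinite or zero one. Printed audit tables traditionally write 0 in that
cell, so the report layer offers a `paper` style that renders the
convention while the computed objects keep `NA` (`render_table()`,
`run_audit(paper_style = TRUE)`). The same style prints T% as a fraction
of 1, the other common convention.

## The schedule

The MSBOS value for a procedure is derived from the histogram of
transfused-unit counts: the raw value is the weighted mean
$\sum_k k\,h_k / n$ — by construction identical to TI — and the scheduled
order is its **ceiling**. Rounding up, rather than half-up, is deliberate:
a schedule that covers the mean demand must not round 1.03 mean units down
to 1 reserved unit. The ceiling convention is verified in the tests on
every row of the bundled cohort (1.03 → 2, 0.77 → 1, 0 → 0).

A raw value of 0 (no patient transfused) yields a T&S recommendation: no
units reserved, typing and antibody screen only. The classical literature
also uses $1.5 \times$ TI; the `multiplier` argument supports that
convention but defaults to 1, which is appropriate where adult-size bags
are used for pediatric patients and the mean already overstates per-kg
demand. A third category, "no testing required", exists in published
schedules but no rule in this framework produces it, so the package never
emits it.

Per-procedure **overrides** can raise a crossmatch recommendation above
the computed value. This exists because schedules are ultimately clinical
documents: an audit committee may keep a 2-unit order for a procedure
whose arithmetic says 1 (aortic coarctation in the bundled example is
exactly such a case). Overrides live in configuration, never in code, and
can never turn a T&S into a crossmatch.

## The fitted object

`blood_audit()` is the package's central function. It returns a classed
object holding the per-procedure summaries, the five indices with
threshold flags (per procedure and pooled under `"ALL"`), and the
schedule. `coef()` gives the pooled indices; `predict()` looks up the
recommendation for procedure codes; `simulate()` draws
parametric-bootstrap cohorts from the fitted per-procedure histograms;
`plot()` shows per-procedure CTR against the cut-off. `run_audit()` wraps
the whole pipeline file-in, files-out for scripted use, and
`inst/cli/blood-audit` exposes it as a command line.

```{r}
fit <- blood_audit(example_cardiac_cohort())
fit
predict(fit, c("VSD", "PDA"))
```

## The synthetic-cohort generator

`generate_cohort()` emulates the structure the audit assumes: a fixed
number of crossmatched units per patient (2 in the bundled pediatric
cardiac practice, reflecting a standing 2-unit preoperative order) and
transfused-unit counts drawn i.i.d. from a per-procedure categorical
distribution on $\{0,\dots,K\}$, default $K = 3$, the largest count seen
in practice for these procedures. Optional wastage events are Bernoulli
per issued unit with a categorical split over the four wastage areas.
One seeded generator drives each cohort; the caller's RNG state is left
untouched, and the same spec and seed reproduce the same cohort exactly.

What the generator does *not* emulate — patient covariates (weight,
hemoglobin, comorbidity), within-surgeon correlation, seasonal drift — is
exactly what passing tests cannot certify about real data. The tests show
the pipeline's arithmetic and plumbing are correct, not that a 2-unit
order is right for any particular service; a site derives that from its
own records.

`exact_cohort_from_histogram()` is the deterministic counterpart: it
reconstructs the exact patient list realizing a transfused-unit
histogram. The bundled `example_cardiac_cohort()` — 146 elective
pediatric cardiac episodes over eight procedures, two adult units
crossmatched each — is built this way from its eight histograms, so the
whole published-style audit table is reproducible from code with no data
files.

## Numerical and design choices

* Unit counts are whole integers; no volume arithmetic. Validation
  rejects negative or fractional counts with the offending row number.
* Display rounding is half-up at 2 decimals (matching how audit tables
  are printed); internal values keep full precision. Note printed tables
  are not always self-consistent — the bundled cohort's source prints
  25/15 as 1.66 — so tests compare at the printed precision, ±0.01.
* The schedule ceiling subtracts a $10^{-9}$ guard before `ceiling()` so
  floating noise cannot push an exact integer up a unit.
* `units_issued` defaults to `units_crossmatched` when no issue column
  exists, making WAPI computable from minimal exports (reserved units are
  what services reliably record).
* Procedure codes are free strings normalized by trimming and
  upper-casing, with an optional alias map in configuration; repeated
  patient identifiers are treated as distinct episodes (audits count
  episodes, not admissions).
* Tie-break for table order: descending cohort size, then code,
  so regenerated reports are byte-identical.
* Two CTR cut-offs circulate in the literature (2.5 and 2.0); both are
  configurable, flagging defaults to 2.5 with `strict = TRUE` switching
  to 2.0.

Problem sizes in the test suite: property tests loop over cohorts of
10–80 records across 5–10 seeds; the parameter-recovery check draws one
10,000-patient cohort and requires the empirical TI, T% and CTR to land
within three standard errors of the specified distribution's moments. The
whole suite runs in a few seconds.

## Limitations

The audit is descriptive: it summarizes past ordering against past use
and cannot anticipate case-mix change, nor say *why* a procedure
over-orders. It deliberately excludes plasma and platelet products, whose
wastage dynamics differ, and offers no hemoglobin-trigger or risk-factor
modelling; sites wanting demand *prediction* need patient-level covariates
this data model does not carry.
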