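---
title: "Modelling elective surgery, hospital revenue and surge capacity with surgecap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling elective surgery, hospital revenue and surge capacity with surgecap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgecap)
library(dplyr)
```

## The problem

During an epidemic surge, hospitals can free inpatient and intensive-care
(ICU) beds by cancelling elective surgery — at the cost of the revenue
those surgeries generate.  Quantifying that trade-off needs three linked
pieces of accounting:

1. **Classification.**  From administrative insurance claims, decide which
   admissions are *elective surgical*, *non-elective (emergent) surgical*
   or *non-surgical*.
2. **Utilization and revenue.**  Turn admissions into bed person-days and
   gross payments, stratified by month, state and major diagnostic
   category (MDC), and split each state's bed inventory into beds occupied
   by emergent cases, beds occupied by elective cases, and unoccupied
   (available) beds.
3. **Surge demand.**  Project epidemic hospital and ICU caseloads per
   state from age-specific rates, convert incidence into peak bed census
   through a length-of-stay convolution, and compare demand with bed
   supply with and without elective cancellation.

Real claims extracts of the necessary scale are proprietary, so the
package ships a synthetic claims generator with ground-truth labels; every
downstream stage is exercised and tested against it.

## Claims classification

An admission is **surgical** when it carries an operating-room revenue
code (UB-04 codes 0360, 0361, 0362, 0367, 0369, 0975) or admission-type
code 1.  A surgical admission is **elective** when none of its codes
(revenue or dedicated emergency/provider flags) is an emergency marker;
the default emergency set is the ER revenue codes 0450–0459 and 0981 and
is configurable, since code usage varies across payers.

**Complication attribution.**  Any admission falling within 30 days after
an elective surgery (inpatient or outpatient) of the same enrollee is
attributed to that surgery: it is labelled `elective_surgical` with
`is_complication = TRUE` and linked to its parent surgery.  Conventions
the data dictionary leaves open were fixed as follows:

* the window is half-open, `(surgery date, surgery date + 30]`: a same-day
  admission is part of the surgical encounter, a day-30 readmission is a
  complication;
* the window anchors on the *surgery* (admission) date, not the discharge
  date — outpatient surgeries have only one date, and a single convention
  for both settings keeps the rule coherent;
* a readmission that is itself independently elective keeps its own label
  (it is a new surgery, not a complication);
* windows anchor only on true elective surgeries — a readmission within 30
  days of a *complication* is not chained onto the original surgery.

The three categories always partition the records, labels are invariant to
row order, and widening the window can only move records *into* the
elective category.  MDC-level reporting excludes the eye (02),
health-status (23) and HIV (25) categories and records with a missing MDC,
all configurable.

## Utilization, occupancy and bed allocation

Person-days use inclusive day counting: admission and discharge days both
count, so a one-day stay contributes one person-day.  Each calendar day of
a stay is assigned to its own month; ICU days sit at the start of the stay
(only cell totals are consumed downstream, but the day-level oracle in the
test suite needs a fixed convention).

The **unoccupied fraction** of a state's beds is estimated from temporal
slack in its own utilization series: monthly person-day totals are
converted to average daily census (dividing by days in the month, so that
28- vs 31-day months do not inject spurious variation), and

$$\text{unoccupied} = \frac{\max_m \text{census}_m - \overline{\text{census}}}{\max_m \text{census}_m}.$$

This treats the maximum observed monthly census as full capacity — an
assumption, stated as such: it cannot see beds that were never filled
during the observation window.

`allocate_beds()` then splits an external bed inventory:
occupied = total × occupied fraction; elective = occupied × elective share
of person-days; emergent = occupied − elective; available = total −
occupied.  Rounding to whole beds uses largest-remainder correction so
that emergent + elective + available equals the total *exactly* in every
state and level — the conservation identity the reported national bed
counts must satisfy.

## Revenue accounting

Gross payments are aggregated by MDC × category × setting.  The headline
denominator is *all inpatient revenue plus outpatient surgical revenue*;
outpatient non-surgical encounters (office visits and the like) are out of
scope.  An `inpatient_only` denominator is also provided.  Complication
admissions' revenue is credited to the elective category; whether it
carries the *parent surgery's* MDC (default) or the readmission's own MDC
is a documented switch, since either attribution is defensible.  Statewide
spread is summarised as median and IQR with linear interpolation between
order statistics (the `quantile()` type-7 convention) — the same
percentile rule is used everywhere quartiles are reported.  Payments are
nominal USD; no inflation adjustment is applied.

## The surge-demand model

Expected caseloads per state are

$$E[\text{hosp}_s] = \sum_a \text{pop}_{s,a} \cdot \pi \cdot h_a, \qquad
  E[\text{ICU}_s] = \sum_a \text{pop}_{s,a} \cdot \pi \cdot c_a,$$

with $\pi$ the infection prevalence (default 0.05 — the planning
assumption that at least 5% of the population becomes infected), and
$h_a, c_a$ age-band hospitalization and ICU rates per infection, each
carried as lower-bound / mean / upper-bound triples so rate uncertainty
propagates to every output.  The bundled default rates follow the shape of
early-2020 US surveillance reporting (hospitalization 1.6–2.5% at ages
0–19 rising to 31.3–70.3% at 85+; mean = midpoint of the range).  ICU
rates are interpreted as conditional on infection (configurable to
conditional-on-hospitalization).

**Peak census.**  A scenario incidence curve (single-modal by assumption,
default 100-day course) is scaled so total admissions equal the expected
caseload, then convolved with a rectangular length-of-stay kernel:

$$\text{census}(t) = \sum_{u = t - L + 1}^{t} \text{admissions}(u),$$

with $L = 11$ days for inpatient beds and $L = 9$ days for ICU beds by
default.  (Both values are configurable; where a single mean stay of 9
days is preferred, set both to 9.)  Admissions are assumed synchronous
with infection; a configurable infection-to-admission lag (default 0) is
available.  The census series is carried $L - 1$ days past the end of the
curve, which makes person-days conserve exactly:
$\sum_t \text{census}(t) = \text{cases} \times L$.  Patients are carried
as fractional reals throughout; rounding happens only in reports.

**Overcapacity.**  For each state × scenario × bound × level the headline
metric is peak census divided by bed supply, as a percentage: available
beds as-is, or available + elective beds when elective surgery is
cancelled.  Since freeing elective beds can only enlarge the denominator,
the cancelled ratio is never larger — a monotonicity property the test
suite sweeps across a 50-state synthetic panel.  Because "patients
requiring admission per available bed" can also be read cumulatively, a
`cumulative_per_bed` column (total cases over the course per bed) is
emitted alongside; peak census is the headline.  Scenarios
(`current_projection`, `mandates_easing`, `universal_masks`) differ by
caseload scale and curve shape and are inputs, not outputs: the package
does not model transmission.

## The synthetic claims generator

`generate_claims()` emulates the *structure* of a large employer-sponsored
claims extract — not any real marginal distribution:

* per-admission category draw with configurable elective share (default
  0.30 of inpatient admissions, matching the roughly 30% of person-days
  associated with elective surgery that motivates the bed-allocation
  stage), non-elective surgical share 0.20;
* discretized log-normal lengths of stay (median 4 days) and log-normal
  payments per category (medians ≈ \$28k elective inpatient, \$32k
  emergent surgical, \$11k medical, \$6.5k outpatient surgery — plausible
  gross-billing magnitudes, chosen once);
* ICU involvement on 10% of inpatient stays; 15 MDC codes with weights
  tilted toward musculoskeletal, circulatory, digestive, respiratory and
  pregnancy; ~1% missing MDC;
* codes consistent with the classification rules by construction: elective
  records carry a surgical marker and no emergency code, emergent
  surgeries a surgical plus an emergency marker (placed in either code
  field), non-surgical records neither;
* each elective surgery spawns a readmission 1–30 days later with
  probability 0.08;
* optional insurer switching (an enrollee appearing under two IDs),
  default off.

Ground-truth labels are assigned by an exhaustive pairwise window check,
independent of the classifier's join-based implementation, so the
label-accuracy test is a genuine dual-route comparison.  One subtlety
matters for parameter recovery: an admission that *coincidentally* falls
inside another surgery's window truly is a complication under the rules,
which biases the realized elective fraction above the configured draw
probability.  Recovery experiments therefore switch off the extra window
channels (no spawned complications, no outpatient surgery) and measure the
share among non-complication records, leaving the 3-standard-error check a
clean binomial comparison.

What passing tests on this generator do **not** show: fidelity to real
claims (coding error, payer mix, seasonality, regional practice variation,
the Medicare population outside employer plans), hence none of the demo's
dollar or percentage outputs are estimates of real national quantities.
They show that the accounting is internally correct and that the rules
recover known ground truth.

## Numerical choices and degenerate inputs

* Bed rounding: largest-remainder with ties broken by component order —
  conservation is exact, never off-by-one.
* Percentiles: type-7 linear interpolation, everywhere.
* Zero denominators: groups with zero person-days or zero revenue report
  `NA` (missing), not 0; a state with zero available and zero elective
  beds reports an infinite ratio with a warning.
* A state with fewer than two months of utilization has no defined
  unoccupied fraction (error); an all-zero census gives `NA` with a
  warning.
* Epidemic curves: a discretized Gaussian pulse normalised to the exact
  total; optional day-level noise is rearranged monotonically around the
  peak so the single-mode invariant survives.
* Determinism: every stochastic step derives from the single configured
  seed; two runs of the pipeline from the same configuration are
  byte-identical.

## Problem sizes

The bundled demo runs 2,000 enrollees over two years in eight states —
a few thousand admissions — which is ample for the structural checks the
pipeline makes and keeps a full run in the low seconds.  Parameter
recovery experiments use ~10,000 admissions, where 3 binomial standard
errors is about ±1.4 percentage points at a share of 0.3.  Property
sweeps for the demand model use a synthetic 50-state panel across three
scenarios and all three bounds.

## Known limitations

* The occupancy proxy (max monthly census = capacity) is optimistic about
  how much slack the busiest month reveals.
* Complication attribution is purely temporal; it will claim unrelated
  admissions that fall inside a window, exactly as a revenue-code-only
  rule on real claims would.
* The demand model has no transmission dynamics, no age structure in LOS,
  and treats regional infection rates as uniform within a state.
* Scenario curves, rates, populations and bed inventories are inputs;
  their realism bounds the realism of every downstream ratio.
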