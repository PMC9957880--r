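---
title: "A lifetime discrete-event simulation of knee cartilage repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime discrete-event simulation of knee cartilage repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrosim)
```

## The question the model answers

Articular cartilage defects of the knee do not heal on their own; left
untreated they progress toward osteoarthritis, and a substantial share
of patients eventually needs a total knee replacement (TKR).
Matrix-associated autologous chondrocyte implantation (M-ACI) is an
expensive cell-based repair (about 11,000 EUR per procedure under
German DRG reimbursement) whose clinical promise is durability: if the
repair holds for decades, downstream re-operations and knee
replacements are avoided. Whether that durability is worth the up-front
price from the payer's perspective is a question no trial will answer
within a career, so it is answered by simulation.

`chondrosim` implements an individual-level, continuous-time
discrete-event simulation (DES). Each synthetic patient enters with a
symptomatic defect and is followed until death in two parallel
healthcare worlds under common random numbers:

* **with M-ACI** -- M-ACI is the primary repair for every patient (this
  mirrors the factual world, because the reference cohort consists of
  patients who actually received M-ACI);
* **without M-ACI** -- the counterfactual world, in which patients
  receive microfracture (MF), matrix-associated bone marrow stimulation
  (mBMS), partial or total knee replacement, or conservative care.

The per-patient difference in discounted lifetime costs and QALYs is
the quantity of interest; cohort means give the incremental
cost-effectiveness ratio (ICER), and the per-patient distribution gives
the cost-effectiveness acceptability curve (CEAC).

## Synthetic population

The original patient-level data (sex, age, defect size for 10,000
M-ACI recipients) are proprietary. The generator reproduces the
published *marginal* distributions instead: a 60.7% / 39.3% male/female
split; age strata (<35, 35--45, 45--55, >=55 years) and defect-size
strata (<2, 2--4, 4--6, 6--8, 8--10, >=10 cm2) per sex, with the
published per-sex means (age 35.9/36.6 years, defect 4.5/4.1 cm2).
Within a stratum values are drawn uniformly; a per-sex shift, clipped
to each value's stratum, then aligns the sample means with the
published means to within 1%. Age and defect size are treated as
independent given sex because only marginals are published; the open
upper strata are closed at 70 years and 15 cm2 as pragmatic supports.
Ages and defect sizes are continuous.

What the generator does *not* emulate: any age--defect-size
correlation, secular trends in the treated population, bilateral
disease, or region-level heterogeneity. Results conditional on these
features are outside what passing tests can certify.

Mortality comes from a per-sex Gompertz--Makeham life table
(`life_table_default()`), calibrated once so that the default cohort's
median death age is about 84 years (median modelled horizon about 48
years), consistent with contemporary German period mortality; an exact
official table can be supplied as CSV (`read_life_table()`). Death ages
are sampled by walking annual survival from the entry age and placing
death uniformly within the death year.

## Failure-time model

Each intervention carries a two-component Weibull mixture for its time
to failure,
$$S(t) = w\,e^{-(t/\lambda_s)^{k_s}} + (1-w)\,e^{-(t/\lambda_l)^{k_l}},$$
read as two competing failure *causes*: a short-term cause (graft
failure, early symptomatic relapse; weight $w$, shape $k_s \le 1$-ish)
and a long-term wear-out cause (shape $k_l > 1$). Calibration per
intervention proceeds in two steps:

1. the long-term component is fitted through configured survivorship
   anchors -- a closed form through two anchors, a fixed shape with one
   anchor, least squares on the log--log linearised survival with more;
2. the short-term scale is then solved so that the *mixture* reproduces
   the published 2-year failure probability exactly (M-ACI 7%, MF 39%,
   mBMS 4%, PKR 4%, TKR 4%).

The published sources give only the 2-year rates and, for TKR, an
average service life around 25 years. The long-term anchors and mixture
weights shipped as defaults are therefore calibration choices of this
package, chosen (before any acceptance measurement of headline
economics) to reproduce the published trajectory statistics of the
reference study: about 47% of M-ACI patients re-operated within 25
years, about 82% ever, and a mean time to second intervention near 17
years, which pins the M-ACI mixture at roughly a quarter of implants
failing from the short-term cause and the rest wearing out with a
median near 28 years. The comparator repairs (MF, mBMS) were calibrated
against the published without-M-ACI re-operation tempo (second
intervention after about 12 years on average, 3.2 surgeries per
lifetime). All anchors live in the configuration and can be replaced.

There is deliberately **no** separate "unsuccessful primary" draw: the
2-year failure probability of the mixture subsumes early
unsuccessfulness, because the sources print a single 2-year rate and a
separate acute-failure draw would double-count it.

## Event engine

Per patient and scenario the engine loops over: treatment decision,
intervention, failure draw, re-decision -- until death. The rules:

* **Eligibility** (clinical guideline bounds): MF for defects up to
  2 cm2 (5 cm2 in the MF scenario analysis); mBMS up to 5 cm2, with
  defects of 5--10 cm2 -- for which no guideline option exists --
  routed to mBMS-or-wait (this is the model's largest structural
  guess); M-ACI above 2 cm2 in the with-M-ACI scenario (waived at the
  primary decision, where every patient receives M-ACI); knee
  replacement for massive defects (>10 cm2) *or* after at least one
  failed repair, reflecting osteoarthritis progression -- without this
  second route the published TKR incidence is unreachable, since only
  3.8% of the cohort has a defect above 10 cm2. TKR only between 55 and
  80 years of age.
* **Policy**: among eligible options, a categorical draw with
  configured weights per scenario and decision stage (primary, second,
  third-plus). Options include `conservative` (wait about a year under
  conservative therapy, then re-decide) and `none` (permanently decline
  further surgery; the patient settles into the "no further repair"
  state). The shipped weights are calibrated, not published: they
  approximate the published intervention mix (about a third of
  with-M-ACI second interventions renew the M-ACI and 4% move to TKR;
  the counterfactual mix is mBMS-heavy with a modest per-decision TKR
  share) and the published lifetime surgery counts.
* **Repair success**: a successful intervention closes the defect to
  0 cm2 until its failure time; failure restores the original defect
  size (configurable to re-sample) and a re-intervention follows after
  a 0.35-year scheduling delay (configurable).
* **Replacement pathway**: a failed PKR leads to TKR (waiting, in the
  "before second replacement" state, until the age window opens); a
  failed TKR to at most one revision (age <= 80); a failed revision to
  the terminal "no further replacement" state. TKR and revision carry a
  perioperative death risk interpolated linearly in age from 0.0449% at
  55 to 0.11% at 80.
* **Common random numbers**: each patient owns deterministic
  substreams (derived from the root seed and patient id by an integer
  mixing function) for death age, failure quantiles, policy draws and
  perioperative Bernoullis; both scenarios consume identical streams,
  and the k-th intervention uses the k-th failure draw, so paired
  differences isolate the policy effect. Adding patients never
  perturbs earlier patients' draws.

Time is continuous; there are no cycles and no half-cycle corrections.

## QALYs, costs, discounting

Between events a patient occupies exactly one health state; utility
weights per year follow the NICE appraisal schedule: 0.65 symptomatic
before a repair (0.62 when only a replacement remains, 0.56 when
symptomatic after a replacement), 0.76 in the first year after a
cell-based repair and 0.82 thereafter, MF benefit decaying back to 0.65
from year 5, 0.78 after a successful replacement, and 0.69 in the
absorbing "no further repair/replacement" states. Because the schedule
has no mBMS rows and mBMS is a marrow-stimulation technique (a
modification of microfracture), mBMS uses the MF schedule by default
(`economics.mbms_utility = "mf"`; the alternative `"aci"` reading is a
switch). Procedure costs are the DRG/EBM figures (M-ACI 11,000, MF
1,500, mBMS 3,500, PKR 6,000, TKR 9,000, TKR revision 15,000 EUR);
conservative therapy costs 800 EUR/yr while a patient is symptomatic
*awaiting* treatment -- not in the absorbing adapted states, whose 0.69
utility (above the 0.65 symptomatic weight) reflects living with the
condition rather than active therapy, and whose decades-long duration
would otherwise dominate lifetime costs.

Point costs at time $t$ are discounted by $(1+r)^{-t}$ (base case
$r = 2\%$/yr); continuous streams are integrated as annual slices
anchored at each state's start, each slice discounted at its start.
Lifetime discounted QALYs are reported; the reference study's printed
per-arm QALYs are read as lifetime discounted values (their follow-up
phrasing is ambiguous, and no 36-year truncation at 2% reproduces their
printed levels).

The ICER is the ratio of mean incremental discounted cost to mean
incremental discounted QALYs; the CEAC reports, per willingness-to-pay
threshold, the fraction of patients with non-negative incremental net
monetary benefit, and the dominant fraction counts patients with
strictly lower cost and strictly higher QALYs under M-ACI.

## Sensitivity analyses

`tornado()` varies each scalar parameter (all procedure costs, all
2-year failure rates, the conservative-therapy cost, and a single
multiplier on all utility weights, capped at 1) by +/-20% around the
baseline with the same cohort and streams, recording the ICER at both
extremes. `run_scenario_analysis()` applies arbitrary overrides; the
two shipped scenarios of interest are 4.5% discounting of costs and
effects, and MF eligibility extended to 5 cm2 in both scenarios.

## Numerical choices and degenerate inputs

* Weibull two-point fits reject equal times, survival outside (0,1),
  and survival increasing in time; calibration rejects long-term
  anchors that already exceed the 2-year failure rate at the given
  mixture weight.
* Zero-width strata are allowed and draw their single value; the
  mean-matching shift is iterated (up to 25 times) because clipping to
  stratum bounds erodes part of each shift; it stops within 0.5% of the
  target mean.
* A zero QALY difference yields an undefined ICER (`NA`), never an
  infinity; dominance quadrants are flagged separately.
* Death ages are capped at the life table's terminal age; death is
  placed uniformly within the death year and strictly after entry.
* The per-patient uniform block is fixed-layout (2 death, 48 failure,
  64 decision, 6 perioperative draws) with deterministic refills, so
  trajectories of any length remain reproducible.

## Problem sizes used by the shipped checks

The packaged acceptance protocol (`scripts/acceptance.R`) averages
10,000-patient paired runs over 30 seeds, the cohort size of the
reference study; the test suite exercises the same pipeline at 2,000
patients over 6 seeds, a size chosen so the whole suite runs in a few
minutes while keeping Monte-Carlo noise on cohort fractions below about
one percentage point.

## Known limitations

* The assignment-policy weights and long-term anchors are calibrated to
  published aggregate statistics, not estimated from patient-level
  data; they are the model's principal unverifiable inputs.
* Failure hazards are independent of age, sex and defect size, as in
  the reference model.
* The counterfactual mix cannot reproduce the published 24%/35% MF/mBMS
  primary shares *and* the guideline eligibility bounds simultaneously
  (only 13.6% of patients are MF-eligible at 2 cm2); eligibility wins,
  so the primary mix is mBMS-heavier than printed.
* New defects at other sites, bilateral knees, waiting-list dynamics
  and societal costs are out of scope.
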