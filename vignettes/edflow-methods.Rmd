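---
title: "Modeling low-acuity ED flow and testing-rate scenarios with edflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling low-acuity ED flow and testing-rate scenarios with edflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edflow)
```

## The modeling problem

Low-acuity patients (Emergency Severity Index 4 and 5) make up a large
share of pediatric emergency department visits, and providers differ by
roughly an order of magnitude in how often they order diagnostic testing
for them. Because tested patients occupy a treatment room for a long
testing-and-treatment interval and need a second provider contact before
discharge, the testing rate is a lever on the whole department's
throughput, not just on the tested patient's visit. `edflow` implements
a discrete-event simulation (DES) of a low-acuity track together with
the analysis pipeline that turns it into decision support: what would
happen to mean length of stay (LOS) and wait times if testing rates
moved from their current values to a benchmark derived from the
best-performing providers?

Two outcome definitions are used throughout. **LOS** is the time from
arrival to disposition. **Wait** is the time from arrival to the start
of provider evaluation. Both are reported in minutes as per-ESI means.

## The patient pathway

Each simulated patient flows through:

1. **Triage** — a nurse is seized for screening followed immediately by
   vital signs (one contiguous nurse service; triage nursing is a single
   encounter in practice).
2. **Rooming** — the patient queues for a treatment room; once one is
   free, a transfer-to-room delay moves them into it. The room is held
   from the start of transfer until bed cleaning completes after the
   patient leaves.
3. **Evaluation** — the patient queues for a provider. On the default
   (attending/NP/PA) path this is a single evaluation; on the optional
   resident path a resident evaluates first and an
   attending/resident review follows. The wait clock stops at the start
   of the first evaluation.
4. **Testing** — with a fixed per-ESI probability, the visit includes a
   combined testing-and-treatment delay (no separate lab or radiology
   resources), followed by a provider reassessment. Untested patients
   skip both and proceed straight to discharge.
5. **Discharge** — a nurse performs the discharge process; disposition
   is its end. Bed cleaning then releases the room.

All queues are FIFO and ESI-agnostic: the track serves only ESI 4/5 and
no prioritization between them is modeled. Nurses serve triage and
discharge from one queue; providers serve evaluations, reviews, and
reassessments from one queue. The event engine is written in C++ and is
fully deterministic given the pre-drawn inputs.

Routing choices that the published material leaves open — most
importantly whether vitals precede rooming — are fixed in the
`pathway_variant` flag of `pathway_config()`; the single implemented
variant performs screening and vitals at triage, before rooming, which
is consistent with the process ordering of the source tables and with
the wait definition ending at provider evaluation.

## Service-time distributions

`default_pathway()` carries one `dist_spec()` per process (minutes):

```{r}
for (nm in names(default_pathway()$specs)) {
  cat(format(nm, width = 28)); print(default_pathway()$specs[[nm]])
}
```

Parameter order follows the convention of the commercial simulation
tools in which such models are typically fitted: scale (or mean) first,
shape (or sd) second. Gamma(0.567, 4.9) is therefore scale 0.567, shape
4.9, mean 2.78 min. Lognormal specs are given as the arithmetic mean and
sd of the variate itself and converted internally to log-scale
parameters. The alternative (shape-first) reading is available as
`param_convention = "shape_first"`; for the gamma family the two
readings share the same mean, so the choice affects variances only.
Range-expanded beta specs (`2 + 28 × Beta(a, b)`) use `shift` and
`scale_mult`. Small negative shifts (−0.001), which arise from fitted
offsets, are handled by sampling, shifting, then clamping at zero; the
clamped mass for these specs is negligible, and `analytic_mean()`
documents that it ignores the clamp.

## Arrivals

Arrivals follow a non-homogeneous Poisson process with a
piecewise-constant rate per clock hour, repeated daily.
`default_arrival_profile()` constructs a smooth diurnal shape — a rising
half-cosine from the 05:00 trough to the 19:00 peak and a falling one
overnight — affinely mapped so the slowest and busiest hours run at 1.63
and 8.56 patients/hour, then bent by a single power exponent, solved
numerically at construction, so the expected annual volume is exactly
44,962 visits (35,838 ESI 4, 9,124 ESI 5; the ESI label is an
independent Bernoulli draw per arrival). Only the rate range and the
annual totals are published constraints; the shape between them is a
package default and fully overridable via `arrival_profile()`.

## Randomness, streams, and common random numbers

Every replication takes one integer seed. `stream_seeds()` spawns one
named sub-seed per source of randomness — the arrival process, the
testing decision, the resident assignment, and each of the eleven
service-time processes — and every patient's durations for *all*
processes are drawn up front. Two consequences:

* **Reproducibility**: identical seeds give bitwise-identical visit
  logs.
* **Common random numbers (CRN)**: the testing decision compares one
  uniform per patient against the testing proportion, so raising the
  proportion under the same seed only *adds* tested patients while
  every arrival time and service duration stays fixed. Scenario
  comparisons under `paired_streams = TRUE` are therefore
  variance-reduced and exactly monotone where the model is monotone.

Scenario experiments default to *independent* streams per arm, matching
the way the replication-based intervals treat arms as independent; CRN
is an option for direction checks, not the default inferential design.
Per-scenario seeds are keyed by scenario label, so results are invariant
to the order in which scenarios are listed.

A 7-day warm-up precedes the measured horizon of every replication:
the simulation starts empty, and discarding the first week removes the
initialization bias; patients arriving in the warm-up are simulated but
excluded from the visit log. The run is drained past the horizon so no
arrival is censored.

## Inference

Replication summaries feed a pooled-variance two-sample t interval
(`pooled_t_ci()`): with arm sizes `n_a`, `n_b` (replications or months),
degrees of freedom `n_a + n_b − 2`, and the pooled SD, the interval is
`d ± t · s_p · sqrt(1/n_a + 1/n_b)`. This construction reproduces, to
the printed decimal, both the 5-vs-5 replication comparisons and the
5-replication-vs-12-month administrative validation comparisons of the
study this package re-implements; the 12 arises from monthly aggregation
of a fiscal year. The published material never names its interval
method or the administrative sample size — this reconstruction is an
inference, adopted because it is exactly consistent with all eight
printed intervals, and it is flagged as such here. Display rounding is
half-away-from-zero to one decimal (`round_display()`); internal
arithmetic is unrounded. A LOS reduction of at least 15 minutes
(inclusive boundary; roughly 10% of a typical low-acuity LOS) is
flagged as clinically impactful. No multiple-testing correction is
applied, matching the source analysis.

## The achievable benchmark

The Achievable Benchmark of Care (ABC) is a pared mean over the best
providers. Testing is overuse in this setting, so the *desirable* event
is a visit without testing. Providers are ranked by the adjusted
performance fraction `(x + 1)/(d + 2)` of desirable events — a
shrinkage that keeps tiny denominators from dominating — and selected
from the top until they cover at least 10% of all visits (the
pared-mean convention; configurable). The benchmark testing rate is the
complement of the selected providers' aggregate untested rate. The
percentile scenarios (90th-percentile and highest-testing provider) use
the nearest-rank rule on unweighted provider-level rates, since no
percentile convention is published. Providers with few visits are
included by default (the shrinkage handles them); `min_visits` allows
exclusion. Because the underlying provider table of the original study
is unpublished, its printed benchmark rates (13.5% ESI 4, 4.2% ESI 5)
are treated as scenario inputs, not as quantities to re-derive.

## Synthetic data

`gen_provider_table()` stands in for the institutional provider
extract: provider testing rates are drawn from a lognormal on the rate
scale whose log-sd is set so the population p90/p10 ratio equals the
target spread (default 10-fold), redrawn if above 1, then rescaled so
the realized visit-weighted mean hits the target rate (defaults 22.5% /
11.9%); visits are allocated by a symmetric Dirichlet (concentration 2)
and tested counts are binomial. `gen_admin_monthly()` draws monthly
administrative LOS/wait means as normals around the fiscal-year values,
the assumption consistent with the reconstructed 12-month pooled-t
validation arithmetic. The distribution families here are invented
stand-ins — the real per-provider volume distribution and monthly
dispersion mechanism are unpublished — so passing tests demonstrate
pipeline correctness on data *with the stated summary structure*, not
fidelity to the original EMR extract: no case-mix, no seasonality, no
provider-volume/rate correlation.

## Calibration and the shipped defaults

The original model's resource counts and schedules are unpublished.
`calibrate_resources()` grid-searches integer counts (defaults: rooms
6–20, nurses 2–8, providers 1–6 — chosen to bracket plausible
low-acuity staffing) minimizing the summed squared relative error
against the four current-testing targets (mean LOS 156.8/133.3, mean
wait 87.6/85.1 for ESI 4/5), with common random numbers across
candidates and a 25% per-target miss declared a calibration failure.
The shipped `default_resources()` — 10 rooms, 2 nurses, 2 providers —
is the argmin of that objective under the default pathway and arrival
profile, evaluated at full replication effort (365-day replications).

Two properties of the calibrated model deserve emphasis.

* The fitted surface is close but not exact: about 148/127 min LOS and
  88/89 min wait. With three integer capacities, Table-quality service
  times, and a fixed diurnal profile, the reachable surface is coarse.
* **Constant capacities make the model more testing-sensitive than the
  system it emulates.** Reaching ~87-minute mean waits at this volume
  forces treatment-room utilization near criticality during the evening
  peak, and near criticality the queueing relief from lowering testing
  rates is steep: the simulated current-vs-benchmark differences (about
  29/22 min LOS, 19/18 min wait at the shipped defaults) exceed the
  published ones (19.1/10.9 and 8.9/7.4). The real department almost
  certainly absorbs part of its waiting in time-varying staffing and
  scheduling — which this package deliberately does not model (see
  Limitations) — leaving a large testing-insensitive waiting floor.
  Users comparing scenarios should read the model's differences as an
  upper-bound-flavored sensitivity under constant capacity, and the
  direction and ordering of scenario effects as the robust output.

## Provider impact reports

`provider_impact_report()` situates one provider against the panel
(rate, rank, percentile, visit share) and attributes the system-wide
current-vs-benchmark LOS difference `D` linearly:
provider `i` with visit share `w_i` and rate `p_i` is credited
`D · w_i (p_i − b)/(P − b)`, where `b` is the benchmark and `P` the
visit-weighted population rate. The linear form is a reporting
convention (the underlying response is not exactly linear in the
testing rate); its virtues are that a provider at the benchmark gets
zero and that credits sum exactly to `D`.

## Numerical choices and degenerate inputs

* Simultaneous events are ordered by scheduling sequence, which makes
  FIFO exact and the engine deterministic even with zero-duration
  services.
* Zero-rate arrival profiles are legal and yield empty logs; empty logs
  summarize to `n = 0` with `NA` means and are rejected by
  `utilization()` with a diagnostic.
* Busy fractions are capped at 1 (service can drain past the horizon).
* Ties in the ABC ranking are broken by provider id; the benchmark of a
  panel of identical providers is their common rate.
* `sd = 0` admin summaries are legal (all months identical); negative
  sds are rejected.
* Distribution specs are validated at construction, not at sampling.

## Problem sizes used by the tests

The shipped test-and-acceptance workloads are sized for a single CPU:
the scenario experiment runs 2 arms × 5 replications × 365 days
(~45,000 patients/year, about 1.5 s total); property checks use 10^5
Monte-Carlo draws per distribution, a 750-day M/M/1 run (>10^5
arrivals, 5% band against the closed form), 1,000 random pared-mean
instances against a brute-force oracle, and 100-seed generator
self-checks. These sizes are the package's chosen trade-off between
statistical resolution and turnaround.

## Limitations

* One track, constant resource counts: no dynamic staffing schedules,
  no high-acuity interaction, no admissions/boarding, no separate lab
  or radiology resources (testing is one combined delay — which, as the
  source analysis itself notes, tends to *understate* testing's true
  system impact even as constant capacity can overstate queueing
  sensitivity).
* No return-visit or missed-diagnosis modeling; changing testing rates
  in the real world has safety dimensions outside this model's scope.
* The validation-side administrative data are synthetic stand-ins;
  validation-style comparisons exercise the arithmetic, not the
  institution.
* Calibration recovers *an equivalent* constant-capacity configuration,
  not the original department's resources.
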