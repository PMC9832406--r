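---
title: "Exact multi-criteria scheduling of outpatient waiting lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact multi-criteria scheduling of outpatient waiting lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinicsched)
```

## The problem

Ophthalmology services carry long outpatient backlogs in which patients at
risk of irreversible sight loss can sit behind patients whose delay is
clinically harmless.  Manual booking typically works through the list in
referral order (longest wait first), which ignores clinical risk and the
distance patients must travel.  `clinicsched` treats booking as a
capacity-constrained assignment problem: given a waiting list, a calendar of
appointment slots per clinic per day, and a statement of what the service
wants to prioritize, it computes a provably optimal schedule.

Each patient $p \in \mathcal{P}$ carries

* $RTT_p \ge 0$ — referral-to-treatment time, the weeks already waited;
* a risk category, mapped to a score $R_p$ by a *risk weighting*
  (default $R1 = 1000$, $R2 = 10$, $R3 = 1$; see below);
* a distance score $D_{p,l} \in [1, 50]$ per clinic $l \in \mathcal{L}$,
  higher meaning the patient lives closer to that clinic.  It is a benefit
  score, not mileage: how a service converts real travel distances to the
  1–50 scale is a local policy decision and deliberately out of scope.

Clinics publish capacities $C_{l,t}$ for every day $t \in \{1, \dots, T\}$
of the planning horizon.  With binary variables $x_{p,l,t}$ indicating that
patient $p$ is booked at clinic $l$ on day $t$, the model is

$$
\max \sum_{p}\sum_{l}\sum_{t}
  \left( w_{RTT}\, RTT_p + w_D\, D_{p,l} + w_R\, R_p \right) x_{p,l,t}
$$

subject to

$$
\sum_{l}\sum_{t} x_{p,l,t} \le 1 \;\; \forall p, \qquad
\sum_{p} x_{p,l,t} \le C_{l,t} \;\; \forall l, t, \qquad
x_{p,l,t} \in \{0,1\}.
$$

The seven named objectives (RTT, D, R and their unweighted sums) are the
0/1 corners of the weight space; `objective_spec(weights = ...)` admits any
non-negative trade-off.  A subtlety in the uniqueness constraint: summing
only over days would permit one booking *per clinic*.  The package enforces
at most one appointment per patient across all clinics and days — the
reading consistent with a shared booking system and with the saturation
arithmetic of the case study (519 patients, 329 slots, 190 left waiting).

## Why the solution is exact

Every variable appears in exactly one patient constraint and one clinic-day
constraint, so the constraint matrix has transportation structure and is
totally unimodular: the LP relaxation has an integral optimal vertex, and a
network-flow computation yields the true ILP optimum.  Three methods are
provided:

* **`min_cost_flow`** (default).  Objective coefficients never depend on the
  day, so the day index can be aggregated away: patients are routed through
  a bipartite network onto clinics with capacity $\sum_t C_{l,t}$, plus a
  zero-profit overflow node for unscheduled patients, by successive
  shortest paths with node potentials (compiled code, 64-bit integer
  arithmetic).  Day cells are then filled deterministically.  The case
  study's 519-patient instance solves in roughly a second.
* **`lp_relaxation`**.  The literal slot-level LP, solved with the dense
  two-phase simplex in `boot`.  Every solution is asserted to be within
  `integrality_tolerance` (default $10^{-6}$) of binary before rounding —
  a live check of the total-unimodularity argument, not an approximation.
  Dense pure-R pivoting limits this route to a few thousand variables; it
  exists for cross-validation, not production.
* **`milp`**.  Branch-and-bound over the LP relaxation (branching on the
  most fractional variable, best-bound pruning).  Because the relaxation is
  integral it terminates at the root in practice; it guards against the
  pathological case and gives a third independent route.

Three oracles verify the solver in the test-suite: a greedy top-$K$
selection (exact whenever $w_D = 0$, because clinic-independent
coefficients make any $K = \min(|\mathcal{P}|, \sum C_{l,t})$ patients
packable), a pure-R Bellman–Ford min-cost-flow on the *slot-level* network
(different algorithm, granularity and language from the production solver),
and exhaustive enumeration on micro-instances (at most 8 patients/slots).
All routes must agree exactly; the randomized equivalence tests run over
200 micro-instances per suite execution.

### Numerical choices

Coefficients are scaled by $10^6$ and rounded to integers before entering
flow arithmetic, so all comparisons inside the solver are exact; inputs
with more than six decimals of precision are resolved at that granularity.
Coefficient magnitudes are capped at $10^7$ (an error asks the caller to
rescale weights) so that path sums stay well inside 64-bit range.  Ties
between alternative optima are broken deterministically: patients are
processed in ascending id (or input) order, and within a clinic the
earliest days are filled first.  The objective value reported to the user
is recomputed from the chosen assignments in double precision from the
original coefficients, so scaling never touches reported totals.

## The risk weighting

The three-tier Welsh eye-care risk classification is encoded as scores.
Candidate encodings differ across descriptions of the original tool, and
only $R1 = 1000$, $R2 = 10$, $R3 = 1$ is arithmetically consistent with the
published outcome table: a scheduled-risk total of 235,940 across 329 slots
decomposes only as $235 \times 1000 + 94 \times 10$, and the remaining-risk
total of 1648 across 190 patients only as $162 \times 10 + 28 \times 1$.
That is also the only candidate in which higher clinical risk gets the
higher score.  It is therefore the default, and [risk_weights()] enforces
$R1 > R2 > R3 > 0$ while letting services substitute their own values.
The same decomposition pins down the case-study cohort mix — 235 R1, 256
R2, 28 R3 (totalling 519) — which the published material never states
directly; `case_study_instance()` ships that composition.

With the default weighting, an R1 score of 1000 exceeds any combined
RTT-plus-distance contribution under the generator bounds
($104 + 50 = 154$), so under *any* objective containing the risk term no
R1 patient is ever displaced — the "no high-risk patient remained"
behaviour.  The same is intentionally *not* true between R2 and R3
(score gap 9): a long-waiting R3 patient may legitimately outrank a
fresh R2 patient under combined objectives, which is why the
scheduled-risk total of a combined objective can fall slightly below the
risk-only optimum.

## The synthetic generator

No patient-level data from the original service is available, so the
generator recreates the study conditions:

* **Cohort** (`cohort_spec()` / `generate_cohort()`): $n$ patients with
  risk composition given as exact counts or probabilities (default: the
  case-study proportions), RTT drawn uniformly from 1–104 weeks, and one
  distance score per clinic drawn uniformly from 1–50 (integers by
  default — the 1–50 "score" framing is discrete; a continuous mode
  exists).  The 104-week ceiling (a two-year backlog) is the package's own
  choice: it is a realistic worst case for a pandemic-era ophthalmology
  backlog and keeps RTT below the R1/R2 risk gap, preserving risk-first
  prioritization under combined objectives.
* **Calendar** (`calendar_spec()` / `generate_calendar()`): the true
  per-clinic split of the 329 slots was never published, so the default
  policy spreads the total as evenly as possible over all clinic-day cells
  (round-robin remainder, cells differing by at most one slot); an
  explicit matrix can be supplied.  A 6-week horizon defaults to
  $T = 30$ days (5-day working weeks; configurable).
* All draws are seeded and byte-reproducible.

What the generator does **not** emulate: the real (unpublished) RTT
distribution, any correlation between risk and waiting time, geographic
clustering of patients around clinics, within-day time slots, staff-absence
capacity variation, and no-show behaviour.  Consequently the tests
demonstrate correctness of the *optimization* — saturation counts, the risk
optimum, oracle equivalence are invariant to the synthetic draws — but
quantities that depend on per-patient values (e.g. the RTT-optimal total)
vary with the seed and are not asserted against the published figures.

## Rolling-horizon deployment

In practice the tool would run periodically — nightly or weekly — as
referrals accumulate.  `rolling_run()` simulates that loop: each period
solves the current list against a fresh copy of the calendar window,
removes the scheduled patients, ages the survivors' RTT by
`period_length_days / 7` weeks, and appends the period's new arrivals
(constant or Poisson counts, attributes drawn from a cohort template).
Two behaviours are design choices the deployment description leaves open:
carried-over patients must age (otherwise re-solving is meaningless), and
unfilled slots expire rather than roll forward (a clinic day that has
passed cannot be rebooked).  Capacity is stationary by default — the same
window every period — matching the assumption that staffing variations are
handled upstream.

## Problem sizes and runtime

The shipped tests solve the full 519-patient case study under all seven
objectives (about a second per solve), cross-check the solver against the
slot-level flow oracle up to ~80 patients and against exhaustive
enumeration on 200 random micro-instances, and exercise the LP and
branch-and-bound routes on instances up to a few hundred slot-level
variables; the whole suite runs in well under a minute on one core.  These
sizes were chosen as the smallest that exercise every guarantee; the
default solver itself scales comfortably to thousands of patients.

## Known limitations

* Appointments are resolved to a clinic and a *day*, not a time of day.
* Capacities are deterministic; sick leave and cancellations are out of
  scope, as is automatic re-booking of no-shows (re-run the tool with the
  missed patient back on the list).
* The distance score is taken as given; converting postcodes or travel
  times to the 1–50 scale is the caller's responsibility.
* `lp_relaxation` and `milp` are verification routes with a deliberate
  size guard; use the default flow method for real instances.
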