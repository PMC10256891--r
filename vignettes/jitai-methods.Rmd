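---
title: "Methods: the geofence-triggered support engine, the trial simulator, and the outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engine, simulator, statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitaitrial)
```

## The problem

Smoking lapses early in a quit attempt strongly predict full relapse, and
a large share of lapses are triggered by *distal cues* — the places where
a smoker habitually smokes. A just-in-time adaptive intervention (JITAI)
for cessation therefore wants to (i) learn, before the quit date, where an
individual smokes, and (ii) deliver brief support at the moment the
individual re-enters such a place during the quit attempt, when the window
for intervening on a cue-induced craving is minutes, not hours.

`jitaitrial` implements that decision logic as a deterministic, replayable
engine; wraps it in an agent-based simulator of a two-arm
app-versus-usual-care feasibility trial; and provides the statistics such
a trial reports.

## The engine

**Learning (training stage).** Each self-reported smoking episode carries
a location and situational context (urge 0–5, stress, mood, one of five
situations, presence of other smokers). Reports are clustered by a
nearest-centre rule: a report joins the nearest existing cluster whose
centre lies within the fence radius (ties to the earliest-born cluster),
otherwise it founds a new candidate. A cluster reaching
`min_reports_for_fence` reports (default 2 — a place where smoking is
"reported more than once") becomes a circular geofence. Each fence keeps a
per-time-of-day tally of its reports in 3-hour bins anchored at the start
of the delivery window.

**Triggering (committed stage, the 28-day challenge).** Location fixes
update a per-fence dwell tracker. A trigger decision is due when
continuous dwell first reaches `min_dwell_minutes` (default 5), and again
at every `redecision_interval_hours` (default 3 h) of continued presence.
A due decision fires only if all gates pass, evaluated in this order:

1. support has not stopped (before `support_stop_months` = 3 × 30-day
   months after the quit date);
2. the local clock is inside the active window (default 08:00–21:30,
   boundaries inclusive);
3. the fence's report tally in the current 3-hour bin reaches
   `trigger_threshold` (default 2) — this is the "frequency thresholds"
   mechanism; the deployed values are not public, so both the binning and
   the threshold are configuration;
4. no message already fired for this fence within the re-decision
   interval (cooldown);
5. in the maintenance stage, a decay gate (below).

**Maintenance decay.** For two further months message frequency halves
every month: a due, gate-passing decision in maintenance month $m$
($m = 1, 2$) fires with probability $0.5^m$. The Bernoulli draw comes
from a counter-based Lehmer stream keyed by the engine seed, the
evaluation minute, and the number of messages sent, so a replay of the
same event log is bit-identical while distinct evaluations get
independent draws. (Keying by message count alone — one reading of the
build notes — makes a failed draw absorbing until the next fired message
and drives the month-over-month ratio to 1/3 instead of 1/2; the
time-keyed counter preserves the intended halving.)

**Relapse and reset.** Strictly more than one reported episode per day on
two consecutive days is classified as relapse; the quit attempt can be
restarted at any time, which restarts the challenge, decay and stop
clocks while retaining learned fences and message history.

**Numerical conventions.** Distances are haversine on a 6,371,000 m
sphere; a point exactly on the boundary is inside. Fixes are treated as
exact (accuracy is only a simulator noise parameter). Dwell continuity
breaks on exit or on a fix gap exceeding twice the median observed fix
interval. All clock rules use the user's local timezone (one timezone per
log, carried in the configuration); day boundaries are local midnight.
The fence radius (100 m) is a design choice at typical urban geofence
scale — the deployed radius is not public.

## Message tailoring

Messages carry stage, situation and context tags plus a
behaviour-change-technique label. Geofence-triggered selection filters by
stage and the fence's modal situation, prefers the fence's dominant
elevated context (modal over its reports; ties urge > stress > mood >
others), and cycles without repetition until the eligible set is
exhausted. Bodies are placeholders: the deployed advice text is not
public, so only the taxonomy and the selection contract are modelled.
Profile statistics define `money_saved = days_quit × cigarettes_per_day ×
price_per_cigarette` — the artifact's definition, since no formula is
published.

## The simulator: what it emulates, and what it does not

A simulated smoker moves on a deterministic weekly template over four
labelled places (home, work, social, other) with Gaussian positional
noise; smoking reports before the quit date arrive at
Poisson(`cigarettes_per_day × adherence`) per day (population mean 15.4,
sd 7.1 cigarettes/day; heavy smoking ≥ 16/day and low socioeconomic
status at 29% prevalence are the two allocation stratifiers, allocated by
stratified permuted blocks of sizes {2, 4}).

After the quit date, each *entry into a place* is a cue exposure; a lapse
occurs with per-exposure probability `baseline_lapse_hazard`, multiplied
by `message_effect_multiplier` (ρ) if a support message fired for the
dwelt fence within the re-decision interval — the coverage window. A
lapse escalates to relapse with probability `relapse_given_lapse`. This
is the minimal mechanism that makes the engine's output matter; it is
*not* a validated behavioural model. Defaults (hazard 0.004, relapse
0.5, ρ 0.5) put the usual-care true 6-month prolonged-abstinence rate
near the level the trial's self-reports suggest (~14%).

Observation is then degraded by the trial's missingness structure, with
defaults taken from the published feasibility estimates: 75% install,
everyone who installs sets a quit date, log-normal engagement with median
10 days (sdlog 1.8 — the published quartiles (1, 31) are not jointly
log-normal-representable around a median of 10, so the heavy-tail/median
contract is what is matched), 77%/71% follow-up at 6 months/6 weeks,
abstinence misreporting at 5%, and saliva-kit return among self-reported
abstainers of 52% (app) vs 19% (usual care). Cotinine is drawn below the
10 ng/ml cutoff only for genuine recent abstainers, so misreporters are
exposed by the assay.

A green simulator test therefore establishes internal consistency — the
pipeline reproduces the rates it is configured with, the null behaves as
a null, seeds reproduce bit-identically — not behavioural realism: there
is no real human mobility, no pharmacology, and lockdown-era movement
reduction (which the trial itself experienced) is not modelled.

**Two execution paths.** `simulate_trial(engine_detail = TRUE)` runs the
decision engine in-loop for every engaged app-arm installer.
`simulate_outcome_cohort()` is a vectorised outcome-level implementation
of the same hazard and measurement model in which coverage of
engaged-period exposures is Bernoulli with `coverage_prob`; it exists
because repeated-trial calibration (500 trials of 2,000/arm) is far
outside what the event-level engine can do on one CPU. The two paths are
cross-checked on arm-level rates in the test suite.

**Null-effect calibration.** The type-I check sets ρ = 1 *and*
arm-symmetric saliva return. Under the defaults' differential return
(52% vs 19%) the observed validated outcome has OR ≈ 2.7 even when the
true effect is null — that differential is precisely the reporting bias
the trial's post hoc sensitivity analysis worries about, and it is
modelled deliberately; but a calibration of the estimator must put the
null in the observable, so the measurement is symmetrised there.

## The statistics

Outcomes follow the Russell-standard convention: prolonged abstinence
(≤ 5 cigarettes since quitting, none in the previous week) validated by
saliva cotinine < 10 ng/ml, with anabasine < 0.2 ng/ml additionally
required for nicotine-substitution users; withdrawn or missing counts as
smoking before any estimation.

Estimators, chosen to match the reporting conventions of the trial
literature and verified against the published values at printed
precision:

* **Odds ratios:** Wald on the log scale,
  $\exp(\ln\widehat{OR} \pm z_{\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$; zero
  cells are an explicit error (no continuity correction).
* **Risk differences:** Newcombe's hybrid score method — per-group Wilson
  limits $(l_i, u_i)$ combined as
  $\hat d - \sqrt{(p_1-l_1)^2+(u_2-p_2)^2}$,
  $\hat d + \sqrt{(u_1-p_1)^2+(p_2-l_2)^2}$. Plain Wald does not
  reproduce the published intervals; Newcombe does, exactly at 1 dp.
* **Proportions:** Wald by default (reproduces the published feasibility
  intervals); Clopper–Pearson for degenerate cells.
* **Chi-square:** Pearson without continuity correction, df = 1.
* **Bayesian exceedance:** flat prior on the log odds ratio, posterior
  $\mathcal{N}(\ln\widehat{OR},\ 1/a+1/b+1/c+1/d)$, upper tail beyond
  $\ln c$. This approximation does **not** reproduce the published
  90%/93%/85% (it gives 93/95/89); the originating method's prior is not
  specified in the text, so those values are documented as out of reach
  rather than fitted.
* **Logistic regression:** maximum likelihood by IRLS, convergence when
  the largest score component falls below 1e-8, with explicit
  (quasi-)separation errors instead of silently diverging estimates —
  the published adjusted model itself hit quasi-complete separation.

Display rounding is half-away-from-zero at the published precisions
(2 dp for ORs, 1 dp for differences, whole percent for feasibility
rates). One printed value is arithmetically irreproducible: the primary
unadjusted OR prints as 4.44 but computes to 4.43 at 2 dp, while its
95% CI (1.21, 16.21) reproduces exactly; the package reports the
computed value.

## Known limitations

* The deployed trigger thresholds, fence radius and message texts are
  not public; all are configuration with documented defaults.
* The movement template is deterministic; exposure variation enters only
  through event-level randomness.
* The behavioural effect mechanism (multiplicative hazard in a 3-hour
  coverage window) is an identification device, not an estimate.
* Exact conditional (adjusted) inference and the original Bayesian
  method are out of scope; `logistic_fit` provides the generic adjusted
  machinery only.
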