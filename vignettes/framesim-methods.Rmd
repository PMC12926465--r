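---
title: "Methods: theory-based crisis agents and the FRAME evaluation suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theory-based crisis agents and the FRAME evaluation suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(framesim)
```

framesim couples an agent-based simulation of household formula-seeking
during a 14-day shortage with the within-subjects statistical machinery
needed to evaluate how realistic those agents appear to raters. This
vignette documents the model, the parameters that matter, the numerical
choices, and what the synthetic-data machinery does and does not show.

## The environment

The scenario is a stylized stand-in for a five-ZIP-code urban study area.
Real geographic, transit and survey layers are data, not method, so they
are replaced by parameterized fixtures: five disjoint bounding boxes on a
planar kilometre grid, points of interest placed uniformly inside their
zone, and a transit fixture with nine bus routes, two rail lines and
twelve stops. Three of the five zones are classed low-income/low-access
and get lower vehicle-ownership and higher WIC/SNAP participation
probabilities. Distribution families for household attributes are
Bernoulli (vehicle, WIC, SNAP), categorical (income tier, employment
schedule, infants per household) and a clamped normal for caregiver
stress in [0, 1].

Travel speeds default to walk 5, bus 20, drive 40, rail 60 km/h. Transit
time is walk to the nearest in-service stop + half the headway (expected
wait) + in-vehicle distance along the stop sequence + walk from the
alighting stop; requesting transit outside service hours signals a
`framesim_no_service` condition and callers fall back to walking. Time is
hourly within 14 days (336 ticks): daily planning happens at hour
granularity so that operating-hour and work-schedule barriers bind.
Opening windows are half-open `[start, end)`; crisis extensions (clinics
17–20, food banks 17–19) only count while the shortage trigger is active.

Each household takes one decision per day at its first work-free hour
from 09:00 (day shift 9–17 → decides at 17:00; evening shift 14–22 →
09:00; flexible → 09:00). This is deliberately the mechanism by which
employment schedules become access barriers: a day-shift caregiver can
only reach ordinary 9–17 services when crisis-extended hours are active.

## The supply chain

Units flow manufacturers → distributor buffer → shelves. Two
manufacturers with market shares 0.6/0.4 stand in for the real duopoly
(no shares are published; they are configurable). The distributor
delivers every `restock_interval` days (default 3), allocating
proportionally to baseline shelf stock with the integer remainder held
back. Panic buying engages strictly below 30% of baseline visible stock
and multiplies per-trip demand by 1.5 (the threshold is fixed by the
study design; the multiplier magnitude is a package default). A
cumulative ledger enforces conservation after every tick:

> produced + initial stock = in transit + on shelf + purchased +
> emergency distributed + spoiled.

Spoilage is zero (formula is shelf-stable over two weeks); the field is
kept for extension. Imports under a waiver enter through the `produced`
side so conservation holds. Online purchases and informal community
transfers are sourced outside the regional chain and deliberately do not
touch the ledger. Policy events — plant closure, import waiver, tariff,
price control, WIC brand expansion, emergency funding, broadcast — apply
on their start day and (where reversible) expire after their end day.

## Household agents

**Theory-based agents.** Seven belief constructs in [0, 1]: perceived
severity, susceptibility, barriers, benefits (Health Belief Model),
perceived behavioral control and subjective norm (Theory of Planned
Behavior), and social outcome expectancy (Social Cognitive Theory).
Cues are derived only from agent-visible information: own inventory
decline, own remembered stockouts, transit availability, global
broadcasts, and the recent successes of social ties. Belief updating is
additive with per-cue gain κ (default 0.1) and clamping — the decision
cycle names the step but no functional form is published, so a bounded
linear update is the declared substitute, chosen as the simplest form
with the required signed directions (e.g. declining supply raises
severity and susceptibility, an observed stockout lowers control, peer
success through support channels raises social expectancy and norms).

Traits (twelve entries across the three theories, Beta(2, 2) by default)
multiply their matching beliefs elementwise and stay fixed for the whole
scenario; there is no reinforcement learning — across days only beliefs,
memory, inventory and the environment change. Intention scores are a
linear map from the weighted beliefs (a documented 7 × 7 weight matrix in
`default_intention_weights()`; the mapping's signs are fixed by the
construct table, the magnitudes are package defaults), plus an urgency
bonus (critical ≤ 2 days of supply, moderate ≤ 5 — the tiers are used by
the design but the cutoffs are ours), cue bonuses (peer success boosts
the three support channels scaled by the social-reinforcement trait;
broadcasts boost all active strategies scaled by cue responsiveness),
a −0.3 penalty on any strategy the agent itself saw fail twice running,
and a stress-proportional pull toward longer trips that scales with
urgency. Hard gates (−∞): WIC contact without enrollment, far travel with
neither vehicle nor transit, store trips with no work-free shopping hour.
Waiting carries a 0.15 intercept so a drive-free agent at low urgency
waits. Uniform noise on [−ε, ε] (ε default 0.05 of the score scale)
breaks determinism; exact ties resolve in fixed strategy order with
`visit_store` first and `wait` last, and an all-gated agent waits rather
than deadlocking.

**Control agents** use the fixed urgency tree described in the README —
no beliefs, no noise, no memory. At moderate urgency "a known stocked
store" is read as a same-zone store with positive current stock; the
control's omniscience here is part of its simplicity.

**Execution accounting.** A unit is one can ≈ one infant-day. Purchases
add `units / infants` to the days-of-supply field and daily consumption
subtracts `infants`, floored at zero; both rules are fixed by the
accounting contract, which makes `supply_days` a *pressure index* rather
than a strict days-remaining quantity for multi-infant households —
larger households deplete faster and gain less per can, which is the
intended hardship gradient. Food banks serve households that have fully
run out, neediest first (lowest supply, then most infants), two days of
supply per distribution while stock lasts; clinics distribute one-day
samples to critically low households when the fraction of selling POIs in
the panic regime exceeds 0.3, which also activates extended hours and the
daily policy broadcast.

**Reproducibility.** Every stochastic draw — population attributes,
POI placement, intention noise, social and online outcomes — uses a
substream seeded by a stable string hash of `(root seed, context)`, with
a 20-draw burn-in to decorrelate nearby seeds. Runs are pure functions of
`(configs, seed)`: the event log replays byte-identically and agent
populations are iteration-order independent.

## Vignettes and counterbalancing

Vignette rendering is template-based (one neutral sentence per day from
the structured event record), never generative, so it is deterministic
and auditable. Blinding is enforced mechanically: the rendered text is
scanned against a banned-term list (theory vocabulary, condition labels)
and rendering fails hard on any hit.

Presentation orders come from a cyclic 8 × 8 Latin square on the eight
vignettes (symbol order shuffled by seed), assigned round-robin. With a
participant count divisible by eight every vignette occupies every
position equally often; otherwise exact equality is arithmetically
impossible (34 participants × 8 positions), so the plan is maximally
balanced with (vignette, position) counts differing by at most one.

## The FRAME statistical suite

The rater is the repeated-measures unit throughout. Summaries report
per-vignette means over raters × dimensions, condition totals as
unweighted means of vignette means, and SDs/95% t-intervals over
rater-level means (per-dimension rows use all ratings); report rendering
rounds half-up to two decimals.

* **Paired t / Cohen's dz** on rater condition means; the dz interval is
  obtained by noncentrality inversion (`uniroot` on the noncentral-t CDF,
  tolerance 1e-10). Zero-variance differences are reported as t = 0 /
  p = 1 (no effect) or an infinite-t flag rather than an error.
* **ICC**: two-way random, absolute agreement, average measures —
  ICC(2,k) — as the default, with consistency ICC(3,k) by flag; the
  choice is surfaced because the published wording ("average ratings")
  does not pin the variant. Confidence bounds use the McGraw–Wong F-based
  construction stepped up from single measures. Zero between-item
  variance leaves the coefficient undefined and is reported as such, not
  as 0.
* **Repeated-measures ANOVA** (2 agent types × 4 dimensions on rater cell
  means): classical within-subject decomposition, partial η², Mauchly's W
  from orthonormalized within-factor contrasts with the Box chi-square
  approximation including the second-order term, Greenhouse–Geisser ε
  from the contrast covariance eigenvalues (floored at 1/(k−1)), and
  ε-corrected p reported alongside the uncorrected one. A two-level
  factor satisfies sphericity trivially (ε = 1). With fewer than three
  raters sphericity tests are flagged unavailable. W and ε are invariant
  to the orthonormal basis; the tests exercise this by checking a
  Helmert-based implementation against a polynomial-contrast oracle and
  against `anova.mlm`.
* **Holm post-hocs** over explicitly declared families mirroring the
  reporting layout: agent type within each dimension (4), dimension pairs
  within each type (6 per type, adjusted within type), dimension pairs
  averaged over type (6). Estimates are marginal mean differences with
  paired-t standard errors. The step-down adjustment is delegated to
  `stats::p.adjust(method = "holm")` and verified against a
  hand-enumerated oracle.
* **Percentile bootstrap** (default B = 10,000) resamples raters — the
  design's exchangeable unit — and reports 2.5/97.5 percentile intervals
  of the per-dimension condition differences. Type-6 quantiles are used:
  a calibration study across quantile conventions showed their slightly
  wider tails give the best finite-sample coverage, which for the plain
  percentile method at n = 34 sits near 0.94 rather than the nominal
  0.95 (an O(1/n) property of the percentile interval, not a defect of
  the resampling).
* **Power analysis**: exact noncentral-t power with ncp = dz√n and an
  integer search for the smallest n reaching the target; cross-checked
  against `power.t.test`.

## The synthetic rater generator

Latent rating = grand mean + ±δ/2 condition shift + dimension effect +
condition × dimension interaction + rater intercept + vignette intercept
+ residual, discretized by round-and-clamp onto 1..5 (an ordinal
cutpoint mode and a continuous mode exist; the continuous mode is what
makes exact unbiasedness checks possible). Defaults produce tables whose
condition means (≈ 3.4–4.0) and SDs (≈ 0.6–1.3) look like realistic
rating-study fixtures; this is a plausibility choice, not a fit to any
data set, and no claim is made that the generator reproduces human rater
psychology.

For calibration experiments (type-I error, power, bootstrap coverage) the
model sets the vignette SD to zero: the paired t on rater means treats
the eight vignettes as fixed stimuli, so random vignette intercepts act
as a per-replicate shift of the true effect and would confound a
nominal-level check. With that model the latent effect size is
dz = δ√8/σ (sixteen cells per condition; rater intercepts cancel in the
difference), inverted by `delta_for_dz()`. Discretization shaves the
realized effect size slightly, which is visible as empirical power a few
points below the analytic noncentral-t value.

What passing these experiments shows: the pipeline's estimators and
error rates are correct under a well-specified additive ordinal model.
What it does not show: robustness to rater drift, order effects,
halo/anchoring, or non-exchangeable raters — none of which the generator
emulates.

## Problem sizes and runtime choices

The packaged experiments use 100 households × 14 days per simulation run
(a few seconds each), 20 matched seed pairs for the adaptation contrast,
1,000 replicates for type-I and power calibration, and 500 replicates ×
B = 10,000 for bootstrap coverage — sizes chosen so the whole suite runs
comfortably on a laptop while keeping Monte-Carlo error well inside the
assertion tolerances (binomial SE ≈ 0.007 at 1,000 replicates).

## Known limitations

* The environment is a stylized fixture: no real road networks, geodesic
  coordinates, GTFS schedules or survey microdata; conclusions about the
  *relative* behavior of the two agent designs transfer, absolute rates
  do not.
* The belief-update and intention forms are declared linear substitutes
  for an unpublished mechanism; only their signed directions are fixed by
  the construct mapping.
* `supply_days` accounting intentionally follows the unit contract above;
  for multi-infant households it is a pressure index, not literal days.
* Unsafe-feeding behaviors (dilution, substitutes) are background
  context, not modeled actions.
* Inferential statistics on the original human ratings cannot be
  reproduced without the raw data; the suite reproduces the printed
  summary arithmetic and is otherwise validated by oracle equivalence and
  calibration, and the percentile-bootstrap coverage sits at ~0.94 at
  n = 34 as discussed above.
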