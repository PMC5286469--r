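---
title: "Window-anchored network inference: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-anchored network inference: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingrn)
```

This vignette is the package's own account of the science: the model
fitted inside each window, the thresholds that matter and why they have
the defaults they do, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The within-window model

A window holds three genes. Every candidate regulatory relationship is a
linear ODE cascade: a root gene A driven by an external input follows

$$\frac{dA}{dt} = U(t) - k_{\mathrm{self}} A,$$

and a regulated gene follows

$$\frac{d(\mathrm{target})}{dt} = \sum_{\mathrm{regulators}} k_{\mathrm{reg}}\,
\mathrm{regulator} \;-\; k_{\mathrm{self}}\,\mathrm{target} \;-\; D,$$

with a constant removal term $D \ge 0$. The input is either a
time-invariant constant or the three-parameter sigmoid
$U(t) = u_{\max}/(1 + e^{-(t - t_{1/2})/\theta})$, the minimal form that
produces a delayed onset. State variables are *relative* expression: all
data are normalized so each gene's maximum over time (and perturbation
series) is 1, so rates are in hr⁻¹ on that unit-max scale.

Two modelling conventions deserve emphasis because the behaviour of the
whole method depends on them:

* **States are clamped at zero.** Expression cannot be negative; without
  the clamp, a removal constant would drag an unexpressed gene below zero
  before its regulator rises. With it, $D$ acquires a mechanistic
  meaning: the target stays silent until
  $k_{\mathrm{reg}}\cdot\mathrm{regulator}(t) > D$, which is exactly the
  delayed-onset (lag) phenomenology the hierarchy step relies on.
* **Regulation rates are unbounded in sign.** The equations are written
  in stimulating form, but the fitter may return a negative rate, which
  is reported as an inhibitory edge. Self-degradation rates, removal
  constants and input levels are constrained nonnegative; all rates are
  boxed at 10 hr⁻¹, far above the 0.02–0.3 hr⁻¹ range that unit-max
  expression kinetics actually produce.

The structure library per window is: the two single-edge relationships
from the top gene, parallel fan-out, the two serial orders, convergent
fan-in (two inputs, one sink), and the null relationship that adds no new
edges. The exact membership of the library is one of the genuinely open
design points; the library is config-extensible (`structures` in
`grn_config()`), and single-edge candidates are included because the
all-or-nothing multi-edge structures otherwise force a false edge to ride
along with a true one whenever only half of a fan-out is real. In
migrated windows, candidates are restricted to edges incident to the
incoming gene — all acyclic combinations of the lag-admissible ones —
with previously inferred edges riding along as fixed topology (rates
refit by default; freezable via `refit_inherited`). Regulators that lie
outside the window enter as fixed forcing trajectories, interpolated from
the observed samples by a monotone spline on a fine grid: a coarser
interpolation is measurably worse than an integrated state, and the
difference is enough to distort model comparisons.

Each candidate is offered with constant inputs, with sigmoid inputs, and
(when only some roots show positive lags) the mixed form. The BIC
arbitrates: a sigmoid costs two parameters more than a constant, so it
survives selection only when the delayed onset is real.

## Fitting and selection

Parameters are estimated by bounded Levenberg–Marquardt least squares
(`minpack.lm`) on the stacked residuals of all three genes, jointly over
perturbation series with shared parameters. Initial conditions are the
observed $t = 0$ values. Five starts are used: one data-driven start
(sigmoid half-times placed at the observed onset of the root's own
trajectory — generic starts routinely miss sharp onsets and handicap
models that deserve to fit) and four seeded log-uniform jitters, every
third of which flips the sign of regulation-rate starts so inhibitory
optima are reachable. Multi-starting stops early once a fit reaches an
essentially perfect SSE (`sse_early_stop`, default 1e-10). In piloting,
larger multi-start budgets never changed a selection outcome; they only
multiplied runtime. Standard errors come from the Jacobian-based
covariance at the optimum.

A fit of a root gene in one series of a multi-perturbation dataset uses
the data to decide whether that root's input is active there: a root that
is identically zero in a series has its input switched off in that
series. Without this, joint fits of perturbation data are meaningless —
and it is the perturbation contrast that makes convergent fan-in
identifiable at all: from a single series, a regulator that has already
saturated is mathematically indistinguishable from a constant removal
term.

Candidates are compared with the SSE-form information criterion

$$\mathrm{BIC} = \frac{\sum_i \mathrm{SSE}_i}{\tau} + p_{\mathrm{total}}\,\ln n,$$

exactly as printed above (the score divides by $\tau$, not $\tau^2$; the
discrepancy with the Gaussian $-2\ln L$ form is inherited deliberately and
documented rather than "fixed"). Two numerical choices matter here:

* **τ is the pooled residual SD of the window's best-fitting candidate**,
  floored at `tau_min = 1e-3` on the unit-max scale. The best fit gives
  the least upward-biased estimate of the measurement error; estimating τ
  from single-gene input+decay fits instead would fold model error into
  the scale (a cascade-driven gene is not an input+decay gene), inflate τ
  on clean data, and flatten every contrast until the null wins
  everywhere. All candidates in a window share one τ so their scores are
  comparable; the floor stops noiseless data from collapsing the scale.
* **New edges must beat the null by more than `delta_bic_min = 2`** — the
  conventional "positive evidence" threshold. This is not decorative. A
  regulator–target edge describes its target with one parameter fewer
  than the null's free-input description, so accepting on any strict
  improvement admits every wrong edge whose misfit stays below one
  parameter's worth of BIC; such parsimony artifacts then cascade,
  because a falsely regulated gene loses its root status and corrupts
  later windows. Exact ties break by fewer parameters, then structure
  name, so selection is invariant to candidate ordering.

Accepted edges with a fitted |rate| below `min_rate = 0.005` hr⁻¹ are
dropped as kinetically negligible: multi-edge library structures
otherwise carry a zero-rate edge alongside a real one.

## Lags, hierarchy, and zones

A gene's lag is the earliest time point after which expression rises (or
falls) for at least two consecutive steps, each exceeding `lag_delta`
(default 0.05) of the trajectory's range — a relative threshold, which is
scale-free on unit-max data. The wording "ends at the time point after
which expression increases" is ambiguous between that point and its
successor; the earlier reading is used, which reproduces a 6 h lag for a
gene flat over [0, 6]. With several series, a gene's lag is its earliest
activation over the series.

The hierarchy rule is that a regulator activates strictly before its
target: the ordered pair $(g_i \to g_j)$ is admissible iff
$\mathrm{lag}(g_i) < \mathrm{lag}(g_j)$ (a positive `min_gap` makes the
required separation explicit; "noticeably different" is not otherwise
quantified). Genes that never activate can only be targets. When no pair
is admissible, the window has no usable lag differences: the menu is
unconstrained and the top gene is chosen by single-gene SSE instead —
note this recovers edges between equal-lag genes only through fit
quality, which is exactly the regime where this family of methods is
weakest. Absolute |ρ| is used for ranking closeness in the correlation
steps (an inhibitory partner is as "close" as a stimulating one); the
signed value is retained for reporting.

Activation zones in the final network are the distinct lag values in
ascending order; genes that never activate form a final zone of their
own.

## The synthetic-data generator

The generator exists so the whole pipeline is testable without external
downloads. It integrates a ground-truth cascade (DAG, constant/sigmoid
inputs, per-gene self-degradation and removal constants) from a zero
initial state per perturbation series, samples the canonical uneven grid
0, 6, 12, 24, 48, 72, 96, 672 h, adds seeded Gaussian noise scaled by
each gene's signal amplitude, clips at zero, normalizes to unit max, and
rounds to a measurement resolution of 1e-6 — sub-resolution expression
reads as zero, as on a real array, which is what gives delayed genes
their exactly-flat prefixes and keeps Spearman ranks informative.
(Noiseless smooth monotone trajectories would otherwise all have rank
correlation exactly 1, and the correlation-guided window machinery would
be flying blind.)

What it deliberately does **not** emulate: feedback loops (the method is
built for feed-forward cascades), nonlinear (Hill/mass-action)
regulation, stochastic expression, and measurement designs other than
shared time grids. Passing tests on this generator therefore show that
the pipeline recovers networks *whose kinetics match its model family
and whose lags are separable on the sampling grid* — not that it succeeds
on arbitrary real data. The fixtures encode that regime explicitly:

* `scenario_adipo7()` — seven genes, two sub-cascades under a constant
  and a sigmoid input, five edges. Its kinetics were designed against
  the identifiability structure of the grid: every onset sits inside the
  densely sampled first 48 h where possible, sibling genes are leaves in
  distinct lag groups, the constant-input root decays slowly enough to
  keep rising across the window (a regulator that saturates early is
  indistinguishable from a step input and would invite spurious edges),
  and the sigmoid root's rise is anchored by the 48 h sample. Noiseless,
  this fixture is recovered exactly, end to end.
* `scenario_dream10()` — ten genes, eleven edges, two perturbation
  series with the root inputs split between them, mild noise. At that
  noise level the positive-evidence acceptance gate favours specificity
  heavily; sensitivity is reported, not asserted.
* `scenario_structure()` — randomized three-gene scenarios per library
  structure, used for the structure-recovery rate. The convergent
  scenario ships two perturbation series because the fan-in is not
  identifiable from one (see above), and keeps both parents varying
  while the sink rises.

`sample_random_dag()` draws removal constants as a fraction (0.35–0.8) of
each target's steady-state drive, walked in topological order. Drawing
them from an absolute range independent of drive silences roughly half of
all cascade genes, which makes a fixture useless.

## Degenerate inputs and numerical notes

Missing values are a hard error (the fits need complete series); constant
genes get zero correlation with a warning and are excluded from
windowing; all-zero genes are left unnormalized with a warning. The
integrator is a fixed-order RK4 with a step that starts small, grows
geometrically as the transient relaxes, is capped by the self-degradation
stability limit, and is refined across the steep part of any sigmoid
input; it matches closed forms of the linear system to better than 1e-6
on the canonical grid and agrees with `deSolve` to the same tolerance on
random cascades. Integration failures surface as infinite SSE, never as
exceptions that abort selection. A hard cap of `5 × N` windows guards
pathological correlation structures; the migration loop otherwise runs
until no lineage can reach an unvisited triple. `n` in the BIC counts
observations per gene pooled across series.

## Known limitations

The method cannot orient or even detect edges between genes with
identical lags except through fit quality; it assumes feed-forward
structure and will not find feedback; convergent regulation needs
multi-perturbation data; and on an eight-point grid, genes activating
after the second-to-last sample carry too few informative points for any
model comparison to be meaningful — their regulation is decided by
parsimony, not shape. Under realistic noise the acceptance gate trades
sensitivity for precision, which is the regime this family of approaches
targets (few, well-supported edges rather than dense rankings).
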