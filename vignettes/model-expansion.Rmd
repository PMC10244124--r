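---
title: "Confidence-layered expansion of ODE signaling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-layered expansion of ODE signaling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odexpand)
```

## The problem

Mechanistic ODE models of signaling networks are small — a few dozen
states built and validated over years — while phosphoproteomic time
series cover thousands of sites. `odexpand` bridges the two scales: it
starts from a trusted core model and grows it outward, one phosphosite
at a time, attaching each site to the existing model through a small
kinetic motif whose agreement with the site's replicate time series is
judged by a chi-squared test. Because sites are attached in sweeps of
adjacency under a prior-knowledge interaction graph whose edges carry a
confidence grade (the number of primary literature sources), the result
is a *layered* model: early layers rest on the most trusted
interactions and data, later layers on progressively weaker evidence,
and purely data-driven additions come last. The expansion is strictly
feed-forward — an added site receives inputs only from the core or from
earlier layers — so the core's dynamics are never perturbed by the
additions.

## Model agreement and the acceptance gate

Agreement between a simulation $\hat{y}_t(\theta)$ and data is the
normalized sum of squared residuals

$$v(\theta) = \sum_t \left(\frac{y_t - \hat{y}_t(\theta)}{\mathrm{SEM}_t}\right)^2,$$

with $y_t$ the replicate mean and $\mathrm{SEM}_t$ its standard error.
Under additive Gaussian noise this is a chi-squared statistic, and a
candidate is **accepted** iff $v^* < \chi^2(\alpha=0.05,\,df)$. The
per-site gate defaults to $df = 8$: with the 9-point reference sampling
grid (0–60 min) this is points minus one. Whether one should instead
correct for the number of fitted kinetic parameters is a genuinely open
choice; we expose `df` in `expand_config()` and keep 8 as the default.

`filter_sites()` implements the upstream data rule: any site with fewer
than two replicates at any control time point is excluded, then means
and SEMs are computed. SEMs below a floor
(`max(1e-6, 5% of the site's mean range)`) are raised to the floor —
zero-variance replicates would otherwise give infinite weights, a case
the cost function cannot meaningfully handle.

## The kinetic motifs

Each site is a two-pool (or three-pool) fraction model driven by frozen
upstream trajectories $u(t)$, with all pool fractions summing to one:

| family | ODE on the phosphorylated fraction $P$ | kinetic parameters |
|---|---|---|
| `phos` | $\dot P = k_u u (1-P) - k_{ret} P$ | 2 |
| `dephos` | $\dot P = k_b (1-P) - k_u u P$ | 2 |
| `satphos` | $\dot P = k_u \frac{u}{K_m + u}(1-P) - k_{ret} P$ | 3 |
| `phos2` | $\dot P = (k_1 u_1 + k_2 u_2)(1-P) - k_{ret} P$ | 3 |
| `dephos2` | $\dot P = k_b (1-P) - (k_1 u_1 + k_2 u_2) P$ | 3 |
| `phosdephos` | $\dot P = k_1 u_1 (1-P) - (k_2 u_2 + k_{ret}) P$ | 3 |
| `extra` | $U \to P \to S \to U$ with drive $k_u u$, transition $k_{tr}$, return $k_{ret}$ | 3 |

These are the minimal mass-action forms honoring a fixed parameter
budget: one parameter per input plus a single return parameter (the
saturated variant adds a half-saturation constant, the secondary-state
chain a transition rate). The secondary state captures
overshoot-and-return kinetics such as receptor internalization.

Given $u(t)$, every family is *linear* in the pool fractions. The
integrators in `src/motif_step.cpp` exploit this: coefficients are
frozen at substep midpoints and each substep is advanced with the exact
exponential update (scalar families) or the exact 2×2 matrix
exponential (secondary-state chain). This is unconditionally stable —
rate constants up to the 1e4 bound cannot blow up the step — and costs
microseconds per trajectory, which matters when hundreds of thousands
of candidate evaluations run in a single expansion. The default grid
subdivides every data interval into at least 4 substeps of at most
0.5 min; against an adaptive solver at tolerance 1e-10 the error is
below 2e-3 on the reference grid, far below the replicate noise the
fits work against.

### The observable mapping

Phospho data are on an arbitrary fold-change scale, so a site's
observable is $y = a P + b$. Both mapping parameters are profiled out
of every cost evaluation in closed form (weighted least squares), with
the slope clamped to $[0, 100]$; keeping $a \ge 0$ preserves the
direction semantics of the motif families (a phosphorylating input must
not explain decreasing data through a sign flip). We initially fitted
$a$ as a free optimizer dimension and profiled only $b$, but the
optimizer then stalled on degenerate ridges (large-$a$, flat-$P$
solutions) even on noise-free recovery fixtures; profiling both
parameters removed the failure mode entirely and cut the search space
to the 2–3 kinetic parameters.

## Parameter fitting

`fit_global()` is a population global search (differential evolution,
rand/1/bin, F = 0.7, CR = 0.9) with an L-BFGS-B polish of the
incumbent, under a hard budget of objective evaluations. Kinetic
parameters are searched in log10 space over $[10^{-4}, 10^4]$.
Per-motif fits default to 2000 evaluations split over 3 restarts;
everything is deterministic given the seed, and per-site seeds derive
from the master seed plus a stable hash of the site name, so results do
not depend on scheduling or on which other sites are present.

## Prediction uncertainty

The uncertainty of a prediction $\hat p$ (an observable at a time
point) is the interval attainable while the model still agrees with
data: minimize (and maximize) $\hat p$ subject to
$v(\theta) \le \chi^2$. The constraint is relaxed into the objective as
a penalty, $|\hat p| + |\hat p(\theta^*)| \cdot (1 + |v(\theta) -
\chi^2|)$, added whenever the constraint is violated; maximization runs
on the sign-flipped objective. The penalty scale $|\hat p(\theta^*)|$
is taken per time point. The best-fit parameters are injected into
every search population, so the feasible set is never empty and the
returned envelopes always contain the best-fit trajectory; returned
optima are additionally re-checked for feasibility before they can
tighten an envelope. On a one-parameter decay model the envelopes match
a dense grid scan to ~0.1%. For composite datasets the default
threshold is the full-dataset chi-squared limit; `v* + 3.84` (a cost
increase of one degree of freedom) is a supported alternative the user
can pass explicitly.

## The expansion loop

Within one *sweep*, the engine finds all unadded sites whose protein is
targeted by an edge (at or above the current confidence level) from a
protein already in the model, and tests them independently in a
seeded random order against trajectories frozen at the start of the
sweep — this is what makes the per-site tests embarrassingly parallel
and the layer composition independent of scheduling. Per site, edges
are tried in canonical order (descending confidence, then source name):
first the three single-input families (the lowest-cost family is kept;
the first accepted edge wins), then — only if all singles fail — the
dual-input families pairing the best rejected single edge with every
other candidate edge, then the secondary-state chain. Ties in cost
within 1e-9 go to fewer parameters, then to the family order above.
Accepted sites form a new layer; their trajectories are then computed
once and frozen. Sweeps repeat at a level until nothing is accepted,
then the level descends. Previously tested (site, edge) combinations
are never refitted.

Phases run in order: responder sites only, then all sites, then a
data-driven phase in which each remaining site is offered the `top_k`
(default 3) included nodes whose affine-mapped trajectories fit its
data best — these data-driven edges rank below every prior-knowledge
confidence level. Edge signs, when present, restrict the families
tested (activating edges to phosphorylation-type, inhibiting to
dephosphorylation-type); unsigned edges get all families.

When one protein carries several added sites, adjacency is evaluated at
the protein level and the earliest-added site node stands in as the
protein's canonical signal for downstream attachment; a core protein's
signal is its designated activity observable (the `[activity]` section
of the model format).

## Scenarios

Inhibitors are modeled as multiplicative *clamps* on a node's outgoing
influence (default factor 0.1; the degree of inhibition of a real
compound is unknown, so it is a configuration knob, and partial
inhibition is the conservative reading): the clamped state's value is
scaled wherever it appears in other states' rate expressions, and its
trajectory is scaled before it drives downstream motifs — the state's
own dynamics are not frozen. Predicted direction per site is the sign
of the relative change at 20 min, with changes below 1e-3 declared
unclear. Observed direction uses the inhibitor-minus-control difference
of means at 20 min with a one-combined-SEM interval; sites whose
interval spans zero, or with fewer than two inhibitor replicates, are
ignored and excluded from accuracy denominators. The type-2-diabetes
condition rescales initial values (receptor to 55%, GLUT4 pool to 50%
in the demo core) and optionally attenuates effect parameters in
$[0, 1]$, with kinetic parameters unchanged; the per-site readout is
the fold change versus the normal condition at 20 min.

## The demo core and time conventions

The shipped ~10-state core (`build_demo_core()`,
`inst/extdata/demo_core.txt`) is an illustrative adipocyte-like
network: insulin → receptor → PKB → GLUT4 translocation
(glucose-uptake observable); an adrenergic input → adenylate cyclase →
cAMP → HSL (lipolysis observable) and an exocytosis observable; and the
crosstalk arm PKB → PDE3B ⊣ cAMP. It deliberately does *not* reproduce
any published core model's equations or parameter values — it exists so
that expansion, scenarios and tests run end-to-end without external
inputs. Time is minutes everywhere, stimulus onset at t = 0; models are
pre-equilibrated for 1000 min with inputs off before stimulation
(standard steady-state initialization; a no-op for the demo core, whose
initial values are already at rest).

## The synthetic ground truth

`generate_truth()` builds the world the engine is benchmarked on: a
feed-forward network of (default) 30 phosphoproteins in 3 tiers rooted
at the demo core's insulin-responsive branch, each site simulated from
a randomly drawn motif family with kinetics in realistic ranges
(timescales of ~0.3–10 min), observed on the 9-point 0–60 min grid
with 3 replicates of additive Gaussian noise (sd = 5% of signal,
floor 0.01). True edges draw confidence counts uniformly from 5–20,
decoys (1:1 with true edges, never duplicating them, never pointing
downstream of their source) from 1–8 — the overlap forces the
confidence descent to matter. Nonresponder sites have
time-point-wise random means with the same replicate noise: data with
replicate-level precision but no smooth kinetic structure, which is
exactly what a sound gate must reject. An inhibitor block is generated
by clamping PKB to 0.1 and re-simulating.

What the generator does **not** emulate — mass-spec missingness, site
localization ambiguity, batch effects, correlated noise, feedback
edges — bounds what the benchmark shows: passing it demonstrates that
the machinery recovers planted structure under idealized sampling, not
that it would achieve the same operating point on real
phosphoproteomes.

Problem sizes used in the shipped checks: the recovery benchmark uses
the 30-protein default; the pure-noise control uses 50 sites × 2 decoy
edges (≥ 200 gated candidate tests); determinism is demonstrated on a
10-protein world; uncertainty calibration on a 1-parameter model
against an 8001-point grid scan.

## Worked example

```{r example, eval = FALSE}
library(odexpand)

tr <- generate_truth(truth_spec(n_proteins = 8, tiers = 2, seed = 11))
ex <- expand_model(tr$core, tr$dataset, tr$interactions,
                   expand_config(seed = 11))
score_recovery(ex, tr)

rep <- predict_inhibition(ex, condition(clamps = c(AKT1 = 0.1)),
                          tr$dataset)
rep$per_layer

t2d_propagate(ex, t2d_demo_condition())
```

## Known limitations

* Feed-forward only: sites whose dynamics depend on feedback into the
  core or earlier layers will be mis-modeled or rejected.
* Earlier-layer parameters are never re-estimated when later layers are
  added.
* The acceptance gate judges each site marginally; it does not control
  any family-wise error across thousands of tests.
* Upstream trajectories are frozen per layer, so uncertainty in an
  upstream fit does not propagate into downstream acceptance decisions.
* The SBML export (not bundled; the canonical format is the sectioned
  text file) would be lossy on observables by design.
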