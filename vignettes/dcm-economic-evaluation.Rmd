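---
title: "Methods: economic evaluation of vital-statistics data collection methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: economic evaluation of vital-statistics data collection methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmeval)
```

## The evaluation model

`dcmeval` treats the portfolio of data collection methods (DCMs) that a
country runs for vital statistics as a set of production units: each
converts an annual budget into vital-event records of some quality. The
evaluation proceeds in four stages.

**Quality.** An expert panel scores each DCM on a set of data-quality
criteria on a linear 0–10 scale. The criteria follow the standard
assessment framework for vital-statistics systems — accuracy, relevance,
consistency/comparability, timeliness, accessibility — plus, when the
government's long-term policy is a complete civil registration (CRVS)
system, a sixth criterion measuring whether the DCM builds towards or
undermines that goal. Scores are treated as continuous: consensus scores
are typically means of individual integer scores and are carried at full
precision, never re-rounded internally.

**Aggregation.** The score matrix collapses to one composite quality index
$Q_j \in (0, 1]$ per DCM by one of three methods:

- *Unweighted* (`unweighted_index()`): the mean criterion score, divided by
  the maximum mean across the evaluated DCMs so the best performer scores
  exactly 1. The division by the best mean (rather than by the scale
  maximum 10) is a deliberate design choice: it makes the index a relative
  measure within the evaluated set, is invariant to a common rescaling of
  the score scale, and guarantees the index bounds regardless of how
  generous the panel was.
- *Weighted* (`weighted_index()`): criterion weights fixed a priori,
  normalized to sum to one, then the same best-normalization. Equal weights
  reduce exactly to the unweighted index, which the test suite asserts.
- *Benefit of the doubt* (`bod_index()`): each DCM receives the weights
  most favourable to itself, from the linear program
  $\max_{w \ge 0} \sum_k w_k y_{jk}$ subject to
  $\sum_k w_k y_{ik} \le 1$ for every observation $i$. This is the
  multiplier form of an output-only CCR model with a unit input. Any DCM
  holding a strict maximum on some criterion attains index 1, so with a
  single consensus matrix of 9–10 observations the method barely
  discriminates — a property, not a bug, that the package surfaces rather
  than hides. Discrimination improves by pooling the individual expert
  matrices into the constraint set (`pooling = "pooled_experts"`), which
  multiplies the number of observations by the panel size. How the pooled
  per-DCM index should collapse the per-expert optima is genuinely open; we
  use the arithmetic mean of each DCM's per-expert optima, documented as a
  convention rather than a reproduction claim.

**Cost-effectiveness.** Each DCM's total annual cost is multiplied by an
apportioning fraction reflecting how much of the system serves
vital-statistics work (e.g. 25% of a census budget, 30% of CRVS). The
quality-adjusted data index $\mathrm{QADI}_j = Q_j \times q_j$ multiplies
quality by a quantity-of-data measure $q_j$, and DCMs are ranked by cost
per QADI. The product form for the QADI is the natural quality-adjustment
(analogous to quality-adjusted life years), and it is validated empirically:
from the bundled inputs it reproduces the published league tables of the
stylised example to four decimals.

**Efficiency.** `solve_dea()` computes radial DEA efficiencies
$\theta_j \in (0,1]$ under constant or variable returns to scale and either
orientation (output-oriented expansions $\varphi \ge 1$ are reported as
$1/\varphi$ so both orientations share the (0, 1] convention). The default
efficiency-analysis model in `efficiency_index()` uses the apportioned cost
as single input and the QADI as single output under CRS — chosen for
transparency: in that model $\theta_j$ is the QADI-per-cost ratio
normalized by the best DCM, so the efficiency ranking coincides *exactly*
with the cost-effectiveness ranking, which the suite asserts as a theorem
rather than a coincidence. Alternative output sets (quantity and quality as
separate outputs; quantity plus the raw criterion scores) are provided for
sensitivity analysis; no claim is made that any of them reproduces
externally published cost-efficiency indices, whose exact formulation is
not fully specified in the source material of the stylised example.

## Scenarios as first-class configuration

Rankings are highly sensitive to three policy switches, so they are bundled
in `scenario_config()` and echoed in every report:

| switch | Scenario A (CRVS policy) | Scenario B (no CRVS policy) |
|---|---|---|
| quantity metric $q_j$ | unit records (≈ sample size) | target population |
| CRVS evaluated | no | yes (30% cost apportioned) |
| criteria | six (incl. improvement) | five |

The bundled fixtures encode the stylised example of a hypothetical
low-income country of 33 million with ten candidate systems. Under A the
facility-based HMS ranks first and household surveys last; under B the
surveys come first. This rank reversal is asserted in the tests because it
is the central practical lesson: the evaluation's framing, not only its
data, drives procurement-relevant conclusions.

### Fixture precision

The fixtures store consensus scores as exact sixths (e.g. 2.3333…, not the
two-decimal 2.33 shown in printed tables), because the consensus of a
six-member panel scoring integers is a multiple of 1/6. This matters:
carrying the printed two-decimal scores changes the DHS cost-per-QADI in
the fourth decimal (8.4729 vs the correct 8.4740). All internal arithmetic
is at full double precision; rounding happens only at report time
(`report_precision`, default 4 decimals).

## The panel simulator

`generate_panel()` emulates a scoring panel of (by default six) experts.
Each (DCM, criterion) cell draws independently from a triangular
distribution specified by its mean and support $[a, b]$; the mode is
recovered from the triangular mean identity $c = 3\,\mathrm{mean} - a - b$,
and specifications whose implied mode leaves the support are rejected
rather than silently clamped. Sampling is by inverse CDF. Each cell uses
its own deterministic substream derived from the master seed and the cell
key, so editing one cell's specification never perturbs another cell's
draws — important when probing sensitivity to a single assumption.
`consensus_from_panel()` combines experts by the cell-wise arithmetic mean.

What the simulator does **not** model: inter-expert correlation (real
panels anchor on each other), systematic elicitation biases (optimism,
halo effects across criteria of the same DCM), and integer scoring habits
(draws are continuous). Tests passing on simulated panels therefore
demonstrate the pipeline's arithmetic and determinism, not the behaviour of
real expert panels.

The bundled demonstration spec (`panel_spec_scenarioA.csv`) is synthetic:
it centres each cell's triangular distribution on the consensus score with
a symmetric half-width of $\min(2, \mathrm{mean}, 10 - \mathrm{mean})$
score points, so the implied mode equals the mean and always lies in the
support. Two points is a realistic disagreement band for a structured
0–10 elicitation; the truncation near the scale ends keeps the mean exact.

## Numerical choices

- **Linear programming.** All BoD and DEA programs are solved by a dense
  two-phase primal simplex with Bland's anti-cycling rule, implemented in
  the package. DEA programs are notoriously degenerate (zero right-hand
  sides, frontier ties), which defeats general simplex routines that lack
  anti-cycling safeguards; Bland's rule guarantees termination, and at
  these sizes (tens of variables) speed is irrelevant. Pivot and
  feasibility tolerances are $10^{-9}$.
- **Verification.** The solver is cross-checked two ways: `vertex_oracle()`
  exhaustively enumerates basic solutions of the multiplier program on
  instances with at most 3 total dimensions and 6 DMUs and must agree to
  $10^{-9}$; and the envelopment and multiplier forms must agree (strong
  duality) to $10^{-7}$ on every tested instance, including the study data.
- **Frontier snapping.** Efficiencies within $10^{-9}$ of 1 are snapped to
  exactly 1, so frontier units compare cleanly and ties are stable; no
  super-efficiency model is applied, so several DMUs may legitimately share
  $\theta = 1$.
- **Ranking.** Competition ranking throughout (ties share the smallest
  rank; the next rank is skipped); tie display order is by `dcm_id`. Ranks
  depend only on values, never on input order.
- **Degenerate inputs.** All-zero score rows, zero weight vectors,
  nonpositive costs and out-of-range scores are rejected with errors naming
  the offending DCM/criterion/row, not patched.
- **Determinism.** Evaluation is seed-free and byte-reproducible; the
  simulator is reproducible given (`seed`, `n_experts`, spec).

## Problem sizes

The test suite and the acceptance script run the full stylised example
(9–10 DCMs, 5–6 criteria, some hundreds of small LPs), property tests on
randomized instances of up to 6 DMUs and 4 dimensions, and sampler checks
at $10^5$ draws — a few seconds end to end on one core. These sizes were
chosen because the method targets national DCM portfolios, which are of
exactly this order; nothing in the implementation assumes them, and the LP
engine scales comfortably to the dozens of units a multi-country comparison
would need.

## Known limitations

- Costs are annual, single-currency and undiscounted, as in the source
  tables; there is no inflation, discounting or marginal-cost layer, and no
  currency/year metadata (the fixtures carry costs as unitless currency).
- The evaluation answers "which DCM gives the best value for money", not
  "is collecting vital statistics worth its cost" — no monetary valuation
  of data benefits is attempted.
- The BoD and DEA results with consensus-only data have low discriminatory
  power by construction; conclusions should rest on the pooled-expert or
  unweighted variants alongside them.
- Published cost-efficiency indices for the stylised example rest on an
  efficiency formulation that is not fully documented in the source
  material; the package's configurable DEA engine makes its own (stated)
  default choice instead of guessing, and treats those printed indices as
  out of reproduction scope.
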