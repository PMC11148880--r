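---
title: "Methods: a desk-scale virtual treatment planner for head-and-neck radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale virtual treatment planner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vtplanner)
```

## The model

Inverse planning is cast as a Markov decision process over plans. The
environment is a treatment-planning optimizer: given an objective set with
priorities, it returns the optimized dose `d = A x*` and its plan-quality
score. The agent — the virtual treatment planner — observes the state
`s`, the vector of 21 per-metric quality scores, and adjusts one of eight
priority weights per step. The reward is the change in total plan score,
`r = ψ(d') − ψ(d)`, with `ψ ∈ [0, 150]`.

Decision-making is hierarchical, mirroring how human planners work: first
*which* structure's priority to change, then *how*. The Parameter-Net maps
`s` (width 21) through three fully connected layers, each followed by a
Leaky-ReLU with slope 0.1, to 8 values — the predicted attainable
improvement per adjustable priority; the chosen priority is the argmax
(ties to the lowest index, for determinism). A structure-coded vector is
then formed: the chosen structure's scores are kept, all other entries
zeroed, preserving the 21-wide shape. Concatenated with the original
scores (width 42) it enters the Action-Net, same architecture, with 2
outputs: increase or decrease (ties to increase). The step magnitude is 6
when the previous adjustment improved ψ by more than 20%, otherwise 3; the
first adjustment of an episode uses 6. The relative improvement is defined
as `(ψ_new − ψ_prev) / max(ψ_prev, 1)`; the 20% criterion needs a base to be
well defined, and this choice keeps the quantity finite at
ψ near zero. Priorities are clamped to [1, 100], consistent with the fixed
template priorities lying in [30, 100].

Hidden widths default to 128/64/32 for both networks; the layer structure
(three hidden layers, Leaky-ReLU 0.1) is fixed, the widths are
configurable. Before entering the networks each score is divided by its
per-metric maximum, since the maxima are heterogeneous (4 to 15 points).

## Training

The two networks are trained alternately, each while the other is fixed:

- Action-Net: Q-learning regression onto the TD target
  `r + γ · max_p S(s', p; θ_S)`;
- Parameter-Net: supervised regression onto `max_a A(s, p, a; θ_A)` at the
  stored `(s, p)` pairs.

Episodes interact ε-greedily with the planning environment,
`ε = max(0.1, 0.99/EPI)` with `EPI` the episode index; with probability ε
a uniformly random (priority, direction) pair is drawn jointly. Each
transition `(s, p, a, r, s')` goes into a FIFO replay pool (capacity 10⁴)
from which uniform batches of 32 are drawn. There is no target-network
copy — the scheme is implemented as described, with stability coming from
a small learning rate.

Tunable training parameters, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| learning rate α | 1e-3 (Adam) | at desk scale a run yields only ~3·10³ replay updates; smaller rates underfit |
| discount γ | 0.9 | episodes are short (10 steps) and rewards mostly immediate |
| alternation | 3 Action-Net phases per Parameter-Net phase | the Parameter-Net must track the Action-Net closely for its argmax to stay meaningful |
| batch / buffer | 32 / 10⁴ | standard replay settings |
| episodes × steps | 300 × 10 | matches the scale at which the mini-phantom policy reliably beats baseline and random policies |

Each environment reset draws random starting priorities (uniform integers
in [30, 70]), so training covers diverse initial plans on one phantom —
the same single-case regime the method is designed for. All randomness
flows from one seed; identical seeds reproduce identical histories and
weights bit for bit.

## The plan-quality score

`ψ` sums 21 piecewise-linear criteria with maxima summing to 150: coverage
of the four prescription levels (V63/60/57/54 Gy; goals ≥ 95% for the
63/60 Gy targets and ≥ 90% for 57/54 Gy), global and intra-target hotspot
D[0.03cc] (< 69 Gy), serial-organ point doses (cord, cord+5 mm, brainstem,
brachial plexus), parotid mean and V30Gy, mean doses of oral cavity,
esophagus and constrictor, the three avoidance regions, and mean body dose.
Metric values are computed from raw voxel doses, not the binned DVH, to
avoid discretization bias; `D[v cc]` resolves ties toward the lower dose
(conservative for organ limits) and `V[dose]` uses the ≥ convention. The
exact clinical breakpoint tables are proprietary, so the packaged
breakpoints are linear ramps around standard planning goals; they are a
configuration file, not code, and can be replaced wholesale. The phantom
geometry and the default breakpoints are designed to be coherent: a dose
delivering each prescription inside its PTV and nothing elsewhere earns
all 150 points, which anchors the scale.

## The synthetic phantom

The generator emulates the *planning topology* of a head-and-neck case on
a single axial slice: an elliptical body; four nested PTVs
(63 ⊇ 60 ⊇ 57 ⊇ 54 Gy levels, built by intersection so nesting holds by
construction) with a wide bilateral nodal volume and a posterior lobe;
CTVs as 3 mm inner margins; and nine organs placed so the clinically
characteristic overlaps exist — the 54 Gy PTV intersects the oral cavity
(~24% of the organ), pharyngeal constrictor (~70%), both parotids
(~15–20%) and the esophagus (~20%), while cord, brainstem and brachial
plexus stay outside the targets. Auxiliary structures are derived exactly
as a planner would script them: `_opti` organs cropped of all PTVs, a 5 mm
cord expansion, 3 mm target inner rings, the PTV union and its difference
with the boost CTV, and three geometric avoidance regions (posterior neck
band, oral-cavity shell, trachea tube — stand-ins for expert-drawn
regions, cropped of the targets). Positions and sizes are jittered by a
seeded RNG (±3 mm, ±5%), so seeds emulate patients; required overlaps are
verified and an unsatisfiable grid raises an infeasibility error.

What the phantom does **not** emulate: 3D cranio-caudal anatomy, CT
densities and heterogeneity, realistic organ shapes, or deformable
anatomy (adaptive replanning is represented as planning on a re-generated
phantom). Passing tests therefore demonstrate that the decision-making
loop works against a faithful *interface* — dose operator, objectives,
scores — not that the dosimetry is clinically accurate.

Grids: the default phantom is 72×72 voxels at 3 mm (the 3 mm margins and
rings are nonempty at this spacing under the voxel-centre distance
convention); the mini phantom used for training is 32×32 at 7 mm with 5
beams and ≈ 90 beamlets, chosen so a full training run of 300 episodes ×
10 steps (3000 optimizations) completes in minutes on one CPU. On the
7 mm grid some thin auxiliary slivers may contain no voxel centres; such
structures bind as inert objectives (zero penalty) rather than erroring.

## Dose engine and optimizer

Photon physics is reduced to what the method actually needs — a linear,
nonnegative dose operator: 5 equispaced coplanar beams, beamlets of 5 mm
(7 mm on the mini grid) covering the PTV projection with a 5 mm margin,
exponential depth attenuation exp(−μ·depth) with μ = 0.005/mm and a
Gaussian penumbra (σ = 3 mm, truncated at 3σ). Entry depths are resolved
per lateral bin from the body contour. The matrix is sparse and its
construction deterministic.

The optimizer minimizes `Σ λ_i · penalty_i(A x)` over `x ≥ 0`. Dose-volume
constraints use the canonical one-sided surrogate: an upper constraint
(τ, V) penalizes only voxels with dose in (τ, D_V], where D_V is the
current dose at volume V, and symmetrically for lower constraints; mean
objectives penalize the squared excess of the structure mean. Penalties
are per-voxel normalized so priorities are comparable across structure
sizes; with 3 slots (dose, volume, priority) per objective the template
carries 47 × 3 = 141 parameters. The solver is deterministic projected
gradient with a Barzilai–Borwein step safeguarded by a monotone
backtracking line search — every accepted step strictly decreases the
objective, so the iteration trace is non-increasing by construction.
Random initialization is forbidden; re-optimizations inside the planning
loop warm-start from the previous fluence, mirroring interactive TPS
behaviour and cutting per-step cost (caps: 200 iterations cold, 40–60
warm).

Commercial optimizers do not document their penalty functional or
priority semantics; equivalence to them is structural (same objective
types, parameters and adjustment interface), not numerical.

## The planning loop

`initializePlan()` performs the initialization pipeline (phantom,
auxiliary structures, beams, template binding, baseline optimization and
scoring); `runAutoplanning()` then loops select → adjust → re-optimize →
re-score, recording every decision (the per-step trace mirrors a planning
log: step, chosen priority, direction, step size, reward, ψ). Stopping:
`maxSteps` adjustments (default 10) or 3 consecutive non-improving steps.
Because a TPS retains every intermediate plan, the workflow returns the
best-scoring plan encountered, not necessarily the last one. Initial
priorities ship with the template (all 50, mid-range), standing in for a
dosimetrist's predefined starting values.

`lookaheadOracleAgent()` evaluates all 16 candidate adjustments by actual
re-optimization and takes the best — an upper reference for one-step
policies, used in the tests to calibrate how much improvement the
environment offers.

## Evaluation statistics

`nonInferiorityTest()` is a paired one-sided t-test of
`H0: mean(A − B) ≤ −margin`; the default margin is 0, transparently
degenerating to a one-sided superiority test rather than inventing a
clinical margin. The zero-variance case is
resolved by certainty (p = 0 or 1). Per-metric comparisons are reported
without multiple-testing correction, matching per-metric p-value
presentation practice.

## Numerical choices and degenerate inputs

- Morphology (expand/erode/ring) thresholds physical voxel-centre
  distances, so results are spacing-independent in physical units; a
  margin below the voxel spacing is a no-op by this convention.
- Argmax ties: lowest index / increase; quantile ties in coverage
  normalization resolve toward the higher quantile (scale = rx / k-th
  largest PTV dose, k = ⌈coverage·n⌉).
- Scoring breakpoints clamp outside their range; metric monotonicity
  (non-increasing for organ metrics, non-decreasing for coverage) is
  validated when the configuration loads.
- Empty structures: an error in scoring (the metric is undefined), inert
  in optimization (zero penalty), and an explicit infeasibility error in
  phantom generation for primaries.

## Known limitations

- Single-slice geometry and toy physics: absolute dose values are
  arbitrary-unit; only relative plan-quality comparisons are meaningful.
- The score ceiling of 150 is reachable by construction on the default
  phantom but not necessarily through the optimizer: achievable ψ on the
  mini phantom sits near 100–110, so learning is assessed by comparison
  against baseline, random and oracle policies, not by absolute score.
- The agent is trained on a single phantom; transfer across seeds
  (emulating new patients) works through the state abstraction but
  degrades for geometries far from the training case, the expected
  failure mode of single-case training.
- Wall-clock planning-time claims have no desk-scale analogue; timing is
  logged but is not an evaluation quantity.
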