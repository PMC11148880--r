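# vtplanner

Automatic inverse treatment planning for head-and-neck (H&N) radiotherapy
with a deep-reinforcement-learning "virtual treatment planner" (VTP), at
desk scale: the whole pipeline — synthetic voxel phantom, beamlet dose
engine, dose-volume objective optimizer, plan-quality scoring, agent
training and the closed planning loop — runs on one CPU with no clinical
software or patient data.

## The problem

In inverse planning, a treatment planning system (TPS) minimizes a weighted
sum of dose-volume penalties over the beamlet fluence `x`, with dose
`d = A x`. The plan that comes out depends on treatment planning parameters
(TPPs) — dose limits τ, volume thresholds V and priority weights λ — that a
human planner adjusts by trial and error. `vtplanner` implements a
hierarchical Q-learning agent that does this adjustment autonomously:

- **Parameter-Net** `S(s, p; θ_S)`: from the state `s` (the 21 per-metric
  plan-quality scores) it predicts, for each of the 8 adjustable priorities
  P1..P8, the achievable improvement; the planner picks
  `p* = argmax_p S(s, p)`.
- **Action-Net** `A(s, p, a; θ_A)`: from the structure-coded state (the
  selected structure's scores kept, all others zeroed, concatenated with
  `s`) it picks the direction `a* ∈ {increase, decrease}`.
- The step magnitude is adaptive: 6 if the previous adjustment improved the
  plan score by more than 20%, else 3.

Plan quality is a ProKnow-style score `ψ(d) ∈ [0, 150]`: 21 piecewise-linear
dosimetric criteria (PTV coverage, hotspots, parotid mean/V30Gy, cord
D[0.03cc], …) summing to 150. The reward for a TPP adjustment is
`r = ψ(d') − ψ(d)`. The two networks are trained alternately: the
Action-Net by Q-learning on TD targets `r + γ max_p S(s', p)`, the
Parameter-Net by regression onto `max_a A(s, p, a)`, with ε-greedy
exploration (`ε = max(0.1, 0.99/EPI)`) and experience replay.

The packaged objective template transcribes a clinical H&N configuration:
47 objectives (20 lower / 18 upper / 9 mean dose-volume constraints) on 26
planning structures — 141 parameter slots, of which 36 objectives are held
fixed and 11 are adjustable, sharing 8 distinct priorities (the `_opti`
auxiliary structures share their primary organ's priority).

## Worked example

```r
library(vtplanner)

# synthetic H&N phantom + auxiliary planning structures, starting from a
# deliberately flat (untuned) priority initialization
pv <- setNames(rep(30, 8), paste0("P", 1:8))
st <- initializePlan(miniPhantomSpec(seed = 1), beamletWidthMm = 7,
                     initialPriorities = pv)
st$score$total
#> [1] 102.7253

# closed-loop planning steps driven by the one-step-lookahead oracle
rec <- runAutoplanning(st, oracleAgent(optIters = 40), maxSteps = 6)
rec$trace
#>   step  p        a stepSize     reward      psi
#> 1    0 NA     <NA>       NA         NA 102.7253
#> 2    1  4 decrease        6 6.99394279 109.7193
#> 3    2  7 increase        3 0.05909593 109.7784
#> 4    3  4 decrease        3 0.74200861 110.5204
#> 5    4  8 increase        3 0.10693141 110.6273
#> 6    5  8 increase        3 0.08622222 110.7135
#> 7    6  8 increase        3 0.07086797 110.7844
```

Each row is one planner decision: which priority it adjusted (`p`), in
which direction, with which step, and the resulting total plan score ψ.
Here the planner first lowers the right-parotid mean priority (P4), which
was over-constraining target coverage, for a +7.0-point jump, then nudges
the constrictor (P7) and brachial-plexus (P8) priorities up, improving
the plan from 102.7 to 110.8 of 150 points.

Training the learned planner instead:

```r
env <- planningEnv(miniPhantomSpec(seed = 1))
fit <- trainVtp(env, trainingHyperparams(episodes = 300, stepsPerEpisode = 10, seed = 7))
rec <- runAutoplanning(st, vtpAgent(fit$pNet, fit$aNet), maxSteps = 10)
```

`nonInferiorityTest()` and `comparisonReport()` provide the paired
one-sided non-inferiority statistics used to compare two arms of plans.

A thin command-line wrapper is shipped at `inst/scripts/vtplan-cli.R`
(`phantom`, `train`, `plan`, `evaluate` subcommands).

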