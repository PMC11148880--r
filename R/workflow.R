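# The closed autoplanning loop: initialize (phantom, beams, objectives,
# baseline optimization) then repeat optimize -> score -> decide -> adjust
# until the stopping criterion, recording a per-step decision trace.

#' Mini phantom specification for training and fast experiments
#'
#' The same synthetic head-and-neck geometry on a coarse 32 x 32 single
#' slice (7 mm voxels), keeping optimization problems to a few hundred
#' beamlets so full reinforcement-learning runs complete on one CPU.
#'
#' @param seed RNG seed.
#' @return A `"PhantomSpec"`.
#' @export
miniPhantomSpec <- function(seed = 1L) {
  phantomSpec(seed = seed, shape = c(32L, 32L, 1L), spacingMm = c(7, 7, 7))
}

#' Initialize a treatment plan
#'
#' Runs the planning initialization pipeline: generate the phantom, derive
#' the auxiliary structures, build the beamlet influence matrix, load and
#' bind the objective template and the scoring configuration, solve the
#' initial optimization and score the baseline plan. Any stage failure is
#' reported with the stage name.
#'
#' @param spec a `"PhantomSpec"` (default [phantomSpec()]).
#' @param templatePath objective template path (default packaged).
#' @param scoringPath scoring config path (default packaged).
#' @param initialPriorities optional named numeric P1..P8 starting
#'   priorities (default: the template's `initial_priorities`).
#' @param nBeams,beamletWidthMm dose-engine settings.
#' @param optIters iteration cap for the baseline optimization.
#' @return A list of class `"PlanState"`: `ss`, `im`, `os`, `bound`,
#'   `config`, `mapping`, `pv`, `x`, `dose`, `score`, `step`.
#' @export
initializePlan <- function(spec = phantomSpec(), templatePath = NULL,
                           scoringPath = NULL, initialPriorities = NULL,
                           nBeams = 5L, beamletWidthMm = 5,
                           optIters = 200L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("initializePlan failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ss <- stage("phantom", {
    s <- generatePhantom(spec)
    deriveAuxiliaryStructures(s)
  })
  im <- stage("influence matrix",
    buildInfluenceMatrix(ss, nBeams = nBeams,
                         beamletWidthMm = beamletWidthMm))
  os <- stage("objective template", loadObjectiveTemplate(templatePath))
  config <- stage("scoring config", loadScoringConfig(scoringPath))
  mapping <- stage("tpp mapping", tppStateMapping(config))
  pv <- if (is.null(initialPriorities)) os@initialPriorities
        else initialPriorities
  os <- stage("priorities", applyPriorities(os, pv))
  bound <- stage("objective binding", bindObjectives(os, ss, im))
  opt <- stage("baseline optimization",
    optimizeFluence(im, os, bound, maxIters = optIters))
  score <- stage("baseline scoring", scorePlan(opt$dose, ss, config, im))
  structure(list(ss = ss, im = im, os = os, bound = bound, config = config,
                 mapping = mapping, pv = pv, x = opt$x, dose = opt$dose,
                 score = score, step = 0L),
            class = "PlanState")
}

# One TPP adjustment applied to a PlanState: re-apply priorities,
# re-optimize from the warm-started fluence, re-score.
stepPlan <- function(state, p, a, stepSize, optIters = 60L) {
  pv <- applyAdjustment(state$pv, p, a, stepSize,
                        bounds = state$os@priorityBounds)
  os <- applyPriorities(state$os, pv)
  opt <- optimizeFluence(state$im, os, state$bound, x0 = state$x,
                         maxIters = optIters)
  score <- scorePlan(opt$dose, state$ss, state$config, state$im)
  state$pv <- pv; state$os <- os; state$x <- opt$x; state$dose <- opt$dose
  state$score <- score; state$step <- state$step + 1L
  state
}

#' Run the closed-loop autoplanning workflow
#'
#' Repeats select-parameter / select-direction / adaptive-step / adjust /
#' re-optimize / re-score, recording each decision. Stops at `maxSteps`
#' adjustments or when the plan score has not improved for `patience`
#' consecutive steps. Entry 0 of the record is the pre-adjustment baseline.
#'
#' @param state a `"PlanState"` from [initializePlan()].
#' @param agent decision function: `agent(state, stepSize)` returning
#'   `list(p, a)` (e.g. [vtpAgent()] or [oracleAgent()]); the step size the
#'   loop is about to apply is passed so lookahead agents can evaluate the
#'   true candidate adjustments.
#' @param maxSteps maximum number of adjustments (>= 0).
#' @param patience stop after this many consecutive non-improving steps.
#' @param optIters per-step optimizer iteration cap (warm-started).
#' @return A list of class `"PlanRecord"`: `trace` (data.frame with one row
#'   per step incl. baseline), `scores` (per-step score vectors), `final`
#'   (the best-scoring `"PlanState"` encountered -- every intermediate plan
#'   is retained by a planning system, so the workflow keeps the best),
#'   `finalStep` (its step index).
#' @export
runAutoplanning <- function(state, agent, maxSteps = 10L, patience = 3L,
                            optIters = 60L) {
  stopifnot(maxSteps >= 0)
  rows <- list(data.frame(step = 0L, p = NA_integer_, a = NA_character_,
                          stepSize = NA_real_, reward = NA_real_,
                          psi = state$score$total))
  scores <- list(state$score$vector)
  best <- state
  bestStep <- 0L
  lastImpr <- Inf
  bad <- 0L
  for (k in seq_len(maxSteps)) {
    stepSize <- adaptiveStepSize(lastImpr)
    dec <- agent(state, stepSize)
    psiPrev <- state$score$total
    state <- stepPlan(state, dec$p, dec$a, stepSize, optIters = optIters)
    r <- reward(psiPrev, state$score$total)
    lastImpr <- r / max(psiPrev, 1)
    rows[[length(rows) + 1L]] <- data.frame(step = k, p = dec$p, a = dec$a,
      stepSize = stepSize, reward = r, psi = state$score$total)
    scores[[length(scores) + 1L]] <- state$score$vector
    if (state$score$total > best$score$total) {
      best <- state
      bestStep <- k
    }
    bad <- if (r > 0) 0L else bad + 1L
    if (bad >= patience) break
  }
  structure(list(trace = do.call(rbind, rows), scores = scores,
                 final = best, finalStep = bestStep), class = "PlanRecord")
}

#' @export
print.PlanRecord <- function(x, ...) {
  cat(sprintf("PlanRecord: %d steps, psi %.2f -> %.2f\n",
      nrow(x$trace) - 1L, x$trace$psi[1], x$trace$psi[nrow(x$trace)]))
  print(x$trace, digits = 4)
  invisible(x)
}

#' Exhaustive one-step-lookahead oracle agent
#'
#' Evaluates all candidate (parameter, direction) adjustments by actually
#' re-optimizing and re-scoring each, and returns the pair with maximal
#' resulting plan score (ties: lowest parameter index, then increase).
#' Intended as a policy-quality reference on small problems; cost is 16
#' optimizations per call under the default 8-priority template.
#'
#' @param state a `"PlanState"`.
#' @param stepSize the step the caller will apply (default 3).
#' @param optIters per-candidate optimizer iteration cap.
#' @return `list(p, a, psi, gains)` where `gains` is the 8 x 2 matrix of
#'   resulting plan scores.
#' @export
lookaheadOracleAgent <- function(state, stepSize = 3, optIters = 60L) {
  nT <- length(state$pv)
  gains <- matrix(NA_real_, nT, 2,
                  dimnames = list(names(state$pv),
                                  c("increase", "decrease")))
  for (p in seq_len(nT)) for (ai in 1:2) {
    cand <- stepPlan(state, p, c("increase", "decrease")[ai], stepSize,
                     optIters = optIters)
    gains[p, ai] <- cand$score$total
  }
  best <- which(gains == max(gains), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(p = unname(best[1]), a = c("increase", "decrease")[best[2]],
       psi = max(gains), gains = gains)
}

#' Make an oracle agent function for [runAutoplanning()]
#' @param optIters per-candidate optimizer iteration cap.
#' @return `function(state, stepSize)` returning the oracle's `list(p, a)`,
#'   evaluated at the step size the loop will apply.
#' @export
oracleAgent <- function(optIters = 60L) {
  function(state, stepSize = 3)
    lookaheadOracleAgent(state, stepSize, optIters)[c("p", "a")]
}

#' Agent wrapper for a trained greedy policy
#'
#' Normalizes the current score vector and applies the hierarchical greedy
#' policy of the trained networks.
#'
#' @param pNet,aNet trained networks.
#' @return `function(state, stepSize)` for [runAutoplanning()].
#' @export
vtpAgent <- function(pNet, aNet) {
  function(state, stepSize = NULL) {
    s <- normalizeState(state$score$vector, state$config$maxPoints)
    pol <- greedyPolicy(pNet, aNet, state$mapping)
    pol(s)
  }
}

#' Reinforcement-learning environment over the planning loop
#'
#' Wraps a plan on a fixed phantom as an episodic environment. `reset()`
#' draws random starting priorities (uniform integers in `priorityRange`
#' from the ambient RNG stream), re-optimizes from scratch and returns the
#' normalized baseline state; `step(p, a, stepSize)` applies one priority
#' adjustment with a warm-started re-optimization and returns the new
#' state, the plan-score reward and the new total score. The phantom and
#' influence matrix are built once and shared across episodes.
#'
#' @param spec phantom specification (default [miniPhantomSpec()]).
#' @param priorityRange range for random initial priorities at reset.
#' @param resetIters,stepIters optimizer iteration caps at reset / per step.
#' @param templatePath,scoringPath,nBeams,beamletWidthMm passed to
#'   [initializePlan()].
#' @return An environment-like list: `reset()`, `step()`, `mapping`,
#'   `nTpps`, `stateWidth`, `maxPoints`, and `plan()` returning the current
#'   `"PlanState"`.
#' @export
planningEnv <- function(spec = miniPhantomSpec(), priorityRange = c(30, 70),
                        resetIters = 150L, stepIters = 40L,
                        templatePath = NULL, scoringPath = NULL,
                        nBeams = 5L, beamletWidthMm = 7) {
  base <- initializePlan(spec, templatePath = templatePath,
                         scoringPath = scoringPath, nBeams = nBeams,
                         beamletWidthMm = beamletWidthMm,
                         optIters = resetIters)
  state <- base
  reset <- function(priorities = NULL) {
    if (is.null(priorities))
      priorities <- setNames(
        round(stats::runif(8, priorityRange[1], priorityRange[2])),
        paste0("P", 1:8))
    os <- applyPriorities(base$os, priorities)
    opt <- optimizeFluence(base$im, os, base$bound, maxIters = resetIters)
    sc <- scorePlan(opt$dose, base$ss, base$config, base$im)
    st <- base
    st$pv <- priorities; st$os <- os; st$x <- opt$x; st$dose <- opt$dose
    st$score <- sc; st$step <- 0L
    state <<- st
    list(state = normalizeState(sc$vector, base$config$maxPoints),
         psi = sc$total)
  }
  step <- function(p, a, stepSize) {
    psiPrev <- state$score$total
    state <<- stepPlan(state, p, a, stepSize, optIters = stepIters)
    list(state = normalizeState(state$score$vector, base$config$maxPoints),
         reward = reward(psiPrev, state$score$total),
         psi = state$score$total)
  }
  list(reset = reset, step = step, mapping = base$mapping, nTpps = 8L,
       stateWidth = length(base$config$metrics),
       maxPoints = base$config$maxPoints, plan = function() state)
}
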