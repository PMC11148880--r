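# The hierarchical virtual planner: the Parameter-Net picks which of the 8
# adjustable priorities to change, the Action-Net picks the direction, and
# an adaptive rule sets the step magnitude (6 or 3).

#' Construct a fully connected network
#'
#' He-initialized dense network with Leaky-ReLU hidden activations (slope
#' 0.1) and a linear output layer. Initialization is deterministic given the
#' seed.
#'
#' @param widths integer vector: input width, hidden widths, output width.
#' @param seed RNG seed for weight initialization.
#' @param slope Leaky-ReLU negative slope.
#' @return A [DenseNet-class].
#' @export
denseNet <- function(widths, seed = 1L, slope = 0.1) {
  stopifnot(length(widths) >= 2)
  layers <- withSeed(seed, lapply(seq_len(length(widths) - 1L), function(i) {
    fanIn <- widths[i]
    list(W = matrix(stats::rnorm(widths[i + 1] * fanIn, sd = sqrt(2 / fanIn)),
                    nrow = widths[i + 1]),
         b = numeric(widths[i + 1]))
  }))
  new("DenseNet", layers = layers, slope = slope)
}

#' Default Parameter-Net (input 21 scores, output 8 TPP values)
#' @param seed RNG seed.
#' @param hidden hidden layer widths.
#' @param nMetrics state width (per-metric scores).
#' @param nTpps number of adjustable priorities.
#' @return A [DenseNet-class].
#' @export
parameterNet <- function(seed = 1L, hidden = c(128L, 64L, 32L),
                         nMetrics = 21L, nTpps = 8L) {
  denseNet(c(nMetrics, hidden, nTpps), seed = seed)
}

#' Default Action-Net (input 42 = structure-coded vector + scores, output 2)
#' @inheritParams parameterNet
#' @return A [DenseNet-class].
#' @export
actionNet <- function(seed = 2L, hidden = c(128L, 64L, 32L),
                      nMetrics = 21L) {
  denseNet(c(2L * nMetrics, hidden, 2L), seed = seed)
}

# Forward pass; X is (n x inputWidth). Returns (n x outputWidth), or with
# activations when keep = TRUE (for backprop).
netForwardFull <- function(net, X, keep = FALSE) {
  stopifnot(is.matrix(X), ncol(X) == ncol(net@layers[[1]]$W))
  L <- length(net@layers)
  acts <- vector("list", L + 1L)
  pre <- vector("list", L)
  acts[[1]] <- X
  H <- X
  for (i in seq_len(L)) {
    Z <- H %*% t(net@layers[[i]]$W) +
      matrix(net@layers[[i]]$b, nrow(H), length(net@layers[[i]]$b),
             byrow = TRUE)
    if (i < L) H <- ifelse(Z > 0, Z, net@slope * Z) else H <- Z
    pre[[i]] <- Z
    acts[[i + 1L]] <- H
  }
  if (keep) list(out = H, acts = acts, pre = pre) else H
}

#' Forward pass of a DenseNet
#'
#' Pure function of (weights, input): repeated calls give identical output.
#'
#' @param net a [DenseNet-class].
#' @param X numeric vector (one input) or matrix (rows are inputs).
#' @return Matrix of outputs (rows correspond to input rows).
#' @export
netForward <- function(net, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  netForwardFull(net, X)
}

#' Structure-coded state vector
#'
#' Keeps the score entries belonging to the selected adjustable priority and
#' zeroes all others, preserving the state dimension. Concatenated with the
#' original scores it forms the Action-Net input.
#'
#' @param s numeric score vector (length 21 under the default config).
#' @param p TPP index in 1..8.
#' @param mapping list mapping each TPP index to >= 1 state indices (e.g.
#'   from [tppStateMapping()]).
#' @return Numeric vector of the same length as `s`.
#' @export
structureCodedVector <- function(s, p, mapping) {
  idx <- mapping[[p]]
  if (is.null(idx) || length(idx) == 0)
    stop("structureCodedVector: empty metric mapping for TPP ", p)
  out <- numeric(length(s))
  out[idx] <- s[idx]
  out
}

#' TPP-to-state-index mapping from a scoring configuration
#'
#' Converts the scoring config's placeholder-to-metric-name map into state
#' indices, ordered P1..P8.
#'
#' @param config a `"ScoringConfig"`.
#' @return List of integer index vectors, one per placeholder.
#' @export
tppStateMapping <- function(config) {
  if (is.null(config$tppMap)) stop("scoring config carries no tpp_map")
  ph <- paste0("P", seq_along(config$tppMap))
  if (!all(ph %in% names(config$tppMap)))
    stop("tpp_map must cover P1..P", length(config$tppMap))
  lapply(ph, function(p) match(config$tppMap[[p]], names(config$metrics)))
}

#' Select the planning parameter to adjust
#'
#' Greedy argmax over the Parameter-Net's predicted improvement values;
#' ties resolve to the lowest index.
#'
#' @param s state vector.
#' @param net the Parameter-Net.
#' @return TPP index in `1..outputWidth`.
#' @export
selectTpp <- function(s, net) {
  q <- netForward(net, s)
  if (!all(is.finite(q))) stop("selectTpp: non-finite network output")
  which.max(q)
}

#' Select the adjustment direction for a chosen parameter
#'
#' Runs the Action-Net on the structure-coded vector concatenated with the
#' original scores and takes the argmax over the two directions; ties
#' resolve to `"increase"`.
#'
#' @param s state vector.
#' @param p chosen TPP index.
#' @param net the Action-Net.
#' @param mapping TPP-to-state-index mapping.
#' @return `"increase"` or `"decrease"`.
#' @export
selectAction <- function(s, p, net, mapping) {
  q <- netForward(net, c(structureCodedVector(s, p, mapping), s))
  if (!all(is.finite(q))) stop("selectAction: non-finite network output")
  c("increase", "decrease")[which.max(q)]
}

#' Adaptive priority step size
#'
#' Step 6 when the previous adjustment improved the plan score by more than
#' the empirical 20% criterion, step 3 otherwise (a change of exactly 20%
#' counts as minor). The first adjustment of an episode uses step 6 (pass
#' `Inf`).
#'
#' @param lastRelativeImprovement relative plan-score improvement of the
#'   previous adjustment.
#' @return 6 or 3.
#' @export
adaptiveStepSize <- function(lastRelativeImprovement) {
  if (is.na(lastRelativeImprovement))
    stop("adaptiveStepSize: improvement must be a number (use Inf initially)")
  if (lastRelativeImprovement > 0.20) 6 else 3
}

#' Apply a priority adjustment
#'
#' Adds or subtracts the step on the selected priority and clamps to the
#' allowed range; all other priorities are unchanged.
#'
#' @param pv named numeric priority vector (P1..P8).
#' @param p TPP index.
#' @param a `"increase"` or `"decrease"`.
#' @param step step size (6 or 3).
#' @param bounds numeric(2) priority bounds.
#' @return The adjusted priority vector.
#' @export
applyAdjustment <- function(pv, p, a, step, bounds = c(1, 100)) {
  stopifnot(p >= 1, p <= length(pv), a %in% c("increase", "decrease"))
  delta <- if (a == "increase") step else -step
  pv[p] <- min(max(pv[p] + delta, bounds[1]), bounds[2])
  pv
}

#' Normalize a score vector for network input
#'
#' Divides each per-metric score by its maximum so heterogeneous per-metric
#' maxima enter the networks on a common scale.
#'
#' @param scores named per-metric score vector.
#' @param maxPoints per-metric maxima (from the scoring config).
#' @return Normalized state in `[0, 1]` per component.
#' @export
normalizeState <- function(scores, maxPoints) {
  as.numeric(scores) / as.numeric(maxPoints)
}
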