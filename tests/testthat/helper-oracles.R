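# Brute-force reference implementations, independent of the package's
# vectorized/morphological code paths, used as oracles on small grids.

# physical voxel-centre coordinates of every voxel, rows = voxels
bfCoords <- function(grid) {
  sh <- grid@shape; sp <- grid@spacingMm
  idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  sweep((idx - 0.5), 2, sp, `*`)
}

# dilation by explicit all-pairs distance check
bfExpand <- function(mask, grid, marginMm) {
  co <- bfCoords(grid)
  inIdx <- which(as.vector(mask))
  out <- logical(length(mask))
  for (v in seq_along(out)) {
    dd <- sqrt(colSums((t(co[inIdx, , drop = FALSE]) - co[v, ])^2))
    out[v] <- any(dd <= marginMm + 1e-9)
  }
  array(out, dim = grid@shape)
}

# per-voxel loop: organ AND NOT (union of targets)
bfCrop <- function(organ, targets) {
  out <- organ
  for (v in seq_along(out)) {
    inAny <- FALSE
    for (t in targets) if (t[v]) inAny <- TRUE
    out[v] <- organ[v] && !inAny
  }
  out
}

# ring: mask voxels within widthMm of some non-mask voxel
bfRing <- function(mask, grid, widthMm) {
  co <- bfCoords(grid)
  outIdx <- which(!as.vector(mask))
  out <- logical(length(mask))
  for (v in which(as.vector(mask))) {
    if (length(outIdx) == 0) next
    dd <- sqrt(colSums((t(co[outIdx, , drop = FALSE]) - co[v, ])^2))
    out[v] <- any(dd <= widthMm + 1e-9)
  }
  array(out, dim = grid@shape)
}

# random logical mask on a grid
randomMask <- function(grid, p = 0.3) {
  array(stats::runif(prod(grid@shape)) < p, dim = grid@shape)
}

# small structure set: one body covering everything plus given masks
tinySS <- function(grid, masks, roles = NULL) {
  body <- array(TRUE, dim = grid@shape)
  if (is.null(roles))
    roles <- setNames(rep("organ", length(masks)), names(masks))
  structureSet(grid, c(list(BODY = body), masks),
               c(BODY = "body", roles))
}

# value iteration on an explicit finite MDP: transition[s, a] -> next state,
# rewardMat[s, a] -> reward (deterministic dynamics)
valueIteration <- function(transition, rewardMat, gamma, tol = 1e-12) {
  nS <- nrow(transition); nA <- ncol(transition)
  Q <- matrix(0, nS, nA)
  repeat {
    V <- apply(Q, 1, max)
    Qn <- rewardMat + gamma * matrix(V[transition], nS, nA)
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
}

# deterministic one-good-TPP toy environment for training tests
toyEnv <- function(goodTpp = 3L, nMetrics = 21L) {
  mapping <- lapply(1:8, function(p) ((p - 1L) %% nMetrics) + c(1L, 9L))
  state <- NULL
  reset <- function() {
    state <<- stats::runif(nMetrics)
    list(state = state, psi = 100)
  }
  step <- function(p, a, stepSize) {
    r <- if (p == goodTpp) 1 else -1
    state <<- stats::runif(nMetrics)
    list(state = state, reward = r, psi = 100 + r)
  }
  list(reset = reset, step = step, mapping = mapping, nTpps = 8L,
       stateWidth = nMetrics)
}
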