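# Q-learning machinery: exploration schedule, tabular reference update,
# experience replay, the two alternating network losses, backprop/Adam, and
# the training loop.

#' Exploration probability schedule
#'
#' `epsilon = max(0.1, 0.99 / EPI)` where `EPI` is the 1-based episode
#' index; non-increasing, floored at 0.1.
#'
#' @param episodeIndex episode index (>= 1).
#' @return The exploration probability.
#' @examples
#' epsilonSchedule(1)    # 0.99
#' epsilonSchedule(100)  # 0.1
#' @export
epsilonSchedule <- function(episodeIndex) {
  if (any(episodeIndex < 1)) stop("epsilonSchedule: episode index must be >= 1")
  pmax(0.1, 0.99 / episodeIndex)
}

#' Tabular Q-learning update
#'
#' The classical action-value update
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') - Q(s,a))`,
#' used as the reference oracle for the network-based targets.
#'
#' @param Q numeric matrix (states x actions).
#' @param s,a current state and action indices.
#' @param r reward.
#' @param sNext next state index.
#' @param alpha learning rate.
#' @param gamma discount factor.
#' @return The updated Q matrix.
#' @export
qUpdateTabular <- function(Q, s, a, r, sNext, alpha, gamma) {
  stopifnot(is.finite(r), alpha >= 0, gamma >= 0, gamma <= 1)
  Q[s, a] <- Q[s, a] + alpha * (r + gamma * max(Q[sNext, ]) - Q[s, a])
  Q
}

#' Experience replay buffer
#'
#' Fixed-capacity FIFO pool of transitions `(s, p, a, r, s')` with uniform
#' sampling. Sampling draws from the ambient RNG stream, so it is
#' reproducible under the training seed.
#'
#' @param capacity maximum number of stored transitions.
#' @return An environment with `push(tr)`, `sample(n)`, `size()`.
#' @export
replayBuffer <- function(capacity = 10000L) {
  pool <- vector("list", capacity)
  n <- 0L
  head <- 0L
  push <- function(tr) {
    head <<- head %% capacity + 1L
    pool[[head]] <<- tr
    n <<- min(n + 1L, capacity)
    invisible(NULL)
  }
  sampleBatch <- function(k) {
    ids <- sample.int(n, size = min(k, n), replace = FALSE)
    pool[ids]
  }
  environment()
  structure(list(push = push, sample = sampleBatch, size = function() n,
                 capacity = capacity), class = "ReplayBuffer")
}

# Action-Net input row for a transition: structure-coded vector + scores.
actionInput <- function(s, p, mapping) c(structureCodedVector(s, p, mapping), s)

#' Temporal-difference loss of the Action-Net
#'
#' Mean squared error between the Action-Net's value for the taken (p, a)
#' and the TD target `r + gamma * max_p S(s'; theta_S)` where S is the
#' Parameter-Net evaluated at the next state.
#'
#' @param batch list of transitions, each a list with `s`, `p` (1..8), `a`
#'   (1 = increase, 2 = decrease), `r`, `sNext`.
#' @param aNet the Action-Net.
#' @param pNet the Parameter-Net.
#' @param gamma discount factor.
#' @param mapping TPP-to-state-index mapping.
#' @return The scalar loss (>= 0).
#' @export
actionNetLoss <- function(batch, aNet, pNet, gamma, mapping) {
  stopifnot(length(batch) > 0)
  X <- do.call(rbind, lapply(batch, function(t) actionInput(t$s, t$p, mapping)))
  sel <- vapply(batch, `[[`, numeric(1), "a")
  Sn <- netForward(pNet, do.call(rbind, lapply(batch, `[[`, "sNext")))
  target <- vapply(batch, `[[`, numeric(1), "r") + gamma * apply(Sn, 1, max)
  pred <- netForward(aNet, X)[cbind(seq_along(batch), sel)]
  mean((pred - target)^2)
}

#' Supervised regression loss of the Parameter-Net
#'
#' Mean squared error between `S(s, p)` and the Action-Net's best achievable
#' value `max_a A(s, p, a)` for each stored (s, p).
#'
#' @inheritParams actionNetLoss
#' @return The scalar loss (>= 0).
#' @export
parameterNetLoss <- function(batch, pNet, aNet, mapping) {
  stopifnot(length(batch) > 0)
  X <- do.call(rbind, lapply(batch, `[[`, "s"))
  sel <- vapply(batch, `[[`, numeric(1), "p")
  XA <- do.call(rbind, lapply(batch, function(t) actionInput(t$s, t$p, mapping)))
  target <- apply(netForward(aNet, XA), 1, max)
  pred <- netForward(pNet, X)[cbind(seq_along(batch), sel)]
  mean((pred - target)^2)
}

# Gradients of the selected-output MSE loss wrt all weights. `sel` gives the
# scored output unit per row; `targets` the regression targets.
netGradients <- function(net, X, sel, targets) {
  fw <- netForwardFull(net, X, keep = TRUE)
  L <- length(net@layers)
  n <- nrow(X)
  pred <- fw$out[cbind(seq_len(n), sel)]
  loss <- mean((pred - targets)^2)
  delta <- matrix(0, n, ncol(fw$out))
  delta[cbind(seq_len(n), sel)] <- 2 * (pred - targets) / n
  grads <- vector("list", L)
  for (i in L:1) {
    H <- fw$acts[[i]]
    grads[[i]] <- list(dW = t(delta) %*% H, db = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% net@layers[[i]]$W
      Z <- fw$pre[[i - 1L]]
      delta <- delta * ifelse(Z > 0, 1, net@slope)
    }
  }
  list(grads = grads, loss = loss)
}

adamInit <- function(net) {
  lapply(net@layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0, t = 0L))
}

adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  layers <- net@layers
  for (i in seq_along(layers)) {
    st <- state[[i]]
    st$t <- st$t + 1L
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[i]]$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[i]]$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[i]]$db
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[i]]$db^2
    c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
    layers[[i]]$W <- layers[[i]]$W -
      lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b -
      lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(net = initialize(net, layers = layers), state = state)
}

#' Training hyperparameters
#'
#' @param alpha gradient-descent learning rate (Adam).
#' @param gamma discount factor in `[0, 1]`.
#' @param episodes number of training episodes.
#' @param stepsPerEpisode planning adjustments per episode.
#' @param batchSize replay batch size.
#' @param bufferCapacity replay pool capacity.
#' @param alternation Action-Net update phases per Parameter-Net phase.
#' @param seed master RNG seed for the run.
#' @param hidden hidden widths for both networks.
#' @return A list of class `"TrainingHyperparams"`.
#' @export
trainingHyperparams <- function(alpha = 1e-3, gamma = 0.9, episodes = 100L,
                                stepsPerEpisode = 10L, batchSize = 32L,
                                bufferCapacity = 10000L, alternation = 3L,
                                seed = 1L, hidden = c(128L, 64L, 32L)) {
  stopifnot(alpha > 0, gamma >= 0, gamma <= 1, episodes >= 0,
            stepsPerEpisode >= 1, batchSize >= 1, alternation >= 1)
  structure(list(alpha = alpha, gamma = gamma, episodes = as.integer(episodes),
                 stepsPerEpisode = as.integer(stepsPerEpisode),
                 batchSize = as.integer(batchSize),
                 bufferCapacity = as.integer(bufferCapacity),
                 alternation = as.integer(alternation),
                 seed = as.integer(seed), hidden = as.integer(hidden)),
            class = "TrainingHyperparams")
}

#' Train the virtual planner by alternating Q-learning
#'
#' Runs epsilon-greedy planning episodes against an environment, storing
#' transitions in a replay pool. With probability epsilon a uniformly
#' random (parameter, direction) pair is taken, otherwise the greedy
#' hierarchical policy. After every environment step the Action-Net is
#' regressed onto the TD targets; every `alternation`-th step the
#' Parameter-Net is regressed onto the Action-Net's maxima (each network is
#' trained while the other is held fixed). Fully reproducible given the
#' hyperparameter seed.
#'
#' The environment contract: `env$reset()` returns
#' `list(state, psi)`; `env$step(p, a, stepSize)` returns
#' `list(state, reward, psi)`; `env$mapping` is the TPP-to-state-index
#' mapping; `env$nTpps` the number of adjustable priorities (8).
#'
#' @param env the planning environment (e.g. [planningEnv()]).
#' @param hyper a [trainingHyperparams()] list.
#' @param pNet,aNet optional warm-start networks.
#' @param verbose print per-episode progress.
#' @return List with `pNet`, `aNet` and `history` (one row per step:
#'   episode, step, epsilon, p, a, stepSize, reward, psi, losses).
#' @export
trainVtp <- function(env, hyper = trainingHyperparams(), pNet = NULL,
                     aNet = NULL, verbose = FALSE) {
  nState <- length(env$mapping[[1]])  # just to force mapping exists
  nTpps <- env$nTpps %||% 8L
  stateWidth <- env$stateWidth %||% 21L
  if (is.null(pNet))
    pNet <- denseNet(c(stateWidth, hyper$hidden, nTpps),
                     seed = hyper$seed + 101L)
  if (is.null(aNet))
    aNet <- denseNet(c(2L * stateWidth, hyper$hidden, 2L),
                     seed = hyper$seed + 202L)
  if (hyper$episodes == 0L)
    return(list(pNet = pNet, aNet = aNet, history = data.frame()))
  buf <- replayBuffer(hyper$bufferCapacity)
  stA <- adamInit(aNet); stP <- adamInit(pNet)
  hist <- list()
  withSeed(hyper$seed, {
    phase <- 0L
    for (epi in seq_len(hyper$episodes)) {
      eps <- epsilonSchedule(epi)
      cur <- env$reset()
      s <- cur$state; psi <- cur$psi
      lastImpr <- Inf
      for (step in seq_len(hyper$stepsPerEpisode)) {
        if (stats::runif(1) < eps) {
          p <- sample.int(nTpps, 1L)
          a <- sample.int(2L, 1L)
        } else {
          p <- selectTpp(s, pNet)
          a <- match(selectAction(s, p, aNet, env$mapping),
                     c("increase", "decrease"))
        }
        stepSize <- adaptiveStepSize(lastImpr)
        nxt <- env$step(p, c("increase", "decrease")[a], stepSize)
        lastImpr <- (nxt$psi - psi) / max(psi, 1)
        buf$push(list(s = s, p = p, a = a, r = nxt$reward, sNext = nxt$state))
        lossA <- NA_real_; lossP <- NA_real_
        if (buf$size() >= hyper$batchSize) {
          batch <- buf$sample(hyper$batchSize)
          # Action-Net TD phase (Parameter-Net fixed)
          X <- do.call(rbind, lapply(batch, function(t)
            actionInput(t$s, t$p, env$mapping)))
          Sn <- netForward(pNet, do.call(rbind, lapply(batch, `[[`, "sNext")))
          targ <- vapply(batch, `[[`, numeric(1), "r") +
            hyper$gamma * apply(Sn, 1, max)
          gr <- netGradients(aNet, X, vapply(batch, `[[`, numeric(1), "a"),
                             targ)
          upd <- adamStep(aNet, gr$grads, stA, hyper$alpha)
          aNet <- upd$net; stA <- upd$state; lossA <- gr$loss
          phase <- phase + 1L
          if (phase %% hyper$alternation == 0L) {
            # Parameter-Net supervised phase (Action-Net fixed)
            XS <- do.call(rbind, lapply(batch, `[[`, "s"))
            targP <- apply(netForward(aNet, X), 1, max)
            grP <- netGradients(pNet, XS,
                                vapply(batch, `[[`, numeric(1), "p"), targP)
            updP <- adamStep(pNet, grP$grads, stP, hyper$alpha)
            pNet <- updP$net; stP <- updP$state; lossP <- grP$loss
          }
        }
        hist[[length(hist) + 1L]] <- data.frame(
          episode = epi, step = step, epsilon = eps, p = p,
          a = c("increase", "decrease")[a], stepSize = stepSize,
          reward = nxt$reward, psi = nxt$psi, lossA = lossA, lossP = lossP)
        s <- nxt$state; psi <- nxt$psi
      }
      if (verbose)
        message(sprintf("episode %d: eps %.3f psi %.2f", epi, eps, psi))
    }
  })
  list(pNet = pNet, aNet = aNet, history = do.call(rbind, hist))
}

#' Greedy policy from trained networks
#'
#' @param pNet trained Parameter-Net.
#' @param aNet trained Action-Net.
#' @param mapping TPP-to-state-index mapping.
#' @return `function(state)` returning `list(p, a)` deterministically.
#' @export
greedyPolicy <- function(pNet, aNet, mapping) {
  function(state) {
    p <- selectTpp(state, pNet)
    list(p = p, a = selectAction(state, p, aNet, mapping))
  }
}
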