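test_that("the exploration schedule follows max(0.1, 0.99/EPI)", {
  expect_equal(epsilonSchedule(1), 0.99)
  expect_equal(epsilonSchedule(3), 0.33)
  expect_equal(epsilonSchedule(100), 0.1)
  eps <- epsilonSchedule(1:500)
  expect_true(all(diff(eps) <= 0))
  expect_true(all(eps >= 0.1))
  expect_error(epsilonSchedule(0), ">= 1")
})

test_that("the tabular Q update matches hand arithmetic and fixed points", {
  Q <- matrix(0, 2, 2)
  Q2 <- qUpdateTabular(Q, 1, 1, r = 1, sNext = 2, alpha = 0.5, gamma = 0.9)
  expect_equal(Q2[1, 1], 0.5)
  expect_identical(Q2[-1], Q[-1])
  # alpha = 0 leaves Q unchanged
  expect_identical(qUpdateTabular(Q2, 1, 1, 1, 2, alpha = 0, gamma = 0.9),
                   Q2)
  # a Bellman-consistent entry is a fixed point
  Qf <- matrix(c(10, 0, 0, 0), 2, 2)
  Qf[1, 1] <- 5 + 0.9 * max(Qf[2, ])
  expect_equal(qUpdateTabular(Qf, 1, 1, 5, 2, 0.7, 0.9), Qf)
})

test_that("tabular Q-learning converges to value iteration on a 5-state MDP", {
  # deterministic chain: action 1 moves right (reward 1 at the end),
  # action 2 resets to state 1 (reward 0); state 5 absorbing
  nS <- 5L
  transition <- cbind(pmin(1:5 + 1L, 5L), rep(1L, 5))
  transition[5, ] <- 5L
  rewardMat <- cbind(c(0, 0, 0, 1, 0), rep(0, 5))
  gamma <- 0.8
  Qstar <- valueIteration(transition, rewardMat, gamma)
  set.seed(1)
  Q <- matrix(0, nS, 2)
  visits <- matrix(0, nS, 2)
  for (it in 1:20000) {
    s <- sample.int(nS, 1)
    a <- sample.int(2L, 1)
    visits[s, a] <- visits[s, a] + 1
    alpha <- 1 / (visits[s, a]^0.7)
    Q <- qUpdateTabular(Q, s, a, rewardMat[s, a], transition[s, a],
                        alpha, gamma)
  }
  expect_lt(max(abs(Q - Qstar)), 1e-3)
})

test_that("network losses match their scalar definitions", {
  mapping <- lapply(1:8, function(p) ((p - 1L) %% 21L) + c(1L, 2L))
  pNet <- denseNet(c(21, 6, 8), seed = 1)
  aNet <- denseNet(c(42, 6, 2), seed = 2)
  set.seed(3)
  batch <- lapply(1:6, function(i)
    list(s = runif(21), p = sample(8, 1), a = sample(2, 1),
         r = rnorm(1), sNext = runif(21)))
  lA <- actionNetLoss(batch, aNet, pNet, gamma = 0.9, mapping)
  # manual recomputation
  manual <- mean(vapply(batch, function(t) {
    pred <- netForward(aNet, c(structureCodedVector(t$s, t$p, mapping),
                               t$s))[1, t$a]
    targ <- t$r + 0.9 * max(netForward(pNet, t$sNext))
    (pred - targ)^2
  }, numeric(1)))
  expect_equal(lA, manual, tolerance = 1e-12)
  expect_gte(lA, 0)
  # permutation invariance
  expect_equal(actionNetLoss(rev(batch), aNet, pNet, 0.9, mapping), lA)

  lP <- parameterNetLoss(batch, pNet, aNet, mapping)
  manualP <- mean(vapply(batch, function(t) {
    pred <- netForward(pNet, t$s)[1, t$p]
    targ <- max(netForward(aNet, c(structureCodedVector(t$s, t$p, mapping),
                                   t$s)))
    (pred - targ)^2
  }, numeric(1)))
  expect_equal(lP, manualP, tolerance = 1e-12)
  expect_gte(lP, 0)
})

test_that("backprop gradients agree with finite differences", {
  net <- denseNet(c(4, 3, 2), seed = 9)
  set.seed(10)
  X <- matrix(runif(8), 2, 4)
  sel <- c(1L, 2L)
  targ <- c(0.3, -0.2)
  gr <- vtplanner:::netGradients(net, X, sel, targ)
  lossAt <- function(net) {
    pred <- netForward(net, X)[cbind(1:2, sel)]
    mean((pred - targ)^2)
  }
  h <- 1e-6
  for (li in 1:2) for (k in 1:2) {
    pert <- net
    pert@layers[[li]]$W[k, 1] <- pert@layers[[li]]$W[k, 1] + h
    num <- (lossAt(pert) - gr$loss) / h
    expect_equal(gr$grads[[li]]$dW[k, 1], num, tolerance = 1e-4)
  }
})

test_that("the replay buffer caps capacity and samples reproducibly", {
  buf <- replayBuffer(5L)
  for (i in 1:8) buf$push(list(i = i))
  expect_equal(buf$size(), 5L)
  set.seed(1); s1 <- buf$sample(3)
  set.seed(1); s2 <- buf$sample(3)
  expect_identical(s1, s2)
})

test_that("training is a no-op for zero episodes and reproducible otherwise", {
  env <- toyEnv(2L)
  h0 <- trainingHyperparams(episodes = 0L, seed = 1L, hidden = c(8L, 4L))
  out <- trainVtp(env, h0)
  expect_equal(nrow(out$history), 0L)
  expect_identical(out$pNet@layers,
                   denseNet(c(21, 8, 4, 8), seed = 102L)@layers)

  h <- trainingHyperparams(episodes = 12L, stepsPerEpisode = 4L,
                           batchSize = 8L, hidden = c(8L, 4L), seed = 5L)
  r1 <- trainVtp(toyEnv(2L), h)
  r2 <- trainVtp(toyEnv(2L), h)
  expect_identical(r1$pNet@layers, r2$pNet@layers)
  expect_identical(r1$aNet@layers, r2$aNet@layers)
  expect_identical(r1$history, r2$history)
  # bookkeeping: one row per executed step, epsilon trace per schedule
  expect_equal(nrow(r1$history), 12L * 4L)
  expect_equal(r1$history$epsilon,
               rep(epsilonSchedule(1:12), each = 4L))
  expect_true(all(r1$history$stepSize %in% c(3, 6)))
})

test_that("the agent learns the rewarding parameter in the toy environment", {
  # one TPP raises the plan score, all others lower it; after training the
  # greedy Parameter-Net should pick it in >= 90% of evaluation states
  # pooled over 10 seeds
  accs <- vapply(1:10, function(sd) {
    fit <- trainVtp(toyEnv(3L),
      trainingHyperparams(episodes = 200L, stepsPerEpisode = 5L,
                          alpha = 1e-3, hidden = c(32L, 16L),
                          seed = sd))
    set.seed(1000 + sd)
    mean(replicate(20, selectTpp(runif(21), fit$pNet) == 3L))
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})
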