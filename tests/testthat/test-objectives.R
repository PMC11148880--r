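test_that("the packaged template transcribes the planning configuration", {
  os <- loadObjectiveTemplate()
  df <- objectivesTable(os)
  # first objective: PTV63 lower dose-volume constraint
  expect_equal(df$structure[1], "PTV63")
  expect_equal(df$dose_cGy[1], 6330)
  expect_equal(df$volume_pct[1], 99.9)
  expect_equal(df$priority[1], 90)
  expect_equal(df$type[1], "lower")

  ct <- objectiveCounts(os)
  expect_equal(ct$objectives, 47L)
  expect_equal(ct$lower, 20L)
  expect_equal(ct$upper, 18L)
  expect_equal(ct$mean, 9L)
  expect_equal(ct$structures, 26L)
  expect_equal(ct$fixed, 36L)
  expect_equal(ct$adjustable, 11L)
  expect_equal(ct$placeholders, 8L)
  expect_equal(ct$sharedAuxiliary, 3L)
  expect_equal(ct$parameterSlots, 141L)
})

test_that("template binds to the phantom and unknown structures fail late", {
  os <- loadObjectiveTemplate()
  ss <- deriveAuxiliaryStructures(generatePhantom(miniPhantomSpec(1)))
  im <- buildInfluenceMatrix(ss, beamletWidthMm = 7)
  expect_silent(bound <- bindObjectives(os, ss, im))
  # a template naming a structure the phantom lacks loads fine but the
  # binding reports the offending name
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    priority_bounds = c(1, 100),
    initial_priorities = list(P1 = 50),
    objectives = list(
      list(structure = "NoSuchOrgan", dose_cGy = 1000, volume_pct = 0,
           priority = "P1", type = "upper"))), tmp)
  os2 <- loadObjectiveTemplate(tmp)
  expect_s4_class(os2, "ObjectiveSet")
  expect_error(bindObjectives(os2, ss, im), "NoSuchOrgan")
})

test_that("priority application is shared, idempotent, and bounded", {
  os <- loadObjectiveTemplate()
  pv <- setNames(c(40, 50, 60, 70, 35, 45, 55, 65), paste0("P", 1:8))
  os2 <- applyPriorities(os, pv)
  df <- objectivesTable(os2)
  # P2 drives both left-parotid mean rows (primary and _opti auxiliary)
  p2rows <- which(df$placeholder == "P2")
  expect_setequal(df$structure[p2rows], c("L Parotid", "L Parotid_opti"))
  expect_true(all(df$priority[p2rows] == 50))
  p7rows <- which(df$placeholder == "P7")
  expect_true(all(df$priority[p7rows] == 55))
  # fixed objectives untouched
  fixed <- is.na(df$placeholder)
  expect_identical(df$priority[fixed], objectivesTable(os)$priority[fixed])
  # idempotent
  expect_identical(objectivesTable(applyPriorities(os2, pv)), df)
  expect_identical(unname(currentPriorities(os2)), unname(pv))
  expect_error(applyPriorities(os, setNames(c(0, rep(50, 7)),
                                            paste0("P", 1:8))), "\\[1, 100\\]")
})

test_that("penalties match hand arithmetic and the voxel-loop oracle", {
  g <- voxelGrid(c(3, 1, 1), c(10, 10, 10))
  m <- array(TRUE, g@shape)
  ss <- tinySS(g, list(S = m))
  im <- new("InfluenceMatrix", A = Matrix::Matrix(diag(3), sparse = TRUE),
            beamAnglesDeg = 0,
            beamlets = data.frame(beam = rep(1, 3), offsetMm = 1:3),
            bodyIndex = which(array(TRUE, g@shape)), params = list())
  mkOs <- function(rows) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(priority_bounds = c(1, 100),
                          initial_priorities = list(P1 = 50),
                          objectives = rows), tmp)
    loadObjectiveTemplate(tmp)
  }
  # mean-upper objective: tau 15, doses (10,20,30), lambda 2 -> 2*(20-15)^2
  os <- mkOs(list(list(structure = "S", dose_cGy = 15, priority = 2,
                       type = "mean")))
  bound <- bindObjectives(os, ss, im)
  val <- objectiveValue(c(10, 20, 30), os, bound)
  expect_equal(val$total, 2 * (20 - 15)^2)
  # satisfied objective scores exactly zero
  expect_equal(objectiveValue(c(5, 10, 15), os, bound)$total, 0)

  # upper DVC on a 10-voxel structure vs an exhaustive voxel loop
  g10 <- voxelGrid(c(10, 1, 1), c(5, 5, 5))
  ss10 <- tinySS(g10, list(S = array(TRUE, g10@shape)))
  im10 <- new("InfluenceMatrix",
              A = Matrix::Matrix(diag(10), sparse = TRUE),
              beamAnglesDeg = 0,
              beamlets = data.frame(beam = rep(1, 10), offsetMm = 1:10),
              bodyIndex = 1:10, params = list())
  set.seed(5)
  for (V in c(0, 20, 50)) {
    osU <- mkOs(list(list(structure = "S", dose_cGy = 40, volume_pct = V,
                          priority = 3, type = "upper")))
    bU <- bindObjectives(osU, ss10, im10)
    d <- runif(10, 0, 100)
    # oracle: D_V = dose at volume V (k-th largest), penalize (tau, D_V]
    n <- 10; tau <- 40
    k <- min(n, max(1, ceiling(V / 100 * n)))
    dV <- sort(d, decreasing = TRUE)[k]
    pen <- 0
    for (j in 1:n) if (d[j] > tau && d[j] <= dV) pen <- pen + (d[j] - tau)^2
    expect_equal(objectiveValue(d, osU, bU)$total, 3 * pen / n,
                 tolerance = 1e-12, label = paste("V =", V))
  }
  # lower DVC symmetric rule
  osL <- mkOs(list(list(structure = "S", dose_cGy = 60, volume_pct = 99.9,
                        priority = 4, type = "lower")))
  bL <- bindObjectives(osL, ss10, im10)
  d <- runif(10, 0, 100)
  k <- min(10, max(1, ceiling(0.999 * 10)))
  dV <- sort(d, decreasing = TRUE)[k]
  pen <- sum((d[d < 60 & d >= dV] - 60)^2)
  expect_equal(objectiveValue(d, osL, bL)$total, 4 * pen / 10,
               tolerance = 1e-12)
})

test_that("the optimizer descends monotonically to the constrained optimum", {
  # 2-beamlet, 2-voxel problem pinched between a lower and an upper
  # objective at the same dose: the unique optimum is the closed-form
  # nonnegative least-squares solution d = (10, 10), i.e. x = (10, 5) for
  # A = diag(1, 2)
  g <- voxelGrid(c(2, 1, 1), c(10, 10, 10))
  ss <- tinySS(g, list(S = array(TRUE, g@shape)))
  im <- new("InfluenceMatrix",
            A = Matrix::Matrix(diag(c(1, 2)), sparse = TRUE),
            beamAnglesDeg = 0,
            beamlets = data.frame(beam = c(1, 1), offsetMm = 1:2),
            bodyIndex = 1:2, params = list())
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(priority_bounds = c(1, 100),
    initial_priorities = list(P1 = 50),
    objectives = list(list(structure = "S", dose_cGy = 10,
                           volume_pct = 99.9, priority = 50,
                           type = "lower"),
                      list(structure = "S", dose_cGy = 10,
                           volume_pct = 0, priority = 50,
                           type = "upper"))), tmp)
  os <- loadObjectiveTemplate(tmp)
  bound <- bindObjectives(os, ss, im)
  sol <- optimizeFluence(im, os, bound, maxIters = 500L, tol = 1e-14)
  expect_equal(sol$x, c(10, 5), tolerance = 1e-6)
  expect_true(all(diff(sol$trace) <= 0))

  # empty objective set: x0 returned unchanged
  osEmpty <- os
  osEmpty@objectives <- os@objectives[0, ]
  osEmpty@adjustableMap <- list()
  x0 <- c(3, 4)
  expect_identical(optimizeFluence(im, osEmpty,
    bindObjectives(os, ss, im), x0 = x0)$x, x0)
  expect_error(optimizeFluence(im, os, bound, x0 = c(-1, 0)), "nonnegative")
})

test_that("a whole-body zero-mean objective drives the dose to zero", {
  ss <- deriveAuxiliaryStructures(generatePhantom(miniPhantomSpec(1)))
  im <- buildInfluenceMatrix(ss, beamletWidthMm = 7)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(priority_bounds = c(1, 100),
    initial_priorities = list(P1 = 50),
    objectives = list(list(structure = "BODY", dose_cGy = 0, priority = 50,
                           type = "mean"))), tmp)
  os <- loadObjectiveTemplate(tmp)
  bound <- bindObjectives(os, ss, im)
  x0 <- rep(1, nBeamlets(im))
  sol <- optimizeFluence(im, os, bound, x0 = x0, maxIters = 300L)
  expect_lt(mean(sol$dose), 1e-3 * mean(computeDose(im, x0)))
})

test_that("optimization is deterministic and respects priority monotonicity", {
  ss <- deriveAuxiliaryStructures(generatePhantom(miniPhantomSpec(1)))
  im <- buildInfluenceMatrix(ss, beamletWidthMm = 7)
  os <- loadObjectiveTemplate()
  bound <- bindObjectives(os, ss, im)
  s1 <- optimizeFluence(im, os, bound, maxIters = 80L)
  s2 <- optimizeFluence(im, os, bound, maxIters = 80L)
  expect_identical(s1$x, s2$x)
  expect_true(all(diff(s1$trace) <= 0))

  # raising one adjustable priority tenfold must not worsen its own penalty
  target <- adjustableMap(os)$P5[1]   # oral-cavity mean objective
  pv <- os@initialPriorities
  pvHigh <- pv; pvHigh["P5"] <- min(pv["P5"] * 10, 100)
  osHigh <- applyPriorities(os, pvHigh)
  sHigh <- optimizeFluence(im, osHigh, bound, maxIters = 80L)
  pLow <- objectiveValue(s1$dose, os, bound)$perObjective[target]
  pHigh <- objectiveValue(sHigh$dose, osHigh, bound)$perObjective[target]
  expect_lte(pHigh, pLow + 1e-9)
})
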