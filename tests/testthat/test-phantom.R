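test_that("phantom generation is deterministic and respects containment", {
  spec <- phantomSpec(seed = 11)
  ss1 <- generatePhantom(spec)
  ss2 <- generatePhantom(spec)
  expect_identical(ss1@masks, ss2@masks)

  body <- structureMask(ss1, "BODY")
  for (n in setdiff(structureNames(ss1), "BODY"))
    expect_true(all(!structureMask(ss1, n) | body), label = n)
  # CTVs nest inside their PTVs, PTVs nest across prescription levels
  for (lev in c("54", "57", "60", "63"))
    expect_true(all(!structureMask(ss1, paste0("CTV", lev)) |
                    structureMask(ss1, paste0("PTV", lev))))
  expect_true(all(!structureMask(ss1, "PTV63") | structureMask(ss1, "PTV60")))
  expect_true(all(!structureMask(ss1, "PTV60") | structureMask(ss1, "PTV57")))
  expect_true(all(!structureMask(ss1, "PTV57") | structureMask(ss1, "PTV54")))
})

test_that("required target-organ overlaps are nonempty", {
  ss <- generatePhantom(phantomSpec(seed = 1))
  ptv54 <- structureMask(ss, "PTV54")
  for (organ in c("Oral Cavity", "Constrictor", "L Parotid", "R Parotid",
                  "Esophagus"))
    expect_gt(sum(ptv54 & structureMask(ss, organ)), 0, label = organ)
})

test_that("an undersized grid raises an explicit infeasibility error", {
  expect_error(generatePhantom(phantomSpec(seed = 1, shape = c(8, 8, 1),
                                           spacingMm = c(4, 4, 4))),
               "infeasible")
})

test_that("expansion matches the brute-force distance oracle", {
  # single voxel, 1 mm spacing, 5 mm margin: exactly the 5 mm ball
  g <- voxelGrid(c(13, 13, 1), c(1, 1, 1))
  m <- array(FALSE, dim = g@shape); m[7, 7, 1] <- TRUE
  expect_identical(expandMask(m, g, 5), bfExpand(m, g, 5))

  # zero margin is the identity; result always contains the input
  set.seed(42)
  g2 <- voxelGrid(c(6, 5, 4), c(2, 3, 2.5))
  for (rep in 1:5) {
    m2 <- randomMask(g2)
    expect_identical(expandMask(m2, g2, 0), m2)
    ex <- expandMask(m2, g2, 4)
    expect_true(all(!m2 | ex))
    expect_identical(ex, bfExpand(m2, g2, 4))
  }
  expect_error(expandMask(m, g, -1), "margin")
})

test_that("overlap cropping matches the exhaustive voxel loop", {
  set.seed(7)
  g <- voxelGrid(c(8, 8, 1), c(2, 2, 2))
  for (rep in 1:5) {
    organ <- randomMask(g, 0.4)
    t1 <- randomMask(g, 0.3); t2 <- randomMask(g, 0.3)
    expect_identical(cropOverlap(organ, list(t1, t2)),
                     bfCrop(organ, list(t1, t2)))
  }
  # disjoint targets leave the organ unchanged; covering targets empty it
  organ <- array(FALSE, g@shape); organ[1:3, 1:3, 1] <- TRUE
  far <- array(FALSE, g@shape); far[6:8, 6:8, 1] <- TRUE
  expect_identical(cropOverlap(organ, far), organ)
  expect_false(any(cropOverlap(organ, organ)))
  expect_error(cropOverlap(organ, array(FALSE, c(2, 2, 2))), "same grid")
})

test_that("inner ring matches the boundary-distance oracle", {
  g <- voxelGrid(c(26, 26, 1), c(1, 1, 1))
  sq <- array(FALSE, g@shape); sq[4:23, 4:23, 1] <- TRUE
  ring <- innerRing(sq, g, 3)
  expect_identical(ring, bfRing(sq, g, 3))
  expect_true(all(!ring | sq))
  # a width at least half the extent leaves nothing to erode
  expect_identical(innerRing(sq, g, 15), sq)
  expect_error(innerRing(sq, g, 0), "width")

  set.seed(3)
  g2 <- voxelGrid(c(7, 7, 3), c(2, 2, 2))
  for (rep in 1:4) {
    m <- randomMask(g2, 0.5)
    expect_identical(innerRing(m, g2, 2.5), bfRing(m, g2, 2.5))
  }
})

test_that("auxiliary derivation yields the 26 template structures and is idempotent", {
  ss <- generatePhantom(phantomSpec(seed = 5))
  aug <- deriveAuxiliaryStructures(ss)
  expect_true(all(planningStructureNames() %in% structureNames(aug)))
  expect_length(planningStructureNames(), 26L)
  # originals unchanged
  for (n in structureNames(ss))
    expect_identical(aug@masks[[n]], ss@masks[[n]])
  # Cord+5mm contains the cord; push rings sit inside their targets
  expect_true(all(!structureMask(aug, "Cord") |
                  structureMask(aug, "Cord+5mm")))
  expect_true(all(!structureMask(aug, "PTV54_push") |
                  structureMask(aug, "PTV54")))
  # idempotent: re-deriving reproduces identical masks
  aug2 <- deriveAuxiliaryStructures(aug)
  expect_identical(aug2@masks, aug@masks)
  # missing prerequisite is a named error
  ss2 <- ss
  ss2@masks[["Trachea"]] <- NULL
  ss2@roles <- ss2@roles[names(ss2@roles) != "Trachea"]
  expect_error(deriveAuxiliaryStructures(ss2), "Trachea")
})

test_that("a parotid disjoint from all PTVs crops to itself", {
  g <- voxelGrid(c(10, 10, 1), c(3, 3, 3))
  par <- array(FALSE, g@shape); par[1:2, 1:2, 1] <- TRUE
  ptv <- array(FALSE, g@shape); ptv[6:9, 6:9, 1] <- TRUE
  expect_identical(cropOverlap(par, ptv), par)
})

test_that("structure sets serialize round-trip and byte-identically", {
  ss <- generatePhantom(miniPhantomSpec(seed = 2))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeStructureSet(ss, f1)
  back <- readStructureSet(f1)
  expect_identical(back@masks, ss@masks)
  expect_equal(back@grid@spacingMm, ss@grid@spacingMm)
  writeStructureSet(generatePhantom(miniPhantomSpec(seed = 2)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
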