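# Synthetic head-and-neck phantom generation and the structure algebra
# (expansion, overlap cropping, inner rings) used to derive the auxiliary
# planning structures. All distances are physical (mm) on voxel centres, so
# the morphology is spacing-independent.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Voxel-centre coordinates (mm), centred on the grid. Returns a list of three
# arrays of grid shape.
voxelCoords <- function(grid) {
  sh <- grid@shape; sp <- grid@spacingMm
  ax <- lapply(1:3, function(k) (seq_len(sh[k]) - 0.5) * sp[k] - sh[k] * sp[k] / 2)
  list(x = array(rep(ax[[1]], times = sh[2] * sh[3]), dim = sh),
       y = array(rep(rep(ax[[2]], each = sh[1]), times = sh[3]), dim = sh),
       z = array(rep(ax[[3]], each = sh[1] * sh[2]), dim = sh))
}

# Axis-aligned ellipsoid mask; semi-axis zero or less on a degenerate axis is
# treated as "span the whole axis" so single-slice grids work naturally.
ellipsoidMask <- function(grid, center, semi) {
  co <- voxelCoords(grid)
  term <- function(v, c, a) if (a <= 0) 0 else ((v - c) / a)^2
  q <- term(co$x, center[1], semi[1]) + term(co$y, center[2], semi[2]) +
       term(co$z, center[3], semi[3])
  array(q <= 1, dim = grid@shape)
}

#' Specification of a synthetic head-and-neck phantom
#'
#' Describes a simplified, fully synthetic axial head-and-neck geometry:
#' an elliptical body contour, four nested planning target volumes at the
#' prescription levels 6300/6000/5700/5400 cGy, their clinical target
#' volumes, and the organs at risk. The default geometry guarantees the
#' clinically characteristic overlaps: the 54 Gy PTV intersects the oral
#' cavity, the pharyngeal constrictor, both parotid glands, and the
#' esophagus. Structure placement is jittered by a seeded RNG so distinct
#' seeds emulate distinct patients; the same seed always reproduces the
#' identical phantom.
#'
#' @param seed integer RNG seed.
#' @param shape integer(3) voxel counts (default a single-slice 64 x 64 grid).
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @param jitterMm maximum absolute positional jitter applied per structure.
#' @param sizeJitter maximum relative size jitter per structure.
#' @return A list of class `"PhantomSpec"`.
#' @examples
#' spec <- phantomSpec(seed = 1)
#' ss <- generatePhantom(spec)
#' ss
#' @export
phantomSpec <- function(seed = 1L, shape = c(72L, 72L, 1L),
                        spacingMm = c(3, 3, 3), jitterMm = 3,
                        sizeJitter = 0.05) {
  grid <- voxelGrid(shape, spacingMm)
  spec <- list(
    seed = as.integer(seed), grid = grid,
    prescriptionLevelsCGy = c(6300, 6000, 5700, 5400),
    jitterMm = jitterMm, sizeJitter = sizeJitter,
    # centres/semi-axes in mm, axial plane (x lateral, y anterior+)
    body = list(center = c(0, 0), semi = c(85, 98)),
    organs = list(
      `Oral Cavity`     = list(center = c(0, 45),    semi = c(30, 25)),
      Cord              = list(center = c(0, -74),   semi = c(6, 6)),
      Brainstem         = list(center = c(0, -88),   semi = c(7, 7)),
      Esophagus         = list(center = c(0, -58),   semi = c(8, 8)),
      Constrictor       = list(center = c(0, -50),   semi = c(16, 7)),
      `L Parotid`       = list(center = c(-74, -15), semi = c(10, 16)),
      `R Parotid`       = list(center = c(74, -15),  semi = c(10, 16)),
      `Brachial Plexus` = list(center = c(-56, -40), semi = c(8, 8)),
      Trachea           = list(center = c(0, 72),    semi = c(8, 8))),
    # target geometry: PTV54 = wide bilateral ellipse + posterior nodal
    # lobe; inner levels are ellipses intersected with the next-outer level
    # so nesting PTV63 subset PTV60 subset PTV57 subset PTV54 holds by
    # construction
    targets = list(
      PTV54main = list(center = c(0, -5),  semi = c(72, 38)),
      PTV54lobe = list(center = c(0, -46), semi = c(13, 13)),
      PTV57     = list(center = c(-20, 0), semi = c(36, 30)),
      PTV60     = list(center = c(-26, 5), semi = c(26, 22)),
      PTV63     = list(center = c(-30, 9), semi = c(17, 15))),
    ctvMarginMm = 3,
    requiredOverlaps = list(
      c("PTV54", "Oral Cavity"), c("PTV54", "Constrictor"),
      c("PTV54", "L Parotid"), c("PTV54", "R Parotid"),
      c("PTV54", "Esophagus")))
  class(spec) <- "PhantomSpec"
  spec
}

#' Generate a synthetic phantom from a specification
#'
#' Produces the body mask, four nested PTVs, their CTVs (3 mm inner margins)
#' and the organs at risk, with seeded positional jitter. The generation is
#' deterministic given the spec (including its seed) and fails with an
#' explicit infeasibility error when the grid cannot accommodate the
#' geometry or a required target-organ overlap is empty.
#'
#' @param spec a `"PhantomSpec"` from [phantomSpec()].
#' @return A [StructureSet-class] with roles body/target/organ.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  grid <- spec$grid
  extent <- grid@shape * grid@spacingMm
  if (extent[1] < 2 * spec$body$semi[1] || extent[2] < 2 * spec$body$semi[2])
    stop("phantom generation infeasible: grid physical extent ",
         sprintf("%.0fx%.0f mm", extent[1], extent[2]),
         " cannot contain the body contour")

  masks <- withSeed(spec$seed, {
    jit <- function(geom) {
      d <- stats::runif(2, -spec$jitterMm, spec$jitterMm)
      f <- 1 + stats::runif(1, -spec$sizeJitter, spec$sizeJitter)
      list(center = geom$center + d, semi = geom$semi * f)
    }
    body <- ellipsoidMask(grid, c(spec$body$center, 0), c(spec$body$semi, 0))
    organs <- lapply(spec$organs, function(g) {
      g2 <- jit(g)
      ellipsoidMask(grid, c(g2$center, 0), c(g2$semi, 0)) & body
    })
    tg <- lapply(spec$targets, function(g) {
      g2 <- jit(g)
      ellipsoidMask(grid, c(g2$center, 0), c(g2$semi, 0)) & body
    })
    ptv54 <- tg$PTV54main | tg$PTV54lobe
    ptv57 <- tg$PTV57 & ptv54
    ptv60 <- tg$PTV60 & ptv57
    ptv63 <- tg$PTV63 & ptv60
    targets <- list(PTV54 = ptv54, PTV57 = ptv57, PTV60 = ptv60, PTV63 = ptv63)
    ctvs <- lapply(targets, function(m) erodeMask(m, grid, spec$ctvMarginMm))
    names(ctvs) <- sub("PTV", "CTV", names(targets))
    c(list(BODY = body), targets, ctvs, organs)
  })

  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty) > 0)
    stop("phantom generation infeasible: empty structure(s) ",
         paste(empty, collapse = ", "),
         " (grid too coarse or too small for the geometry)")
  for (ov in spec$requiredOverlaps) {
    if (!any(masks[[ov[1]]] & masks[[ov[2]]]))
      stop(sprintf(
        "phantom generation infeasible: required overlap %s ~ %s is empty",
        ov[1], ov[2]))
  }

  roles <- c(BODY = "body",
             setNames(rep("target", 8),
                      c("PTV54", "PTV57", "PTV60", "PTV63",
                        "CTV54", "CTV57", "CTV60", "CTV63")),
             setNames(rep("organ", length(spec$organs)), names(spec$organs)))
  structureSet(grid, masks[names(roles)], roles)
}

# Integer voxel offsets whose centre-to-centre physical distance is within
# marginMm. Always includes the zero offset.
ballOffsets <- function(grid, marginMm) {
  sp <- grid@spacingMm
  r <- pmin(floor(marginMm / sp), grid@shape - 1L)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  dist <- sqrt((off$dx * sp[1])^2 + (off$dy * sp[2])^2 + (off$dz * sp[3])^2)
  off[dist <= marginMm + 1e-9, , drop = FALSE]
}

# OR a shifted copy of `mask` into `acc` (shift in voxel units).
shiftOr <- function(acc, mask, dx, dy, dz) {
  sh <- dim(mask)
  xs <- max(1, 1 + dx):min(sh[1], sh[1] + dx)
  ys <- max(1, 1 + dy):min(sh[2], sh[2] + dy)
  zs <- max(1, 1 + dz):min(sh[3], sh[3] + dz)
  if (length(xs) < 1 || length(ys) < 1 || length(zs) < 1) return(acc)
  acc[xs, ys, zs] <- acc[xs, ys, zs] | mask[xs - dx, ys - dy, zs - dz]
  acc
}

#' Isotropic mask expansion (morphological dilation) in physical units
#'
#' A voxel belongs to the result iff some voxel of the input mask has its
#' centre within `marginMm` of that voxel's centre. Margin 0 is the identity
#' and the result always contains the input.
#'
#' @param mask logical array conforming to `grid`.
#' @param grid the [VoxelGrid-class] of the mask.
#' @param marginMm expansion margin in mm (>= 0).
#' @return Logical array of the same shape.
#' @export
expandMask <- function(mask, grid, marginMm) {
  if (marginMm < 0) stop("expansion margin must be >= 0")
  stopifnot(identical(dim(mask), grid@shape))
  off <- ballOffsets(grid, marginMm)
  out <- array(FALSE, dim = dim(mask))
  for (i in seq_len(nrow(off)))
    out <- shiftOr(out, mask, off$dx[i], off$dy[i], off$dz[i])
  out
}

#' Mask erosion by a physical margin
#'
#' A voxel survives iff no voxel outside the mask (within the grid) lies
#' within `marginMm` of it; the dual of [expandMask()].
#'
#' @inheritParams expandMask
#' @return Logical array, a subset of `mask`.
#' @export
erodeMask <- function(mask, grid, marginMm) {
  mask & !expandMask(!mask, grid, marginMm)
}

#' Remove target overlap from an organ mask
#'
#' Returns the organ voxels that belong to none of the target masks:
#' `organ AND NOT (union of targets)`. This is how the `_opti` auxiliary
#' optimization structures are built for organs overlapping the PTVs.
#'
#' @param organMask logical array.
#' @param targetMasks a single logical array or list of them, same grid.
#' @return Logical array.
#' @export
cropOverlap <- function(organMask, targetMasks) {
  if (is.array(targetMasks) || is.logical(targetMasks))
    targetMasks <- list(targetMasks)
  for (m in targetMasks)
    if (!identical(dim(m), dim(organMask)))
      stop("cropOverlap: masks are not on the same grid")
  organMask & !Reduce(`|`, targetMasks)
}

#' Inner ring of a mask
#'
#' The band of voxels within `widthMm` of the mask boundary: the mask minus
#' its erosion by `widthMm`. Used for the `_push` target-periphery
#' structures that force sufficient peripheral target dose.
#'
#' @inheritParams expandMask
#' @param widthMm ring width in mm (> 0).
#' @return Logical array, a subset of `mask`.
#' @export
innerRing <- function(mask, grid, widthMm) {
  if (widthMm <= 0) stop("ring width must be > 0")
  mask & !erodeMask(mask, grid, widthMm)
}

#' Derive the auxiliary planning structures
#'
#' Adds the auxiliary structures used by the objective template to a phantom
#' containing the primary targets and organs:
#' `L/R Parotid_opti`, `Oral Cavity_opti` and `Constrictor_opti` (organ
#' cropped of all PTVs), `Cord+5mm` (5 mm cord expansion), `PTV54_push` and
#' `PTV57_push` (3 mm inner rings), `PTV_all` (union of the PTVs),
#' `PTV-CTV63` (PTV union minus the boost CTV), and the dose-control regions
#' `Avoidance1` (posterior neck band), `Avoidance2` (oral-cavity expansion
#' minus the PTVs) and `Avoidance3` (central trachea tube minus the PTVs).
#' Original masks are left untouched; re-running overwrites the derived
#' masks with identical content.
#'
#' @param ss a [StructureSet-class] with the primary structures.
#' @return The augmented [StructureSet-class].
#' @export
deriveAuxiliaryStructures <- function(ss) {
  need <- c("PTV54", "PTV57", "PTV60", "PTV63", "CTV63", "L Parotid",
            "R Parotid", "Oral Cavity", "Constrictor", "Cord", "Trachea")
  missing <- setdiff(need, structureNames(ss))
  if (length(missing) > 0)
    stop("deriveAuxiliaryStructures: missing prerequisite structure(s): ",
         paste(missing, collapse = ", "))
  grid <- ss@grid
  body <- structureMask(ss, bodyName(ss))
  ptvs <- lapply(c("PTV54", "PTV57", "PTV60", "PTV63"),
                 function(n) structureMask(ss, n))
  ptvAll <- Reduce(`|`, ptvs)

  aux <- list(
    `L Parotid_opti`   = cropOverlap(structureMask(ss, "L Parotid"), ptvs),
    `R Parotid_opti`   = cropOverlap(structureMask(ss, "R Parotid"), ptvs),
    `Oral Cavity_opti` = cropOverlap(structureMask(ss, "Oral Cavity"), ptvs),
    `Constrictor_opti` = cropOverlap(structureMask(ss, "Constrictor"), ptvs),
    `Cord+5mm`  = expandMask(structureMask(ss, "Cord"), grid, 5) & body,
    PTV54_push  = innerRing(structureMask(ss, "PTV54"), grid, 3),
    PTV57_push  = innerRing(structureMask(ss, "PTV57"), grid, 3),
    PTV_all     = ptvAll,
    `PTV-CTV63` = ptvAll & !structureMask(ss, "CTV63"))

  # dose-control regions: posterior neck band behind the cord level, an
  # oral-cavity shell, and the central trachea tube, all cropped of targets
  co <- voxelCoords(grid)
  aux$Avoidance1 <- body & (co$y < -72) & !ptvAll
  aux$Avoidance2 <-
    (expandMask(structureMask(ss, "Oral Cavity"), grid, 10) & body) & !ptvAll
  aux$Avoidance3 <-
    (expandMask(structureMask(ss, "Trachea"), grid, 3) & body) & !ptvAll

  masks <- ss@masks
  roles <- ss@roles
  for (n in names(aux)) {
    masks[[n]] <- aux[[n]]
    roles[n] <- "auxiliary"
  }
  structureSet(grid, masks, roles)
}

#' The 26 planning-structure names of the default objective template
#'
#' @return Character vector of the 26 structure names bound by the shipped
#'   head-and-neck objective template.
#' @export
planningStructureNames <- function() {
  c("PTV63", "PTV60", "PTV57", "PTV54",
    "CTV63", "CTV60", "CTV57", "CTV54",
    "PTV57_push", "PTV54_push", "PTV_all", "PTV-CTV63",
    "Brainstem", "Cord+5mm", "Esophagus",
    "Avoidance1", "Avoidance2", "Avoidance3",
    "L Parotid", "L Parotid_opti", "R Parotid", "R Parotid_opti",
    "Oral Cavity_opti", "Constrictor", "Constrictor_opti",
    "Brachial Plexus")
}
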