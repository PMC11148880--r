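# Linear beamlet dose model d = A x: equispaced coplanar beams, ray-traced
# exponential depth attenuation and Gaussian lateral penumbra. This is a
# deliberately simplified photon model: the planning method only requires a
# linear, nonnegative dose operator, not clinically accurate physics.

#' Build the beamlet influence matrix for a phantom
#'
#' Places `nBeams` equispaced coplanar beams around the phantom. Each beam
#' carries a row of beamlets of width `beamletWidthMm` covering the lateral
#' projection of the union of the PTVs with a 5 mm margin. The dose a
#' beamlet deposits in a body voxel is `exp(-mu * depth)` (depth measured
#' from the body surface along the beam axis, entry resolved per lateral
#' bin) times a Gaussian lateral profile with standard deviation `sigmaMm`,
#' truncated at 3 sigma. The construction is deterministic.
#'
#' @param ss a [StructureSet-class] containing the body and the PTVs (or a
#'   `PTV_all` union; if absent, the union of masks whose role is target is
#'   used).
#' @param nBeams number of equispaced coplanar beams (>= 1).
#' @param beamletWidthMm beamlet width along the lateral axis (> 0).
#' @param muPerMm linear attenuation coefficient per mm (> 0).
#' @param sigmaMm Gaussian penumbra standard deviation in mm (> 0).
#' @param marginMm lateral margin added around the target projection.
#' @return An [InfluenceMatrix-class].
#' @export
buildInfluenceMatrix <- function(ss, nBeams = 5L, beamletWidthMm = 5,
                                 muPerMm = 0.005, sigmaMm = 3,
                                 marginMm = 5) {
  stopifnot(nBeams >= 1L, beamletWidthMm > 0, muPerMm > 0, sigmaMm > 0)
  grid <- ss@grid
  body <- structureMask(ss, bodyName(ss))
  if (!any(body)) stop("buildInfluenceMatrix: empty body mask")
  bodyIndex <- which(body)
  co <- voxelCoords(grid)
  vx <- co$x[bodyIndex]; vy <- co$y[bodyIndex]

  if ("PTV_all" %in% structureNames(ss)) {
    tmask <- structureMask(ss, "PTV_all")
  } else {
    tnames <- names(ss@roles)[ss@roles == "target"]
    if (length(tnames) == 0) tmask <- body
    else tmask <- Reduce(`|`, lapply(tnames, function(n) structureMask(ss, n)))
  }
  tIdx <- which(tmask)
  tx <- co$x[tIdx]; ty <- co$y[tIdx]

  angles <- (seq_len(nBeams) - 1L) * 360 / nBeams
  trip_i <- list(); trip_j <- list(); trip_v <- list()
  beamlets <- list()
  jOff <- 0L
  for (b in seq_len(nBeams)) {
    a <- angles[b] * pi / 180
    u <- c(cos(a), sin(a))          # beam travel direction
    v <- c(-sin(a), cos(a))         # lateral axis
    along <- vx * u[1] + vy * u[2]
    lat <- vx * v[1] + vy * v[2]
    tlat <- tx * v[1] + ty * v[2]
    lo <- min(tlat) - marginMm; hi <- max(tlat) + marginMm
    nb <- max(1L, ceiling((hi - lo) / beamletWidthMm))
    offsets <- lo + (seq_len(nb) - 0.5) * beamletWidthMm
    # body entry depth per lateral bin (beamlet-width bins over the body)
    bins <- pmin(pmax(floor((lat - lo) / beamletWidthMm), -1L), nb)
    entry <- vapply(c(-1L, seq_len(nb) - 1L, nb), function(k) {
      sel <- bins == k
      if (any(sel)) min(along[sel]) else NA_real_
    }, numeric(1))
    names(entry) <- as.character(c(-1L, seq_len(nb) - 1L, nb))
    entryOfVoxel <- entry[as.character(bins)]
    entryOfVoxel[is.na(entryOfVoxel)] <- min(along)
    depth <- pmax(along - entryOfVoxel, 0)
    att <- exp(-muPerMm * depth)
    for (j in seq_len(nb)) {
      dlat <- lat - offsets[j]
      sel <- abs(dlat) <= 3 * sigmaMm
      if (!any(sel)) { beamlets[[jOff + j]] <- c(b, offsets[j]); next }
      val <- att[sel] * exp(-dlat[sel]^2 / (2 * sigmaMm^2))
      keep <- val > 1e-8
      trip_i[[length(trip_i) + 1L]] <- which(sel)[keep]
      trip_j[[length(trip_j) + 1L]] <- rep.int(jOff + j, sum(keep))
      trip_v[[length(trip_v) + 1L]] <- val[keep]
      beamlets[[jOff + j]] <- c(b, offsets[j])
    }
    jOff <- jOff + nb
  }
  bl <- do.call(rbind, beamlets)
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
    x = unlist(trip_v), dims = c(length(bodyIndex), jOff))
  new("InfluenceMatrix", A = A, beamAnglesDeg = angles,
      beamlets = data.frame(beam = bl[, 1], offsetMm = bl[, 2]),
      bodyIndex = bodyIndex,
      params = list(beamletWidthMm = beamletWidthMm, muPerMm = muPerMm,
                    sigmaMm = sigmaMm, marginMm = marginMm))
}

#' Compute the dose distribution for a fluence vector
#'
#' Applies the linear dose operator: `d = A x` (cGy per unit fluence). The
#' result is a nonnegative numeric vector over the body voxels, ordered as
#' `im@bodyIndex`.
#'
#' @param im an [InfluenceMatrix-class].
#' @param x nonnegative fluence vector of length `nBeamlets(im)`.
#' @return Numeric dose vector (cGy) over body voxels.
#' @export
computeDose <- function(im, x) {
  if (length(x) != ncol(im@A))
    stop(sprintf("computeDose: fluence length %d does not match %d beamlets",
                 length(x), ncol(im@A)))
  if (any(x < 0)) stop("computeDose: fluence must be nonnegative")
  as.numeric(im@A %*% x)
}

#' Indices of a structure's voxels within the dose vector
#'
#' @param ss a [StructureSet-class].
#' @param im the [InfluenceMatrix-class] defining the dose-vector ordering.
#' @param name structure name.
#' @return Integer indices into the dose vector.
#' @export
structureDoseIndex <- function(ss, im, name) {
  m <- structureMask(ss, name)
  idx <- match(which(m), im@bodyIndex)
  if (anyNA(idx))
    stop(sprintf("structure '%s' is not contained in the body mask", name))
  idx
}

#' Rescale a plan to a prescribed target coverage
#'
#' Multiplies the dose by the scale that makes the requested fraction of PTV
#' voxels receive at least the prescription: the scale is
#' `rx / q` where `q` is the `(1 - coverage)` upper dose quantile of the PTV
#' (the k-th largest voxel dose with `k = ceiling(coverage * n)`, ties
#' resolved toward the higher quantile). Mirrors the coverage normalization
#' applied before plan comparison.
#'
#' @param d dose vector.
#' @param ptvIdx indices of the PTV voxels within `d`.
#' @param rxCGy prescription dose in cGy.
#' @param coverage fraction of the PTV required to receive at least `rxCGy`
#'   (0 < coverage <= 1).
#' @return A list with elements `d` (rescaled dose) and `scale`.
#' @export
normalizeToCoverage <- function(d, ptvIdx, rxCGy, coverage) {
  stopifnot(coverage > 0, coverage <= 1, length(ptvIdx) > 0)
  dp <- d[ptvIdx]
  if (all(dp <= 0))
    stop("normalizeToCoverage: PTV dose is identically zero")
  k <- ceiling(coverage * length(dp))
  q <- sort(dp, decreasing = TRUE)[k]
  if (q <= 0)
    stop("normalizeToCoverage: requested coverage quantile is zero")
  scale <- rxCGy / q
  list(d = d * scale, scale = scale)
}
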