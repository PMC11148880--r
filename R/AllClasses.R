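#' @import methods
#' @importFrom Matrix sparseMatrix t colSums
#' @importFrom stats runif rnorm pt sd quantile approx setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' VoxelGrid: a regular 3D voxel lattice
#'
#' Defines the geometry every structure mask and dose array lives on: integer
#' voxel counts per axis and the physical voxel spacing in millimetres.
#' Physical coordinates are centred on the grid: the voxel `(i, j, k)` has its
#' centre at `((i - 0.5) * sx - Lx/2, ...)` where `L` is the physical extent.
#'
#' @slot shape integer(3), voxel counts per axis (all >= 1).
#' @slot spacingMm numeric(3), voxel spacing in mm (all > 0).
#' @export
setClass("VoxelGrid", representation(shape = "integer", spacingMm = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be three voxel counts, each >= 1")
    if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
      return("spacingMm must be three positive spacings")
    TRUE
  })

#' Construct a VoxelGrid
#'
#' @param shape integer vector of length 3 (voxel counts).
#' @param spacingMm numeric vector of length 3 (mm per voxel).
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(c(32, 32, 1), c(7, 7, 7))
#' voxelVolumeCc(g)
#' @export
voxelGrid <- function(shape, spacingMm) {
  new("VoxelGrid", shape = as.integer(shape), spacingMm = as.numeric(spacingMm))
}

#' Voxel volume in cubic centimetres
#' @param grid a [VoxelGrid-class].
#' @return Voxel volume in cc (product of spacings / 1000).
#' @export
voxelVolumeCc <- function(grid) prod(grid@spacingMm) / 1000

#' @rdname VoxelGrid-class
#' @param object a VoxelGrid
#' @export
setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s voxels, spacing %s mm (%.4f cc/voxel)\n",
    paste(object@shape, collapse = "x"),
    paste(object@spacingMm, collapse = "x"), voxelVolumeCc(object)))
})

#' StructureSet: named binary masks on a common voxel grid
#'
#' Holds the body contour, target volumes, organs at risk and auxiliary
#' planning structures of a phantom as logical arrays conforming to one
#' [VoxelGrid-class]. Every mask is constrained to lie inside the body mask.
#'
#' @slot grid the [VoxelGrid-class] the masks conform to.
#' @slot masks named list of logical arrays (TRUE = inside).
#' @slot roles named character, one of `"body"`, `"target"`, `"organ"`,
#'   `"auxiliary"` per mask.
#' @export
setClass("StructureSet",
  representation(grid = "VoxelGrid", masks = "list", roles = "character"),
  validity = function(object) {
    nm <- names(object@masks)
    if (is.null(nm) || anyDuplicated(nm)) return("mask names must be unique")
    if (!identical(sort(nm), sort(names(object@roles))))
      return("roles must name exactly the masks")
    if (!all(object@roles %in% c("body", "target", "organ", "auxiliary")))
      return("unknown role")
    body <- nm[object@roles[nm] == "body"]
    if (length(body) != 1L) return("exactly one mask must have role 'body'")
    for (n in nm) {
      m <- object@masks[[n]]
      if (!is.logical(m) || !identical(dim(m), object@grid@shape))
        return(sprintf("mask '%s' does not conform to the grid", n))
    }
    bm <- object@masks[[body]]
    for (n in setdiff(nm, body))
      if (any(object@masks[[n]] & !bm))
        return(sprintf("mask '%s' is not a subset of the body", n))
    TRUE
  })

#' Construct a StructureSet
#' @param grid a [VoxelGrid-class].
#' @param masks named list of logical arrays with dim equal to `grid@shape`.
#' @param roles named character vector assigning a role to every mask.
#' @return A [StructureSet-class].
#' @export
structureSet <- function(grid, masks, roles) {
  new("StructureSet", grid = grid, masks = masks,
      roles = roles[names(masks)])
}

#' @rdname StructureSet-class
#' @param object a StructureSet
#' @export
setMethod("show", "StructureSet", function(object) {
  tab <- table(factor(object@roles,
    levels = c("body", "target", "organ", "auxiliary")))
  cat(sprintf("StructureSet with %d structures (%s) on %s grid\n",
    length(object@masks),
    paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
    paste(object@grid@shape, collapse = "x")))
})

#' Structure names of a StructureSet
#' @param ss a [StructureSet-class].
#' @return Character vector of mask names.
#' @export
structureNames <- function(ss) names(ss@masks)

#' Extract a structure mask
#' @param ss a [StructureSet-class].
#' @param name structure name.
#' @return The logical mask array.
#' @export
structureMask <- function(ss, name) {
  if (!name %in% names(ss@masks))
    stop(sprintf("structure '%s' not present in the structure set", name))
  ss@masks[[name]]
}

#' Name of the body mask
#' @param ss a [StructureSet-class].
#' @return The name of the mask with role `"body"`.
#' @export
bodyName <- function(ss) names(ss@roles)[ss@roles == "body"][1L]

#' ObjectiveSet: the inverse-planning objective template
#'
#' An ordered list of dose-volume and mean-dose objectives, each with a dose
#' limit tau (cGy), a volume threshold V (%) for dose-volume constraints, and
#' a priority weight lambda. Fixed objectives carry numeric priorities;
#' adjustable objectives reference one of the eight priority placeholders
#' P1..P8 that the virtual planner steers (auxiliary structures share the
#' placeholder of their primary organ).
#'
#' @slot objectives data.frame with columns `structure`, `dose_cGy`,
#'   `volume_pct` (NA for mean objectives), `priority` (current numeric
#'   value), `placeholder` (NA for fixed objectives), `type`
#'   (`"lower"`, `"upper"`, `"mean"`).
#' @slot adjustableMap named list mapping placeholders P1..P8 to the row
#'   indices they control.
#' @slot priorityBounds numeric(2), allowed priority range.
#' @slot initialPriorities named numeric(8), template-shipped starting values
#'   for P1..P8.
#' @export
setClass("ObjectiveSet",
  representation(objectives = "data.frame", adjustableMap = "list",
                 priorityBounds = "numeric", initialPriorities = "numeric"),
  validity = function(object) {
    df <- object@objectives
    need <- c("structure", "dose_cGy", "volume_pct", "priority",
              "placeholder", "type")
    if (!all(need %in% names(df))) return("missing objective columns")
    if (!all(df$type %in% c("lower", "upper", "mean")))
      return("objective type must be lower, upper or mean")
    if (any(df$dose_cGy < 0)) return("dose limits must be >= 0")
    dv <- df$type %in% c("lower", "upper")
    if (any(is.na(df$volume_pct[dv])))
      return("dose-volume objectives require a volume_pct")
    ph <- df$placeholder[!is.na(df$placeholder)]
    if (!all(ph %in% paste0("P", 1:8)))
      return("placeholders must be drawn from P1..P8")
    for (p in names(object@adjustableMap)) {
      idx <- object@adjustableMap[[p]]
      if (length(idx) < 1L) return(sprintf("placeholder %s maps to no objective", p))
      if (!all(df$placeholder[idx] == p))
        return(sprintf("adjustableMap for %s is inconsistent", p))
    }
    if (any(is.na(df$priority)))
      return("all objectives must carry a current numeric priority")
    if (length(object@priorityBounds) != 2L ||
        object@priorityBounds[1] >= object@priorityBounds[2])
      return("priorityBounds must be an increasing pair")
    TRUE
  })

#' @rdname ObjectiveSet-class
#' @param object an ObjectiveSet
#' @export
setMethod("show", "ObjectiveSet", function(object) {
  df <- object@objectives
  cat(sprintf(paste0("ObjectiveSet: %d objectives on %d structures ",
                     "(%d lower / %d upper / %d mean), %d fixed + %d ",
                     "adjustable via %d priorities\n"),
    nrow(df), length(unique(df$structure)), sum(df$type == "lower"),
    sum(df$type == "upper"), sum(df$type == "mean"),
    sum(is.na(df$placeholder)), sum(!is.na(df$placeholder)),
    length(object@adjustableMap)))
})

#' Objectives table accessor
#' @param os an [ObjectiveSet-class].
#' @return The objectives data.frame.
#' @export
objectivesTable <- function(os) os@objectives

#' Adjustable-priority map accessor
#' @param os an [ObjectiveSet-class].
#' @return Named list mapping P1..P8 to objective row indices.
#' @export
adjustableMap <- function(os) os@adjustableMap

#' InfluenceMatrix: linear beamlet dose operator
#'
#' Sparse nonnegative matrix A mapping a beamlet fluence vector x to the dose
#' d = A x over the body voxels, built from equispaced coplanar beams with
#' exponential depth attenuation and Gaussian lateral penumbra.
#'
#' @slot A sparse dgCMatrix (body voxels x beamlets), entries >= 0.
#' @slot beamAnglesDeg gantry angles of the beams.
#' @slot beamlets data.frame with one row per beamlet (beam index, lateral
#'   offset in mm).
#' @slot bodyIndex integer indices of the body voxels in the flattened grid
#'   (column-major), defining the dose-vector ordering.
#' @slot params list of physical parameters (beamlet width, mu, sigma).
#' @export
setClass("InfluenceMatrix",
  representation(A = "Matrix", beamAnglesDeg = "numeric",
                 beamlets = "data.frame", bodyIndex = "integer",
                 params = "list"),
  validity = function(object) {
    if (any(object@A@x < 0)) return("influence entries must be nonnegative")
    if (ncol(object@A) != nrow(object@beamlets))
      return("column count must equal total beamlet count")
    if (nrow(object@A) != length(object@bodyIndex))
      return("row count must equal body voxel count")
    TRUE
  })

#' @rdname InfluenceMatrix-class
#' @param object an InfluenceMatrix
#' @export
setMethod("show", "InfluenceMatrix", function(object) {
  cat(sprintf("InfluenceMatrix: %d voxels x %d beamlets (%d beams, %.0f%% filled)\n",
    nrow(object@A), ncol(object@A), length(object@beamAnglesDeg),
    100 * length(object@A@x) / prod(dim(object@A))))
})

#' Number of beamlets
#' @param im an [InfluenceMatrix-class].
#' @return Integer beamlet count.
#' @export
nBeamlets <- function(im) ncol(im@A)

#' DenseNet: a small fully connected network
#'
#' Three hidden layers, each followed by a Leaky-ReLU activation with slope
#' 0.1, and a linear output layer. Used for both sub-networks of the virtual
#' planner: the Parameter-Net (input 21 scores, output 8 TPP values) and the
#' Action-Net (input 42 = structure-coded vector plus scores, output 2
#' adjustment directions).
#'
#' @slot layers list of `list(W, b)` per layer; `W` is (out x in).
#' @slot slope Leaky-ReLU negative slope.
#' @export
setClass("DenseNet", representation(layers = "list", slope = "numeric"),
  validity = function(object) {
    if (length(object@layers) < 1L) return("network needs at least one layer")
    for (i in seq_along(object@layers)) {
      ly <- object@layers[[i]]
      if (!is.matrix(ly$W) || length(ly$b) != nrow(ly$W))
        return("layer weights malformed")
      if (i > 1L &&
          ncol(ly$W) != nrow(object@layers[[i - 1L]]$W))
        return("layer widths do not chain")
    }
    if (object@slope < 0) return("slope must be >= 0")
    TRUE
  })

#' @rdname DenseNet-class
#' @param object a DenseNet
#' @export
setMethod("show", "DenseNet", function(object) {
  widths <- c(ncol(object@layers[[1]]$W),
              vapply(object@layers, function(l) nrow(l$W), integer(1)))
  cat(sprintf("DenseNet %s, Leaky-ReLU slope %.2g\n",
    paste(widths, collapse = "-"), object@slope))
})
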