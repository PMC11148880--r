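# Plain-text serialization: structure sets (JSON with run-length-encoded
# masks), network checkpoints (JSON with architecture metadata), plan
# records and DVH curves (CSV/JSON).

maskToRle <- function(mask) {
  r <- rle(as.vector(mask))
  # canonical form: first run counts FALSE voxels (possibly 0)
  if (r$values[1]) list(lengths = c(0L, r$lengths))
  else list(lengths = r$lengths)
}

rleToMask <- function(lengths, shape) {
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(lengths)), lengths)
  array(vals, dim = shape)
}

#' Write a StructureSet to a JSON container
#'
#' Deterministic plain-text serialization: grid metadata plus one
#' run-length-encoded dataset per mask. Identical structure sets produce
#' byte-identical files.
#'
#' @param ss a [StructureSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructureSet <- function(ss, path) {
  obj <- list(
    grid = list(shape = ss@grid@shape, spacing_mm = ss@grid@spacingMm),
    roles = as.list(ss@roles),
    masks = lapply(ss@masks, function(m) maskToRle(m)$lengths))
  json <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a StructureSet written by [writeStructureSet()]
#' @param path input file path.
#' @return A [StructureSet-class].
#' @export
readStructureSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- voxelGrid(obj$grid$shape, obj$grid$spacing_mm)
  masks <- lapply(obj$masks, function(l) rleToMask(as.integer(l), grid@shape))
  structureSet(grid, masks, unlist(obj$roles))
}

#' Save an agent checkpoint
#'
#' Writes both networks (full-precision weights plus architecture
#' metadata) to a JSON file.
#'
#' @param pNet,aNet the Parameter-Net and Action-Net.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveAgent <- function(pNet, aNet, path) {
  ser <- function(net) list(
    slope = net@slope,
    layers = lapply(net@layers, function(l)
      list(W = l$W, b = l$b)))
  json <- jsonlite::toJSON(list(parameterNet = ser(pNet),
                                actionNet = ser(aNet)),
                           digits = NA, auto_unbox = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Load an agent checkpoint written by [saveAgent()]
#' @param path input file path.
#' @return List with `pNet` and `aNet`.
#' @export
loadAgent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite may simplify the layer list into a data.frame of parallel lists
  deserialize <- function(x) {
    ls <- x$layers
    if (is.data.frame(ls)) {
      layers <- lapply(seq_len(nrow(ls)), function(i)
        list(W = as.matrix(ls$W[[i]]), b = as.numeric(ls$b[[i]])))
    } else {
      layers <- lapply(ls, function(l)
        list(W = as.matrix(l$W), b = as.numeric(l$b)))
    }
    new("DenseNet", layers = layers, slope = as.numeric(x$slope))
  }
  list(pNet = deserialize(obj$parameterNet),
       aNet = deserialize(obj$actionNet))
}

#' Export a plan record as CSV and JSON
#'
#' Writes the per-step decision trace (step, chosen parameter, direction,
#' step size, reward, total score) as `<file>.csv` and, together with the
#' per-step score vectors, as `<file>.json`.
#'
#' @param record a `"PlanRecord"` from [runAutoplanning()].
#' @param file path prefix.
#' @return The prefix, invisibly.
#' @export
exportPlanRecord <- function(record, file) {
  utils::write.csv(record$trace, paste0(file, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(trace = record$trace,
         scores = lapply(record$scores, as.list)),
    paste0(file, ".json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  invisible(file)
}

#' Export DVH curves for a set of structures as CSV
#'
#' @param d dose vector.
#' @param ss a [StructureSet-class].
#' @param im the [InfluenceMatrix-class] (dose ordering).
#' @param structures structure names (default: all nonempty).
#' @param path output CSV path.
#' @param binWidthCGy DVH bin width.
#' @return `path`, invisibly.
#' @export
exportDVH <- function(d, ss, im, structures = NULL, path,
                      binWidthCGy = 10) {
  if (is.null(structures)) {
    structures <- structureNames(ss)
    structures <- structures[vapply(structures, function(n)
      any(structureMask(ss, n)), logical(1))]
  }
  rows <- lapply(structures, function(n) {
    dvh <- computeDVH(d, structureDoseIndex(ss, im, n), binWidthCGy)
    data.frame(structure = n, dose_cGy = dvh$doseCGy,
               volume_pct = dvh$volumePct)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export the per-metric score report as CSV
#'
#' One row per metric: value, awarded score, maximum points.
#'
#' @param score a `"PlanScore"` from [scorePlan()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportMetricReport <- function(score, path) {
  utils::write.csv(score$table, path, row.names = FALSE)
  invisible(path)
}
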