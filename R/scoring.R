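# DVH computation, dosimetric metrics, and the 21-component piecewise-linear
# plan-quality score (the RL state) with total score psi in [0, 150].

#' Load a plan-scoring configuration
#'
#' Reads and validates a YAML scoring configuration: a list of metrics
#' (name, structure, metric kind, threshold, piecewise-linear breakpoints,
#' maximum points) plus the placeholder-to-metric map used by the agent's
#' structure-coded vector. The packaged default defines 21 metrics whose
#' maxima sum to 150.
#'
#' @param path path to the YAML config; defaults to the packaged config.
#' @return A list of class `"ScoringConfig"` with elements `metrics` (list
#'   of metric specs), `maxPoints` (named numeric), and `tppMap`.
#' @export
loadScoringConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scoring_config.yaml",
                        package = "vtplanner", mustWork = TRUE)
  if (!file.exists(path)) stop("scoring config not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$metrics)) stop("scoring config: no metrics defined")
  kinds <- c("mean_dose", "dose_at_volume_cc", "dose_at_volume_pct",
             "volume_at_dose_pct")
  metrics <- lapply(raw$metrics, function(m) {
    for (f in c("name", "structure", "kind", "max_points", "breakpoints"))
      if (is.null(m[[f]])) stop("scoring config: metric missing '", f, "'")
    if (!m$kind %in% kinds)
      stop("scoring config: unknown metric kind '", m$kind, "'")
    if (m$kind != "mean_dose" && is.null(m$threshold))
      stop("scoring config: metric '", m$name, "' needs a threshold")
    bp <- do.call(rbind, lapply(m$breakpoints, function(b)
      c(value = as.numeric(b$value), points = as.numeric(b$points))))
    bp <- as.data.frame(bp)
    if (nrow(bp) < 2 || is.unsorted(bp$value, strictly = TRUE))
      stop("scoring config: breakpoints of '", m$name,
           "' must be strictly increasing in value")
    if (any(bp$points < 0) || any(bp$points > m$max_points))
      stop("scoring config: breakpoint points of '", m$name,
           "' outside [0, max_points]")
    if (is.unsorted(bp$points) && is.unsorted(rev(bp$points)))
      stop("scoring config: breakpoint points of '", m$name,
           "' must be monotone")
    list(name = m$name, structure = m$structure, kind = m$kind,
         threshold = if (is.null(m$threshold)) NA_real_
                     else as.numeric(m$threshold),
         breakpoints = bp, maxPoints = as.numeric(m$max_points))
  })
  names(metrics) <- vapply(metrics, `[[`, character(1), "name")
  if (anyDuplicated(names(metrics)))
    stop("scoring config: duplicate metric names")
  tppMap <- raw$tpp_map
  if (!is.null(tppMap)) {
    bad <- setdiff(unlist(tppMap), names(metrics))
    if (length(bad) > 0)
      stop("scoring config: tpp_map references unknown metric(s): ",
           paste(bad, collapse = ", "))
  }
  out <- list(metrics = metrics,
              maxPoints = vapply(metrics, `[[`, numeric(1), "maxPoints"),
              tppMap = tppMap)
  class(out) <- "ScoringConfig"
  out
}

#' Cumulative dose-volume histogram of a structure
#'
#' The fraction of the structure volume receiving at least each dose level,
#' evaluated on a regular dose grid. `V(0) = 100` for a nonempty structure
#' and the curve is non-increasing.
#'
#' @param d dose vector.
#' @param idx voxel indices of the structure within `d` (nonempty).
#' @param binWidthCGy dose bin width (> 0), default 10 cGy.
#' @return List with `doseCGy` (bin edges from 0) and `volumePct`.
#' @export
computeDVH <- function(d, idx, binWidthCGy = 10) {
  if (length(idx) == 0) stop("computeDVH: empty structure")
  if (binWidthCGy <= 0) stop("computeDVH: bin width must be > 0")
  dv <- d[idx]
  edges <- seq(0, max(dv) + binWidthCGy, by = binWidthCGy)
  vol <- vapply(edges, function(x) 100 * mean(dv >= x), numeric(1))
  list(doseCGy = edges, volumePct = vol)
}

#' Evaluate a dosimetric metric
#'
#' Metric kinds: `mean_dose` (arithmetic mean of structure dose);
#' `volume_at_dose_pct` (% of structure receiving at least the threshold
#' dose); `dose_at_volume_pct` (maximum dose received by at least the given
#' % of the structure); `dose_at_volume_cc` (maximum dose received by at
#' least the given absolute volume, e.g. `D[0.03cc]`). Dose-at-volume
#' resolves ties toward the lower dose, the conservative reading for
#' organ-at-risk limits. Metrics are computed from raw voxel doses, not
#' from a binned DVH.
#'
#' @param d dose vector.
#' @param idx structure voxel indices within `d` (nonempty).
#' @param spec a metric spec from [loadScoringConfig()] (fields `kind`,
#'   `threshold`).
#' @param voxelCc voxel volume in cc (needed for `dose_at_volume_cc`).
#' @return The metric value (cGy or %).
#' @export
evalMetric <- function(d, idx, spec, voxelCc = NULL) {
  if (length(idx) == 0)
    stop("evalMetric: empty structure for metric '", spec$name %||% "?", "'")
  dv <- d[idx]
  switch(spec$kind,
    mean_dose = mean(dv),
    volume_at_dose_pct = 100 * mean(dv >= spec$threshold),
    dose_at_volume_pct = {
      k <- min(length(dv), max(1L, ceiling(spec$threshold / 100 * length(dv))))
      sort(dv, decreasing = TRUE)[k]
    },
    dose_at_volume_cc = {
      if (is.null(voxelCc)) stop("evalMetric: voxelCc required for D[cc]")
      vol <- length(dv) * voxelCc
      if (spec$threshold > vol)
        stop(sprintf(
          "evalMetric: requested volume %.3f cc exceeds structure volume %.3f cc",
          spec$threshold, vol))
      k <- max(1L, ceiling(spec$threshold / voxelCc))
      sort(dv, decreasing = TRUE)[k]
    },
    stop("evalMetric: unknown kind '", spec$kind, "'"))
}

#' Score a metric value against its piecewise-linear breakpoints
#'
#' Linear interpolation of the (value, points) breakpoints, constant beyond
#' the first and last breakpoint, clamped to `[0, maxPoints]`.
#'
#' @param value the metric value.
#' @param spec a metric spec from [loadScoringConfig()].
#' @return Points awarded, in `[0, maxPoints]`.
#' @export
scoreMetric <- function(value, spec) {
  bp <- spec$breakpoints
  pts <- stats::approx(bp$value, bp$points, xout = value, rule = 2)$y
  min(max(pts, 0), spec$maxPoints)
}

#' Score a plan
#'
#' Evaluates every metric of the scoring configuration on the dose and sums
#' the per-metric scores into the total plan score psi (0..150 under the
#' default config). The per-metric score vector is the agent's state.
#'
#' @param d dose vector (over body voxels, ordered as the influence
#'   matrix).
#' @param ss a [StructureSet-class].
#' @param config a `"ScoringConfig"` from [loadScoringConfig()].
#' @param im the [InfluenceMatrix-class] defining dose ordering.
#' @return List of class `"PlanScore"`: `total` (psi), `vector` (named
#'   per-metric scores), `values` (named raw metric values), `table`
#'   (data.frame metric/value/score/max).
#' @export
scorePlan <- function(d, ss, config, im) {
  voxelCc <- voxelVolumeCc(ss@grid)
  missing <- setdiff(
    unique(vapply(config$metrics, `[[`, character(1), "structure")),
    structureNames(ss))
  if (length(missing) > 0) {
    bad <- vapply(config$metrics, function(m) m$structure %in% missing,
                  logical(1))
    stop("scorePlan: structure(s) absent from phantom: ",
         paste(missing, collapse = ", "), " (metrics ",
         paste(names(config$metrics)[bad], collapse = ", "), ")")
  }
  idxCache <- new.env(parent = emptyenv())
  getIdx <- function(n) {
    if (is.null(idxCache[[n]])) idxCache[[n]] <- structureDoseIndex(ss, im, n)
    idxCache[[n]]
  }
  values <- vapply(config$metrics, function(m)
    evalMetric(d, getIdx(m$structure), m, voxelCc), numeric(1))
  scores <- vapply(seq_along(config$metrics), function(i)
    scoreMetric(values[i], config$metrics[[i]]), numeric(1))
  names(scores) <- names(values) <- names(config$metrics)
  out <- list(total = sum(scores), vector = scores, values = values,
              table = data.frame(metric = names(scores),
                                 value = as.numeric(values),
                                 score = as.numeric(scores),
                                 max = as.numeric(config$maxPoints),
                                 row.names = NULL))
  class(out) <- "PlanScore"
  out
}

#' @export
print.PlanScore <- function(x, ...) {
  cat(sprintf("PlanScore: %.2f / %.0f\n", x$total, sum(x$table$max)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Reward for a plan-quality transition
#'
#' The change in total plan score produced by one planning-parameter
#' adjustment: `r = psi_new - psi_prev`. Positive when plan quality
#' improved; antisymmetric under exchange of its arguments.
#'
#' @param psiPrev total plan score before the adjustment.
#' @param psiNew total plan score after the adjustment.
#' @return The reward.
#' @export
reward <- function(psiPrev, psiNew) {
  stopifnot(is.finite(psiPrev), is.finite(psiNew))
  psiNew - psiPrev
}
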