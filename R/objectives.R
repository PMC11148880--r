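# The inverse-planning objective template and the priority-weighted
# one-sided quadratic penalty functional the optimizer minimizes.

#' Load an inverse-planning objective template
#'
#' Reads a YAML objective template (the packaged default transcribes the
#' head-and-neck template: 47 objectives on 26 structures, 36 fixed plus 11
#' adjustable sharing 8 priority placeholders) and validates it. Placeholder
#' rows receive the template's `initial_priorities` as their starting
#' numeric priority. Structure names are not checked here; they are resolved
#' when the template is bound to a phantom with [bindObjectives()].
#'
#' @param path path to the YAML template; defaults to the packaged
#'   head-and-neck template.
#' @return An [ObjectiveSet-class].
#' @examples
#' os <- loadObjectiveTemplate()
#' os
#' @export
loadObjectiveTemplate <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "objective_template.yaml",
                        package = "vtplanner", mustWork = TRUE)
  if (!file.exists(path)) stop("objective template not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$objectives) || length(raw$objectives) == 0)
    stop("objective template: no objectives defined")
  bounds <- as.numeric(raw$priority_bounds %||% c(1, 100))
  init <- unlist(raw$initial_priorities)
  rows <- lapply(raw$objectives, function(o) {
    for (f in c("structure", "dose_cGy", "priority", "type"))
      if (is.null(o[[f]]))
        stop("objective template: entry missing field '", f, "'")
    if (!o$type %in% c("lower", "upper", "mean"))
      stop("objective template: unknown type '", o$type, "'")
    ph <- NA_character_
    pr <- NA_real_
    if (is.character(o$priority)) {
      if (!grepl("^P[1-8]$", o$priority))
        stop("objective template: priority placeholder '", o$priority,
             "' is not one of P1..P8")
      ph <- o$priority
      if (!ph %in% names(init))
        stop("objective template: no initial priority for ", ph)
      pr <- as.numeric(init[[ph]])
    } else pr <- as.numeric(o$priority)
    vol <- if (is.null(o$volume_pct)) NA_real_ else as.numeric(o$volume_pct)
    if (o$type %in% c("lower", "upper") && is.na(vol))
      stop("objective template: dose-volume objective on '", o$structure,
           "' lacks volume_pct")
    if (!is.na(vol) && (vol < 0 || vol > 100))
      stop("objective template: volume_pct out of [0,100]")
    data.frame(structure = o$structure, dose_cGy = as.numeric(o$dose_cGy),
               volume_pct = vol, priority = pr, placeholder = ph,
               type = o$type, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ph <- sort(unique(df$placeholder[!is.na(df$placeholder)]))
  amap <- lapply(ph, function(p) which(!is.na(df$placeholder) &
                                       df$placeholder == p))
  names(amap) <- ph
  initOrdered <- setNames(as.numeric(init[ph]), ph)
  new("ObjectiveSet", objectives = df, adjustableMap = amap,
      priorityBounds = bounds, initialPriorities = initOrdered)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary counts of an objective template
#'
#' @param os an [ObjectiveSet-class].
#' @return A list with the template's headline counts: `structures`,
#'   `objectives`, `lower`, `upper`, `mean`, `fixed`, `adjustable`,
#'   `placeholders`, `sharedAuxiliary` (adjustable objectives on `_opti`
#'   structures sharing a placeholder with their primary organ) and
#'   `parameterSlots` (dose, volume, priority slot per objective).
#' @export
objectiveCounts <- function(os) {
  df <- os@objectives
  adj <- !is.na(df$placeholder)
  shared <- 0L
  for (p in names(os@adjustableMap)) {
    st <- df$structure[os@adjustableMap[[p]]]
    opti <- grepl("_opti$", st)
    if (any(opti) && any(!opti)) shared <- shared + sum(opti)
  }
  list(structures = length(unique(df$structure)),
       objectives = nrow(df),
       lower = sum(df$type == "lower"),
       upper = sum(df$type == "upper"),
       mean = sum(df$type == "mean"),
       fixed = sum(!adj),
       adjustable = sum(adj),
       placeholders = length(os@adjustableMap),
       sharedAuxiliary = shared,
       parameterSlots = 3L * nrow(df))
}

#' Apply a priority vector to the adjustable objectives
#'
#' Writes the eight priority values into every objective governed by each
#' placeholder (shared placeholders update their multiple objectives
#' atomically); fixed objectives are untouched.
#'
#' @param os an [ObjectiveSet-class].
#' @param pv numeric vector of length 8 (optionally named P1..P8) within the
#'   template's priority bounds.
#' @return The updated [ObjectiveSet-class].
#' @export
applyPriorities <- function(os, pv) {
  ph <- names(os@adjustableMap)
  if (is.null(names(pv))) {
    if (length(pv) != length(ph))
      stop("applyPriorities: expected ", length(ph), " priorities")
    names(pv) <- ph
  }
  if (!all(ph %in% names(pv)))
    stop("applyPriorities: missing placeholder(s): ",
         paste(setdiff(ph, names(pv)), collapse = ", "))
  b <- os@priorityBounds
  if (any(pv < b[1] | pv > b[2]))
    stop(sprintf("applyPriorities: priorities must lie in [%g, %g]",
                 b[1], b[2]))
  df <- os@objectives
  for (p in ph) df$priority[os@adjustableMap[[p]]] <- pv[[p]]
  initialize(os, objectives = df)
}

#' Current values of the adjustable priorities
#' @param os an [ObjectiveSet-class].
#' @return Named numeric vector (P1..P8) of current priorities.
#' @export
currentPriorities <- function(os) {
  vapply(os@adjustableMap,
         function(idx) os@objectives$priority[idx[1]], numeric(1))
}

#' Bind an objective template to a phantom
#'
#' Resolves every objective's structure to its voxel indices within the
#' dose vector. A structure named by the template but absent from the
#' phantom is a named error. Structures that exist but contain no voxels
#' (possible for thin auxiliary slivers on coarse grids) bind as inert
#' objectives contributing zero penalty.
#'
#' @param os an [ObjectiveSet-class].
#' @param ss a [StructureSet-class].
#' @param im the [InfluenceMatrix-class] defining dose-vector ordering.
#' @return A `"BoundObjectives"` list used by [objectiveValue()] and
#'   [optimizeFluence()].
#' @export
bindObjectives <- function(os, ss, im) {
  st <- unique(os@objectives$structure)
  missing <- setdiff(st, structureNames(ss))
  if (length(missing) > 0)
    stop("bindObjectives: template structure(s) not in phantom: ",
         paste(missing, collapse = ", "))
  idxByStructure <- lapply(st, function(n) structureDoseIndex(ss, im, n))
  names(idxByStructure) <- st
  idx <- idxByStructure[os@objectives$structure]
  out <- list(idx = idx,
              n = vapply(idx, length, integer(1)),
              structures = st,
              nVoxels = nrow(im@A))
  class(out) <- "BoundObjectives"
  out
}

# Per-objective penalty and active voxel sets for a dose vector.
# Dose-volume constraints use the standard surrogate: for an upper DVC
# (tau, V) only voxels with dose in (tau, D_V] are penalized, where D_V is
# the current dose at volume V; symmetrically [D_V, tau) for lower DVCs.
# Penalties are per-voxel normalized so priorities are comparable across
# structure sizes. Mean objectives penalize (max(0, mean - tau))^2.
objectivePenalties <- function(d, os, bound, gradient = FALSE) {
  df <- os@objectives
  m <- nrow(df)
  tauAll <- df$dose_cGy; lamAll <- df$priority; typeAll <- df$type
  volAll <- df$volume_pct
  pen <- numeric(m)
  w <- if (gradient) numeric(bound$nVoxels) else NULL
  for (i in seq_len(m)) {
    n <- bound$n[i]
    if (n == 0L) next
    idx <- bound$idx[[i]]
    dv <- d[idx]
    tau <- tauAll[i]
    if (typeAll[i] == "mean") {
      mu <- sum(dv) / n
      if (mu > tau) {
        pen[i] <- (mu - tau)^2
        if (gradient) w[idx] <- w[idx] + lamAll[i] * 2 * (mu - tau) / n
      }
    } else {
      k <- min(n, max(1L, ceiling(volAll[i] / 100 * n)))
      dV <- if (k == 1L) max(dv) else if (k == n) min(dv)
            else sort(dv, decreasing = TRUE)[k]
      act <- if (typeAll[i] == "upper") dv > tau & dv <= dV
             else dv < tau & dv >= dV
      if (any(act)) {
        r <- dv[act] - tau
        pen[i] <- sum(r * r) / n
        if (gradient) w[idx[act]] <- w[idx[act]] + lamAll[i] * 2 * r / n
      }
    }
  }
  list(per = pen, total = sum(lamAll * pen), w = w)
}

#' Evaluate the planning objective functional
#'
#' Total penalty `sum_i lambda_i * penalty_i(d)` over all objectives, with
#' one-sided quadratic penalties: dose-volume constraints penalize only the
#' voxels between the dose limit and the current dose-at-volume (the
#' canonical DVC surrogate), mean objectives penalize the squared excess of
#' the structure mean over the limit. Each penalty is nonnegative and zero
#' exactly when the objective is met.
#'
#' @param d dose vector.
#' @param os an [ObjectiveSet-class] (carries the current priorities).
#' @param bound the [bindObjectives()] result.
#' @return List with `total` and `perObjective` (unweighted penalties).
#' @export
objectiveValue <- function(d, os, bound) {
  p <- objectivePenalties(d, os, bound, gradient = FALSE)
  list(total = p$total, perObjective = p$per)
}

#' Optimize the fluence map for an objective set
#'
#' Deterministic projected-gradient descent on the nonnegative orthant with
#' an adaptive monotone line search: each accepted step strictly decreases
#' the objective, so the per-iteration trace is non-increasing. The gradient
#' is `A' w` with `w` the per-voxel penalty derivatives at the current
#' active sets.
#'
#' @param im an [InfluenceMatrix-class].
#' @param os an [ObjectiveSet-class].
#' @param bound the [bindObjectives()] result.
#' @param x0 starting fluence (default zero); must be nonnegative.
#' @param maxIters iteration cap.
#' @param tol relative-decrease convergence tolerance.
#' @return List with `x`, `dose`, `value`, `trace` (objective per accepted
#'   iteration, starting at the initial value) and `iterations`.
#' @export
optimizeFluence <- function(im, os, bound, x0 = NULL, maxIters = 200L,
                            tol = 1e-9) {
  A <- im@A
  nb <- ncol(A)
  if (is.null(x0)) x0 <- numeric(nb)
  if (length(x0) != nb) stop("optimizeFluence: x0 has wrong length")
  if (any(x0 < 0)) stop("optimizeFluence: x0 must be nonnegative")
  x <- as.numeric(x0)
  d <- as.numeric(A %*% x)
  if (nrow(os@objectives) == 0L)
    return(list(x = x, dose = d, value = 0, trace = numeric(0),
                iterations = 0L))
  fEval <- function(dd) objectivePenalties(dd, os, bound)$total
  f <- fEval(d)
  if (!is.finite(f)) stop("optimizeFluence: non-finite objective at start")
  trace <- f
  t <- NA_real_
  At <- Matrix::t(A)
  xPrev <- NULL; gPrev <- NULL
  for (it in seq_len(maxIters)) {
    pe <- objectivePenalties(d, os, bound, gradient = TRUE)
    g <- as.numeric(At %*% pe$w)
    gnorm <- sqrt(sum(g * g))
    if (gnorm < 1e-14) break
    fTry <- function(tt) {
      xn <- pmax(0, x - tt * g)
      dn <- as.numeric(A %*% xn)
      list(x = xn, d = dn, f = fEval(dn))
    }
    if (!is.null(xPrev)) {
      # Barzilai-Borwein spectral step, safeguarded by the backtracking below
      dx <- x - xPrev; dg <- g - gPrev
      denom <- sum(dx * dg)
      if (is.finite(denom) && denom > 1e-30) t <- sum(dx * dx) / denom
    }
    accepted <- FALSE
    if (is.na(t)) {
      # first iteration: expand a conservative step while it keeps improving
      t <- 1 / gnorm
      cand <- fTry(t)
      while (cand$f >= f && t > 1e-20 / gnorm) { t <- t / 2; cand <- fTry(t) }
      if (cand$f < f) {
        repeat {
          bigger <- fTry(2 * t)
          if (bigger$f < cand$f) { t <- 2 * t; cand <- bigger } else break
        }
        accepted <- TRUE
      }
    } else {
      cand <- fTry(t)
      if (cand$f < f) accepted <- TRUE
      else for (h in seq_len(40)) {
        t <- t / 2
        cand <- fTry(t)
        if (cand$f < f) { accepted <- TRUE; break }
      }
    }
    if (!accepted) break
    relDrop <- (f - cand$f) / max(f, 1e-12)
    xPrev <- x; gPrev <- g
    x <- cand$x; d <- cand$d; f <- cand$f
    trace <- c(trace, f)
    if (!is.finite(f)) stop("optimizeFluence: non-finite objective value")
    if (relDrop < tol) break
  }
  list(x = x, dose = d, value = f, trace = trace,
       iterations = length(trace) - 1L)
}
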