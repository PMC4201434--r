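#' Local maxima of an outcome surface
#'
#' A grid cell is a peak iff its outcome probability is greater than or equal
#' to all of its 8-connected neighbours (edge cells compare their existing
#' neighbours). Connected plateaus of equal probability merge into a single
#' peak reported at the lexicographically smallest cell, so a constant surface
#' has exactly one plateau peak. Peaks whose probability does not exceed
#' `floor + min_prominence` are discarded; the floor is the outcome link's
#' zero-activity baseline ([surface_floor()]), not the observed minimum.
#'
#' @param surface An evaluated [evaluate_surface()] object.
#' @param min_prominence Required height above the surface floor for a cell to
#'   qualify as a peak. The default 0.05 suppresses floor-level ripple without
#'   masking secondary peaks, which sit far above it at the published
#'   parameters.
#' @return An object of class `"peak_set"`: a list with `peaks` (data frame
#'   with columns `e1`, `e2`, `P`, sorted by descending `P`, ties broken by
#'   ascending `(e1, e2)`), `floor`, and `min_prominence`.
#' @export
find_local_maxima <- function(surface, min_prominence = 0.05) {
  stopifnot(inherits(surface, "outcome_surface"))
  P <- surface$P
  n1 <- nrow(P)
  n2 <- ncol(P)
  fl <- surface_floor(surface)

  # max over the 8-neighbourhood, excluding the cell itself, via padded shifts
  pad <- matrix(-Inf, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- P
  nbr_max <- matrix(-Inf, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nbr_max <- pmax(nbr_max, pad[(2:(n1 + 1L)) + di, (2:(n2 + 1L)) + dj])
  }
  cand <- which(P >= nbr_max, arr.ind = TRUE)

  # merge 8-connected candidates of equal P (plateaus) into one peak at the
  # lexicographically smallest cell
  peaks <- list()
  if (nrow(cand) > 0L) {
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    key <- cand[, 1L] + n1 * (cand[, 2L] - 1L)
    seen <- logical(length(key))
    idx_of <- function(i, j) match(i + n1 * (j - 1L), key)
    for (start in seq_along(key)) {
      if (seen[start]) next
      queue <- start
      seen[start] <- TRUE
      members <- start
      val <- P[cand[start, 1L], cand[start, 2L]]
      while (length(queue) > 0L) {
        cur <- queue[[1L]]
        queue <- queue[-1L]
        ci <- cand[cur, 1L]; cj <- cand[cur, 2L]
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          ni <- ci + di; nj <- cj + dj
          if (ni < 1L || ni > n1 || nj < 1L || nj > n2) next
          k <- idx_of(ni, nj)
          if (!is.na(k) && !seen[k] && P[ni, nj] == val) {
            seen[k] <- TRUE
            queue <- c(queue, k)
            members <- c(members, k)
          }
        }
      }
      m <- cand[members, , drop = FALSE]
      m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
      peaks[[length(peaks) + 1L]] <- c(m[1L, 1L], m[1L, 2L], val)
    }
  }
  df <- if (length(peaks) > 0L) {
    out <- do.call(rbind, peaks)
    data.frame(e1 = surface$grid$e1_values[out[, 1L]],
               e2 = surface$grid$e2_values[out[, 2L]],
               P = out[, 3L])
  } else {
    data.frame(e1 = numeric(0), e2 = numeric(0), P = numeric(0))
  }
  df <- df[df$P > fl + min_prominence, , drop = FALSE]
  df <- df[order(-df$P, df$e1, df$e2), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(peaks = df, floor = fl, min_prominence = min_prominence),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peak(s), floor %.4f, min_prominence %g\n",
              nrow(x$peaks), x$floor, x$min_prominence))
  if (nrow(x$peaks) > 0L) print(x$peaks)
  invisible(x)
}

global_argmax_cell <- function(P) {
  # lexicographically smallest cell among ties
  idx <- which(P == max(P), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  idx[1L, ]
}

#' Breadth, precision and mass metrics of a surface
#'
#' All thresholds are measured above the surface floor (the outcome link's
#' zero-activity baseline): the half-maximum level is
#' `floor + (max(P) - floor) / 2`. `half_max_area` counts grid cells at or
#' above that level; `axis_halfwidths` counts such cells along the grid row
#' and column through the global maximum (a per-axis precision measure);
#' `total_mass` is the plain sum of P over cells, reported alongside the cell
#' count (the published comparison it supports is ordinal, so no continuous
#' integration is attempted). A perfectly flat surface cannot be given a
#' half-maximum region, so it is flagged `degenerate` and assigned the full
#' grid.
#'
#' @param surface An evaluated [evaluate_surface()] object.
#' @param value_at Optional list of `c(e1, e2)` query cells (or a single such
#'   vector); P at each is reported, named `"P(e1,e2)"`.
#' @param min_prominence Passed to [find_local_maxima()] for the peak count.
#' @return An object of class `"surface_metrics"`: `n_peaks`, `half_max_area`,
#'   `axis_halfwidths` (named `e1`, `e2`), `total_mass`, `n_cells`, `max_P`,
#'   `floor`, `degenerate`, `value_at`, and the `peaks` data frame.
#' @export
breadth_metrics <- function(surface, value_at = NULL, min_prominence = 0.05) {
  stopifnot(inherits(surface, "outcome_surface"))
  P <- surface$P
  fl <- surface_floor(surface)
  degenerate <- max(P) == min(P)
  level <- fl + (max(P) - fl) / 2
  if (degenerate) {
    warning("flat surface: half-maximum region is undefined; reporting the full grid")
    half_area <- length(P)
    hw <- c(e1 = nrow(P), e2 = ncol(P))
  } else {
    half_area <- sum(P >= level)
    am <- global_argmax_cell(P)
    hw <- c(e1 = sum(P[, am[2L]] >= level), e2 = sum(P[am[1L], ] >= level))
  }
  ps <- find_local_maxima(surface, min_prominence)
  va <- NULL
  if (!is.null(value_at)) {
    if (is.numeric(value_at)) value_at <- list(value_at)
    va <- vapply(value_at, function(cell) {
      i <- match(cell[1L], surface$grid$e1_values)
      j <- match(cell[2L], surface$grid$e2_values)
      if (is.na(i) || is.na(j)) {
        stop_value(sprintf("query cell (%g, %g) is not on the grid", cell[1L], cell[2L]))
      }
      P[i, j]
    }, numeric(1))
    names(va) <- vapply(value_at, function(cell)
      sprintf("P(%g,%g)", cell[1L], cell[2L]), character(1))
  }
  structure(
    list(n_peaks = nrow(ps$peaks), half_max_area = half_area,
         axis_halfwidths = hw, total_mass = sum(P), n_cells = length(P),
         max_P = max(P), floor = fl, degenerate = degenerate,
         value_at = va, peaks = ps$peaks),
    class = "surface_metrics"
  )
}

#' @export
print.surface_metrics <- function(x, ...) {
  cat(sprintf(paste0("surface_metrics: %d peak(s), half-max area %d / %d cells ",
                     "(halfwidths e1 %d, e2 %d), total mass %.3f, max P %.4f%s\n"),
              x$n_peaks, x$half_max_area, x$n_cells,
              x$axis_halfwidths[["e1"]], x$axis_halfwidths[["e2"]],
              x$total_mass, x$max_P,
              if (x$degenerate) " [degenerate flat surface]" else ""))
  invisible(x)
}

#' Ordered metric differences between two surfaces
#'
#' Computes `a` minus `b` differences of total mass and maximum probability,
#' P differences at shared query cells, and matches each surface's peaks to
#' the nearest peak of the other (Euclidean distance in environment units).
#'
#' @param a,b Evaluated [evaluate_surface()] objects on identical grids.
#' @param query_cells Optional list of `c(e1, e2)` cells.
#' @param min_prominence Passed to [find_local_maxima()].
#' @return A list with `delta_total_mass`, `delta_max`, `delta_value_at`
#'   (named vector or NULL), and `peak_matching` (data frame: each peak of
#'   `a`/`b` with the distance to its nearest counterpart, NA when the other
#'   surface has no peaks).
#' @export
compare_surfaces <- function(a, b, query_cells = NULL, min_prominence = 0.05) {
  stopifnot(inherits(a, "outcome_surface"), inherits(b, "outcome_surface"))
  if (!identical(a$grid, b$grid)) stop_value("surfaces must share an identical grid")
  ma <- breadth_metrics(a, value_at = query_cells, min_prominence = min_prominence)
  mb <- breadth_metrics(b, value_at = query_cells, min_prominence = min_prominence)
  nearest <- function(from, to) {
    if (nrow(from) == 0L) return(NULL)
    d <- vapply(seq_len(nrow(from)), function(k) {
      if (nrow(to) == 0L) return(NA_real_)
      min(sqrt((to$e1 - from$e1[k])^2 + (to$e2 - from$e2[k])^2))
    }, numeric(1))
    data.frame(e1 = from$e1, e2 = from$e2, P = from$P, dist_to_other = d)
  }
  pm_a <- nearest(ma$peaks, mb$peaks)
  pm_b <- nearest(mb$peaks, ma$peaks)
  pm <- rbind(
    if (!is.null(pm_a)) cbind(surface = "a", pm_a),
    if (!is.null(pm_b)) cbind(surface = "b", pm_b)
  )
  list(delta_total_mass = ma$total_mass - mb$total_mass,
       delta_max = ma$max_P - mb$max_P,
       delta_value_at = if (is.null(ma$value_at)) NULL else ma$value_at - mb$value_at,
       peak_matching = pm,
       metrics_a = ma, metrics_b = mb)
}

#' Distances from peaks to every copy's environmental optimum pair
#'
#' For each peak and each gene copy of each tier, the Euclidean distance (in
#' environment units) between the peak cell and the copy's
#' `(e1 optimum, e2 optimum)` pair. Quantifies how closely peak physiological
#' activity matches peak sensitivity of individual genes.
#'
#' @param peaks A [find_local_maxima()] result.
#' @param cfg The [pathway_config()] the surface came from.
#' @return A data frame with columns `peak`, `peak_e1`, `peak_e2`, `tier`
#'   (`"upstream"`/`"downstream"`), `copy`, `label`, `opt_e1`, `opt_e2`,
#'   `distance`; empty when the peak set is empty.
#' @export
peak_optimum_match <- function(peaks, cfg) {
  stopifnot(inherits(peaks, "peak_set"), inherits(cfg, "pathway_config"))
  pk <- peaks$peaks
  rows <- list()
  for (k in seq_len(nrow(pk))) {
    for (tier in c("upstream", "downstream")) {
      copies <- cfg[[tier]]
      for (i in seq_along(copies)) {
        cp <- copies[[i]]
        o1 <- cp$response_e1$optimum
        o2 <- cp$response_e2$optimum
        rows[[length(rows) + 1L]] <- data.frame(
          peak = k, peak_e1 = pk$e1[k], peak_e2 = pk$e2[k],
          tier = tier, copy = i, label = cp$label, opt_e1 = o1, opt_e2 = o2,
          distance = sqrt((pk$e1[k] - o1)^2 + (pk$e2[k] - o2)^2))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peak = integer(0), peak_e1 = numeric(0), peak_e2 = numeric(0),
                      tier = character(0), copy = integer(0), label = character(0),
                      opt_e1 = numeric(0), opt_e2 = numeric(0), distance = numeric(0)))
  }
  do.call(rbind, rows)
}

# navigate a dotted parameter path like "link_down_outcome.slope" or
# "upstream[2].response_e1.optimum"; returns list(indices) into the config
parse_parameter_path <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop_value("empty parameter path")
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\[([0-9]+)\\])?$", p))[[1]]
    if (length(m) == 0L) stop_value(sprintf("malformed parameter path component '%s'", p))
    out[[length(out) + 1L]] <- m[2]
    if (nzchar(m[4])) out[[length(out) + 1L]] <- as.integer(m[4])
  }
  out
}

set_config_scalar <- function(cfg, path, value) {
  idx <- parse_parameter_path(path)
  node <- cfg
  for (k in idx) {
    if (is.character(k) && (!is.list(node) || is.null(node[[k]]))) {
      stop_value(sprintf("unknown parameter path '%s' (no component '%s')", path, k))
    }
    if (is.numeric(k) && (!is.list(node) || k > length(node))) {
      stop_value(sprintf("unknown parameter path '%s' (index %d out of range)", path, k))
    }
    node <- node[[k]]
  }
  if (!is.numeric(node) || length(node) != 1L) {
    stop_value(sprintf("parameter path '%s' does not address a scalar field", path))
  }
  assign_path <- function(node, idx, value) {
    k <- idx[[1L]]
    if (length(idx) == 1L) node[[k]] <- value else {
      node[[k]] <- assign_path(node[[k]], idx[-1L], value)
    }
    node
  }
  assign_path(cfg, idx, as.numeric(value))
}

#' Sweep one scalar parameter and tabulate surface metrics
#'
#' Re-evaluates the surface for each value of a single scalar configuration
#' field, addressed by a dotted path such as `"link_down_outcome.slope"`,
#' `"link_up_down.intercept"` or `"upstream[2].response_e1.optimum"`. The base
#' configuration is not modified.
#'
#' @param base_cfg A [pathway_config()].
#' @param parameter_path Dotted path to one scalar field.
#' @param values Numeric vector of values to substitute.
#' @param grid An [env_grid()].
#' @param min_prominence Passed to [breadth_metrics()].
#' @return A data frame with one row per value: `value`, `n_peaks`,
#'   `half_max_area`, `halfwidth_e1`, `halfwidth_e2`, `total_mass`, `max_P`,
#'   `floor`.
#' @export
parameter_sweep <- function(base_cfg, parameter_path, values, grid = env_grid(),
                            min_prominence = 0.05) {
  stopifnot(inherits(base_cfg, "pathway_config"), is.numeric(values),
            length(values) >= 1L)
  rows <- lapply(values, function(v) {
    cfg <- set_config_scalar(base_cfg, parameter_path, v)
    m <- breadth_metrics(evaluate_surface(cfg, grid), min_prominence = min_prominence)
    data.frame(value = v, n_peaks = m$n_peaks, half_max_area = m$half_max_area,
               halfwidth_e1 = m$axis_halfwidths[["e1"]],
               halfwidth_e2 = m$axis_halfwidths[["e2"]],
               total_mass = m$total_mass, max_P = m$max_P, floor = m$floor)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
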