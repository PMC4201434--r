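#' Full pathway architecture
#'
#' Assembles gene copies and regulatory links into the two-tier cascade:
#' upstream copies respond only to the environment; each downstream copy's
#' activity is a sigmoidal function (`link_up_down`, the delta link) of its
#' regulatory input times its own environmental weight; the outcome probability
#' is a sigmoidal function (`link_down_outcome`, the gamma link) of total
#' downstream activity.
#'
#' Wiring determines each downstream copy's regulatory input:
#' * `"pooled"`: every downstream copy receives the combined activity of all
#'   upstream copies.
#' * `"independent"`: downstream copy i receives only upstream copy i's
#'   activity (copy counts must match), forming parallel pathways.
#' * a list of integer vectors (one per downstream copy): downstream copy j
#'   receives the combined activity of the mapped upstream copies.
#'
#' `pooling` controls how combined activities enter the delta link. The
#' default `"mean"` divides the summed activity by the number of contributing
#' copies, keeping the regulatory signal on the same \[0, 1\] scale as a single
#' gene's activity irrespective of copy number; `"sum"` passes the raw total
#' (gene dosage accumulates). See the package vignette for why normalized
#' pooling is the default.
#'
#' @param upstream,downstream Lists of [gene_copy()] objects (at least one
#'   each).
#' @param link_up_down [sigmoid_link()] from upstream activity to downstream
#'   expression (delta parameters).
#' @param link_down_outcome [sigmoid_link()] from total downstream activity to
#'   the outcome probability (gamma parameters).
#' @param wiring `"pooled"`, `"independent"`, or an explicit list of integer
#'   vectors mapping each downstream copy to upstream copies.
#' @param pooling `"mean"` (default) or `"sum"`; how multiple mapped upstream
#'   activities are combined into one regulatory input.
#' @return An object of class `"pathway_config"`.
#' @examples
#' cfg <- pathway_config(
#'   upstream = list(gene_copy(env_sensitivity(10, 0.01), env_sensitivity(12, 0.01))),
#'   downstream = list(gene_copy(env_sensitivity(10, 0), env_sensitivity(12, 0))),
#'   link_up_down = sigmoid_link(1, 2),
#'   link_down_outcome = sigmoid_link(1, 2)
#' )
#' outcome_probability(cfg, 10, 12)
#' @export
pathway_config <- function(upstream, downstream, link_up_down, link_down_outcome,
                           wiring = "pooled", pooling = c("mean", "sum")) {
  pooling <- match.arg(pooling)
  if (!is.list(upstream) || length(upstream) < 1L ||
      !all(vapply(upstream, inherits, logical(1), "gene_copy"))) {
    stop_value("'upstream' must be a non-empty list of gene_copy objects")
  }
  if (!is.list(downstream) || length(downstream) < 1L ||
      !all(vapply(downstream, inherits, logical(1), "gene_copy"))) {
    stop_value("'downstream' must be a non-empty list of gene_copy objects")
  }
  stopifnot(inherits(link_up_down, "sigmoid_link"),
            inherits(link_down_outcome, "sigmoid_link"))
  wiring <- validate_wiring(wiring, length(upstream), length(downstream))
  structure(
    list(upstream = upstream, downstream = downstream,
         link_up_down = link_up_down, link_down_outcome = link_down_outcome,
         wiring = wiring, pooling = pooling),
    class = "pathway_config"
  )
}

validate_wiring <- function(wiring, n_up, n_down) {
  if (is.character(wiring) && length(wiring) == 1L) {
    if (!wiring %in% c("pooled", "independent")) {
      stop_value(sprintf("unknown wiring mode '%s'", wiring))
    }
    if (wiring == "independent" && n_up != n_down) {
      stop_value(sprintf(
        "independent wiring requires equal copy counts (got %d upstream, %d downstream)",
        n_up, n_down))
    }
    return(wiring)
  }
  if (is.list(wiring)) {
    if (length(wiring) != n_down) {
      stop_value(sprintf("explicit wiring must have one entry per downstream copy (%d), got %d",
                         n_down, length(wiring)))
    }
    wiring <- lapply(wiring, function(idx) {
      idx <- as.integer(idx)
      if (length(idx) < 1L || anyNA(idx) || any(idx < 1L) || any(idx > n_up)) {
        stop_value(sprintf("explicit wiring indices must be in 1..%d", n_up))
      }
      sort(unique(idx))
    })
    return(wiring)
  }
  stop_value("'wiring' must be \"pooled\", \"independent\", or a list of index vectors")
}

#' Environment grid
#'
#' Ordered evaluation grid over the two environmental factors. The default is
#' the integers 1..20 on both axes, the scale on which the model is defined.
#' Grid coordinates are environmental values, never array indices.
#'
#' @param e1_values,e2_values Strictly increasing numeric vectors.
#' @return An object of class `"env_grid"`.
#' @export
env_grid <- function(e1_values = 1:20, e2_values = 1:20) {
  for (v in list(e1_values, e2_values)) {
    if (!is.numeric(v) || length(v) < 1L || anyNA(v)) {
      stop_value("grid axes must be non-empty numeric vectors")
    }
    if (length(v) > 1L && any(diff(v) <= 0)) {
      stop_value("grid axes must be strictly increasing")
    }
  }
  structure(list(e1_values = as.numeric(e1_values),
                 e2_values = as.numeric(e2_values)),
            class = "env_grid")
}

#' Per-copy upstream activities at one environment
#'
#' @param cfg A [pathway_config()].
#' @param e1,e2 Scalar environmental values.
#' @return One activity in \[0, 1\] per upstream copy.
#' @export
upstream_activities <- function(cfg, e1, e2) {
  stopifnot(inherits(cfg, "pathway_config"))
  vapply(cfg$upstream, function(cp) env_weight(e1, e2, cp), numeric(1))
}

#' Regulatory input of each downstream copy
#'
#' Applies the configuration's wiring and pooling to a vector of upstream
#' activities: pooled wiring combines all copies, independent passes copy i to
#' copy i, and an explicit map combines the mapped subset for each downstream
#' copy. With `pooling = "mean"` combined activities are divided by the number
#' of contributing copies; with `"sum"` the raw total is passed.
#'
#' @param cfg A [pathway_config()].
#' @param U Numeric vector of upstream activities, one per upstream copy.
#' @return One non-negative input value per downstream copy.
#' @export
downstream_inputs <- function(cfg, U) {
  stopifnot(inherits(cfg, "pathway_config"))
  if (length(U) != length(cfg$upstream)) {
    stop_value(sprintf("'U' must have one entry per upstream copy (%d), got %d",
                       length(cfg$upstream), length(U)))
  }
  # sequential addition, matching the vectorized surface path bit-for-bit
  combine <- function(x) {
    tot <- Reduce(`+`, as.list(x))
    if (cfg$pooling == "mean") tot / length(x) else tot
  }
  if (identical(cfg$wiring, "pooled")) {
    rep(combine(U), length(cfg$downstream))
  } else if (identical(cfg$wiring, "independent")) {
    as.numeric(U)
  } else {
    vapply(cfg$wiring, function(idx) combine(U[idx]), numeric(1))
  }
}

#' Per-copy downstream activities at one environment
#'
#' `D_j = link_response(input_j, delta) * env_weight(e1, e2, downstream_j)`:
#' sigmoidally transferred regulatory input, gated by the copy's own
#' environmental weight.
#'
#' @param cfg A [pathway_config()].
#' @param inputs Regulatory inputs from [downstream_inputs()].
#' @param e1,e2 Scalar environmental values.
#' @return One activity in \[0, 1\] per downstream copy.
#' @export
downstream_activities <- function(cfg, inputs, e1, e2) {
  stopifnot(inherits(cfg, "pathway_config"))
  if (length(inputs) != length(cfg$downstream)) {
    stop_value("'inputs' must have one entry per downstream copy")
  }
  mapply(function(cp, x) link_response(x, cfg$link_up_down) * env_weight(e1, e2, cp),
         cfg$downstream, inputs)
}

#' Outcome probability at one environment
#'
#' The full chain: upstream environmental weights, wiring/pooling, downstream
#' sigmoid-times-weight activities, and the gamma link of total downstream
#' activity.
#'
#' @param cfg A [pathway_config()].
#' @param e1,e2 Scalar environmental values.
#' @return Outcome probability strictly within (0, 1).
#' @export
outcome_probability <- function(cfg, e1, e2) {
  U <- upstream_activities(cfg, e1, e2)
  D <- downstream_activities(cfg, downstream_inputs(cfg, U), e1, e2)
  link_response(Reduce(`+`, as.list(D)), cfg$link_down_outcome)
}

#' Evaluate the outcome surface on a grid
#'
#' Vectorized evaluation of the outcome probability and all per-copy
#' activities over every grid cell. Deterministic: identical inputs give
#' bit-identical output.
#'
#' @param cfg A [pathway_config()].
#' @param grid An [env_grid()]; defaults to the integer 1..20 grid.
#' @return An object of class `"outcome_surface"`: a list with `grid`, matrix
#'   `P` (`length(e1_values)` x `length(e2_values)`, rows indexed by e1),
#'   arrays `U` and `D` (copy x e1 x e2), and the originating `config`.
#' @export
evaluate_surface <- function(cfg, grid = env_grid()) {
  stopifnot(inherits(cfg, "pathway_config"), inherits(grid, "env_grid"))
  e1 <- grid$e1_values
  e2 <- grid$e2_values
  n1 <- length(e1)
  n2 <- length(e2)

  weight_matrix <- function(cp) {
    outer(env_response(e1, cp$response_e1), env_response(e2, cp$response_e2))
  }
  Wu <- lapply(cfg$upstream, weight_matrix)    # upstream activities U_i
  Wd <- lapply(cfg$downstream, weight_matrix)  # downstream environmental weights

  combine <- function(mats) {
    tot <- Reduce(`+`, mats)
    if (cfg$pooling == "mean") tot / length(mats) else tot
  }
  inputs <- if (identical(cfg$wiring, "pooled")) {
    rep(list(combine(Wu)), length(cfg$downstream))
  } else if (identical(cfg$wiring, "independent")) {
    Wu
  } else {
    lapply(cfg$wiring, function(idx) combine(Wu[idx]))
  }
  D <- mapply(function(inp, w) link_response(inp, cfg$link_up_down) * w,
              inputs, Wd, SIMPLIFY = FALSE)
  P <- link_response(Reduce(`+`, D), cfg$link_down_outcome)

  as_array <- function(mats) {
    a <- array(0, dim = c(length(mats), n1, n2))
    for (i in seq_along(mats)) a[i, , ] <- mats[[i]]
    a
  }
  structure(
    list(grid = grid, P = P, U = as_array(Wu), D = as_array(D), config = cfg),
    class = "outcome_surface"
  )
}

#' Floor of an outcome surface
#'
#' The nonzero baseline imposed by the outcome link: the outcome probability
#' in the limit of zero downstream activity, `link_response(0, gamma)`. All
#' breadth and prominence thresholds in the package are measured above this
#' floor.
#'
#' @param x An `"outcome_surface"` or `"pathway_config"`.
#' @return The floor probability.
#' @export
surface_floor <- function(x) {
  cfg <- if (inherits(x, "outcome_surface")) x$config else x
  stopifnot(inherits(cfg, "pathway_config"))
  link_response(0, cfg$link_down_outcome)
}

#' @export
print.pathway_config <- function(x, ...) {
  wir <- if (is.character(x$wiring)) x$wiring else "explicit map"
  cat(sprintf("pathway_config: %d upstream / %d downstream copies, %s wiring (%s pooling)\n",
              length(x$upstream), length(x$downstream), wir, x$pooling))
  cat(sprintf("  delta link: intercept %g, slope %g; gamma link: intercept %g, slope %g\n",
              x$link_up_down$intercept, x$link_up_down$slope,
              x$link_down_outcome$intercept, x$link_down_outcome$slope))
  invisible(x)
}

#' @export
print.outcome_surface <- function(x, ...) {
  cat(sprintf("outcome_surface: %d x %d grid, P in [%.4f, %.4f] (floor %.4f)\n",
              length(x$grid$e1_values), length(x$grid$e2_values),
              min(x$P), max(x$P), surface_floor(x)))
  invisible(x)
}
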