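#' Environmental sensitivity of one gene copy to one factor
#'
#' Constructs the unimodal activity function of a single environmental factor:
#' activity is 1 at the optimum and decays as a (possibly asymmetric) Gaussian
#' on either side, `exp(-rate * (e - optimum)^2)`, with `rate_below` applied
#' for `e < optimum` and `rate_above` for `e >= optimum`. Setting both rates
#' to 0 gives an environmentally insensitive ("flat") gene whose activity is 1
#' everywhere; setting only `rate_above = 0` gives a monotone non-decreasing
#' response of the photoperiod type.
#'
#' @param optimum Environmental value (on the 1-20 environment scale) at which
#'   activity is maximal (exactly 1).
#' @param rate_below Non-negative decay rate per squared environmental unit
#'   applied below the optimum.
#' @param rate_above Non-negative decay rate applied at and above the optimum.
#'   Defaults to `rate_below` (the symmetric case written as a single alpha or
#'   beta in figure captions).
#' @return An object of class `"env_sensitivity"`.
#' @seealso [env_response()], [gene_copy()]
#' @examples
#' s <- env_sensitivity(10, 0.01)
#' env_response(10, s)  # 1
#' env_response(20, s)  # exp(-1)
#' @export
env_sensitivity <- function(optimum, rate_below, rate_above = rate_below) {
  stopifnot(is.numeric(optimum), length(optimum) == 1L, is.finite(optimum))
  check_rate(rate_below, "rate_below")
  check_rate(rate_above, "rate_above")
  structure(
    list(optimum = as.numeric(optimum),
         rate_below = as.numeric(rate_below),
         rate_above = as.numeric(rate_above)),
    class = "env_sensitivity"
  )
}

check_rate <- function(rate, what) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop_value(sprintf("'%s' must be a single non-negative finite number, got %s",
                       what, deparse(rate)))
  }
  invisible(rate)
}

#' Evaluate an environmental sensitivity function
#'
#' Returns `exp(-rate * (e - optimum)^2)` with `rate = rate_below` for
#' `e < optimum` and `rate_above` for `e >= optimum` (half-open boundary
#' convention; irrelevant when the rates are equal). Vectorized over `e`.
#'
#' @param e Environmental value(s).
#' @param sens An [env_sensitivity()] object.
#' @return Activity probability in \[0, 1\], same length as `e`.
#' @export
env_response <- function(e, sens) {
  stopifnot(inherits(sens, "env_sensitivity"), is.numeric(e))
  rate <- ifelse(e < sens$optimum, sens$rate_below, sens$rate_above)
  exp(-rate * (e - sens$optimum)^2)
}

#' Saturating sigmoidal regulatory link
#'
#' Constructs the logistic transfer function
#' `f(x) = 1 / (1 + exp(intercept - slope * x))` used both for the
#' upstream-to-downstream link (parameters delta) and the downstream-to-outcome
#' link (parameters gamma). The slope is the gain: for `slope > 0` the function
#' is strictly increasing with inflection at `x = intercept / slope`; for
#' `slope = 0` it is constant. Output is strictly inside (0, 1), so every
#' outcome surface has a nonzero floor `f(0)` (baseline leakage).
#'
#' @param intercept Dimensionless offset (delta0 or gamma0).
#' @param slope Non-negative dimensionless gain per unit of summed activity
#'   (delta1 or gamma1).
#' @return An object of class `"sigmoid_link"`.
#' @examples
#' d <- sigmoid_link(1, 2)
#' link_response(0, d)  # 1/(1 + e) ~ 0.269, the surface floor for gamma=(1,2)
#' link_response(1, d)  # 1/(1 + exp(-1)) ~ 0.731
#' @export
sigmoid_link <- function(intercept, slope) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope < 0) {
    stop_value("'slope' must be a single non-negative finite number")
  }
  structure(list(intercept = as.numeric(intercept), slope = as.numeric(slope)),
            class = "sigmoid_link")
}

#' Evaluate a sigmoidal link
#'
#' @param x Summed activity, `x >= 0`. Vectorized.
#' @param link A [sigmoid_link()] object.
#' @return Probability strictly within (0, 1).
#' @export
link_response <- function(x, link) {
  stopifnot(inherits(link, "sigmoid_link"), is.numeric(x))
  stats::plogis(link$slope * x - link$intercept)
}

#' One gene copy: sensitivities to both environmental factors
#'
#' A gene copy's environmental weight at `(e1, e2)` is the product of its two
#' single-factor responses, so it is 1 exactly at the copy's optimum pair (the
#' "star" condition of the figures) and within \[0, 1\] everywhere.
#'
#' @param response_e1,response_e2 [env_sensitivity()] objects for environmental
#'   factors 1 and 2.
#' @param label Free-text copy identifier.
#' @return An object of class `"gene_copy"`.
#' @export
gene_copy <- function(response_e1, response_e2, label = "") {
  stopifnot(inherits(response_e1, "env_sensitivity"),
            inherits(response_e2, "env_sensitivity"))
  structure(list(response_e1 = response_e1, response_e2 = response_e2,
                 label = as.character(label)),
            class = "gene_copy")
}

#' Environmental weight of a gene copy
#'
#' @param e1,e2 Environmental values (vectorized, recycled together).
#' @param copy A [gene_copy()] object.
#' @return `env_response(e1) * env_response(e2)`, in \[0, 1\].
#' @export
env_weight <- function(e1, e2, copy) {
  stopifnot(inherits(copy, "gene_copy"))
  env_response(e1, copy$response_e1) * env_response(e2, copy$response_e2)
}

#' @export
print.env_sensitivity <- function(x, ...) {
  cat(sprintf("env_sensitivity: optimum %g, rates %g (below) / %g (above)\n",
              x$optimum, x$rate_below, x$rate_above))
  invisible(x)
}

#' @export
print.sigmoid_link <- function(x, ...) {
  infl <- if (x$slope > 0) sprintf("%g", x$intercept / x$slope) else "none (flat)"
  cat(sprintf("sigmoid_link: intercept %g, slope %g (inflection at %s)\n",
              x$intercept, x$slope, infl))
  invisible(x)
}

#' @export
print.gene_copy <- function(x, ...) {
  cat(sprintf("gene_copy%s: e1 optimum %g (rates %g/%g), e2 optimum %g (rates %g/%g)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$response_e1$optimum, x$response_e1$rate_below, x$response_e1$rate_above,
              x$response_e2$optimum, x$response_e2$rate_below, x$response_e2$rate_above))
  invisible(x)
}

# classed error helpers shared across the package: config-file problems map to
# CLI exit code 2, value problems are ordinary parameter errors
stop_value <- function(msg) {
  stop(structure(class = c("pathsurf_value_error", "pathsurf_config_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_schema <- function(msg) {
  stop(structure(class = c("pathsurf_schema_error", "pathsurf_config_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_parse <- function(msg) {
  stop(structure(class = c("pathsurf_parse_error", "pathsurf_config_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
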