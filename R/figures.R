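# Registry of the published figure-panel configurations (Figs 2-5 captions).
#
# Shared caption parameters: sensitive copies decay at rate 0.01 per squared
# environmental unit on both factors (insensitive tiers/factors use rate 0);
# the non-divergent optimum pair is (10, 12); divergent copies sit at (5, 8)
# and (15, 16). Figure 2-3 links are delta = gamma = (1, 2) except panel 2E
# (delta = (5, 7)); Figure 4-5 links are delta = (5, 7), gamma = (1, 2).
# Panels with no copy diversification are rendered as two identical copies
# per tier. Figure 4 panels default to independent wiring (see the vignette
# for why: pooled wiring merges panel B's two activity peaks into one, and
# panel 5A is presented as the pooled counterpart of 4D); a wiring override
# is available. Panels 5A/5C are pooled, 5B/5D independent.

figure_registry <- function() {
  s <- function(opt, rate = 0.01) env_sensitivity(opt, rate)
  cp <- function(o1, o2, r1 = 0.01, r2 = 0.01, label = "") {
    gene_copy(s(o1, r1), s(o2, r2), label = label)
  }
  # two identical copies per tier for the undiversified panels
  twin <- function(copy) {
    list(gene_copy(copy$response_e1, copy$response_e2, paste0(copy$label, "_1")),
         gene_copy(copy$response_e1, copy$response_e2, paste0(copy$label, "_2")))
  }
  d12 <- sigmoid_link(1, 2)
  d57 <- sigmoid_link(5, 7)

  panel <- function(id, upstream, downstream, delta, gamma, wiring, notes,
                    expect = list(), annotations = NULL) {
    list(id = id,
         config = pathway_config(upstream, downstream, delta, gamma, wiring = wiring),
         notes = notes, expected_qualitative = expect, annotations = annotations)
  }
  amax <- function(e1, e2) list(type = "argmax_at", cell = c(e1, e2))
  npk <- function(n) list(type = "n_peaks", n = n)
  pkat <- function(...) list(type = "peaks_at", cells = list(...))
  far <- function(e1, e2) list(type = "argmax_not_within_one_cell", cell = c(e1, e2))

  panels <- list(
    panel("2A", twin(cp(10, 12, label = "up")), twin(cp(10, 12, 0, 0, label = "down")),
          d12, d12, "pooled",
          "upstream tier sensitive to both factors (optima 10, 12); downstream tier flat",
          list(amax(10, 12), npk(1))),
    panel("2B", twin(cp(10, 12, 0, 0, label = "up")), twin(cp(10, 12, label = "down")),
          d12, d12, "pooled",
          "downstream tier sensitive to both factors (optima 10, 12); upstream tier flat",
          list(amax(10, 12), npk(1))),
    panel("2C", twin(cp(10, 12, 0.01, 0, label = "up")), twin(cp(10, 12, 0, 0.01, label = "down")),
          d12, d12, "pooled",
          "upstream sensitive to factor 1 only (optimum 10); downstream to factor 2 only (optimum 12)",
          list(amax(10, 12), npk(1))),
    panel("2D", twin(cp(10, 12, label = "up")), twin(cp(10, 12, label = "down")),
          d12, d12, "pooled",
          "both tiers sensitive with identical optima (10, 12)",
          list(amax(10, 12), npk(1))),
    panel("2E", twin(cp(10, 12, 0.01, 0, label = "up")), twin(cp(10, 12, 0, 0.01, label = "down")),
          d57, d12, "pooled",
          "as 2C but with the steeper upstream-to-downstream link (5, 7)",
          list(amax(10, 12), npk(1))),
    panel("3A", twin(cp(10, 12, label = "up")), twin(cp(10, 12, label = "down")),
          d12, d12, "pooled",
          "both tiers peak at the adaptive optimum (10, 12); identical to 2D plus annotation",
          list(amax(10, 12), npk(1)), annotations = list(adaptive_optimum = c(10, 12))),
    panel("3B", twin(cp(10, 12, label = "up")), twin(cp(5, 8, label = "down")),
          d12, d12, "pooled",
          "upstream at the adaptive optimum (10, 12); downstream mismatched at (5, 8)",
          list(npk(1), far(10, 12)), annotations = list(adaptive_optimum = c(10, 12))),
    panel("3C", twin(cp(15, 16, label = "up")), twin(cp(5, 8, label = "down")),
          d12, d12, "pooled",
          "compensatory mismatch: upstream at (15, 16), downstream at (5, 8)",
          list(npk(1)), annotations = list(adaptive_optimum = c(10, 12))),
    panel("4A",
          list(cp(10, 8, label = "up_1"), cp(10, 16, label = "up_2")),
          list(cp(5, 12, label = "down_1"), cp(15, 12, label = "down_2")),
          d57, d12, "independent",
          "upstream copies divergent in factor 2 (optima 8 / 16), downstream in factor 1 (optima 5 / 15)",
          list(npk(1))),
    panel("4B",
          list(cp(5, 8, label = "up_1"), cp(15, 16, label = "up_2")),
          list(cp(10, 12, label = "down_1"), cp(10, 12, label = "down_2")),
          d57, d12, "independent",
          "upstream copies divergent in both factors; downstream copies not divergent (10, 12)",
          list(npk(2))),
    panel("4C",
          list(cp(10, 12, label = "up_1"), cp(10, 12, label = "up_2")),
          list(cp(5, 8, label = "down_1"), cp(15, 16, label = "down_2")),
          d57, d12, "independent",
          "downstream copies divergent in both factors; upstream copies not divergent (10, 12)",
          list(npk(1))),
    panel("4D",
          list(cp(5, 8, label = "up_1"), cp(15, 16, label = "up_2")),
          list(cp(5, 8, label = "down_1"), cp(15, 16, label = "down_2")),
          d57, d12, "independent",
          "upstream and downstream copies identically divergent: (5, 8) and (15, 16)",
          list(npk(2), pkat(c(5, 8), c(15, 16)))),
    panel("5A",
          list(cp(5, 8, label = "up_1"), cp(15, 16, label = "up_2")),
          list(cp(5, 8, label = "down_1"), cp(15, 16, label = "down_2")),
          d57, d12, "pooled",
          "identically divergent copies under pooled regulation (the pooled counterpart of 4D)",
          list(npk(1))),
    panel("5B",
          list(cp(5, 8, label = "up_1"), cp(15, 16, label = "up_2")),
          list(cp(5, 8, label = "down_1"), cp(15, 16, label = "down_2")),
          d57, d12, "independent",
          "identically divergent copies under independent regulation (two parallel pathways)",
          list(npk(2), pkat(c(5, 8), c(15, 16)))),
    panel("5C",
          list(cp(5, 8, label = "up_1"), cp(15, 16, label = "up_2")),
          list(cp(15, 16, label = "down_1"), cp(5, 8, label = "down_2")),
          d57, d12, "pooled",
          "mismatched pairing (upstream copy 1 at (5, 8) feeds the tier whose copy 1 sits at (15, 16)); pooled",
          list()),
    panel("5D",
          list(cp(5, 8, label = "up_1"), cp(15, 16, label = "up_2")),
          list(cp(15, 16, label = "down_1"), cp(5, 8, label = "down_2")),
          d57, d12, "independent",
          "mismatched pairing as 5C but independent regulation",
          list())
  )
  names(panels) <- vapply(panels, `[[`, character(1), "id")
  panels
}

#' Registered figure-panel identifiers
#'
#' @return Character vector of panel ids (`"2A"` .. `"5D"`).
#' @export
figure_ids <- function() names(figure_registry())

#' Retrieve a registered figure-panel configuration
#'
#' Returns the fully resolved pathway configuration for one published heat-map
#' panel, together with provenance notes and the machine-checkable qualitative
#' expectations encoded for it (peak counts, forced argmax cells). Panels
#' 2A-2E and 3A-3C use two identical copies per tier under pooled regulation;
#' 4A-4D default to independent wiring (overridable); 5A/5C are pooled and
#' 5B/5D independent.
#'
#' @param id Panel identifier, e.g. `"2A"`, `"5B"`.
#' @param wiring Optional wiring override (`"pooled"` or `"independent"`).
#' @return An object of class `"figure_config"`: list with `id`, `config`
#'   ([pathway_config()]), `notes`, `expected_qualitative`, `annotations`.
#' @export
figure_config <- function(id, wiring = NULL) {
  reg <- figure_registry()
  if (!is.character(id) || length(id) != 1L || !id %in% names(reg)) {
    stop_value(sprintf("unknown figure id '%s' (known: %s)",
                       as.character(id)[1L], paste(names(reg), collapse = ", ")))
  }
  fc <- reg[[id]]
  if (!is.null(wiring)) {
    cfg <- fc$config
    fc$config <- pathway_config(cfg$upstream, cfg$downstream, cfg$link_up_down,
                                cfg$link_down_outcome, wiring = wiring,
                                pooling = cfg$pooling)
    # peak-structure expectations are encoded for the default wiring only
    fc$expected_qualitative <- list()
    fc$notes <- paste0(fc$notes, sprintf(" [wiring overridden to %s]", wiring))
  }
  structure(fc, class = "figure_config")
}

#' @export
print.figure_config <- function(x, ...) {
  cat(sprintf("figure_config %s: %s\n", x$id, x$notes))
  print(x$config)
  invisible(x)
}

check_expectations <- function(surface, expected, min_prominence = 0.05) {
  if (length(expected) == 0L) {
    return(data.frame(assertion = character(0), pass = logical(0)))
  }
  ps <- find_local_maxima(surface, min_prominence)
  am_idx <- global_argmax_cell(surface$P)
  am <- c(surface$grid$e1_values[am_idx[1L]], surface$grid$e2_values[am_idx[2L]])
  rows <- lapply(expected, function(ex) {
    switch(ex$type,
      argmax_at = data.frame(
        assertion = sprintf("global argmax at (%g, %g)", ex$cell[1], ex$cell[2]),
        pass = all(am == ex$cell)),
      argmax_not_within_one_cell = data.frame(
        assertion = sprintf("global argmax more than one cell from (%g, %g)",
                            ex$cell[1], ex$cell[2]),
        pass = max(abs(am - ex$cell)) > 1),
      n_peaks = data.frame(
        assertion = sprintf("%d local maxim%s", ex$n, if (ex$n == 1L) "um" else "a"),
        pass = nrow(ps$peaks) == ex$n),
      peaks_at = data.frame(
        assertion = sprintf("peaks exactly at {%s}", paste(
          vapply(ex$cells, function(c2) sprintf("(%g, %g)", c2[1], c2[2]), character(1)),
          collapse = ", ")),
        pass = nrow(ps$peaks) == length(ex$cells) &&
          all(vapply(ex$cells, function(c2)
            any(ps$peaks$e1 == c2[1] & ps$peaks$e2 == c2[2]), logical(1)))),
      stop(sprintf("unknown expectation type '%s'", ex$type))
    )
  })
  do.call(rbind, rows)
}

#' Evaluate, analyze and optionally export one registered panel
#'
#' Evaluates the panel's surface on the given grid, computes metrics and
#' peaks, checks the panel's encoded qualitative expectations, and (when
#' `output_dir` is given) writes the surface CSV, metrics JSON, peaks CSV and
#' optionally a PNG heat map.
#'
#' @param id Panel identifier.
#' @param grid An [env_grid()]; default integer 1..20.
#' @param output_dir Optional output directory.
#' @param wiring Optional wiring override (see [figure_config()]).
#' @param formats Output formats when `output_dir` is given.
#' @param min_prominence Peak prominence threshold.
#' @return A list with `figure` (the [figure_config()]), `surface`, `metrics`,
#'   `peaks`, `expectations` (data frame with `assertion`, `pass`), and
#'   `files` (paths written, or empty).
#' @export
run_figure <- function(id, grid = env_grid(), output_dir = NULL, wiring = NULL,
                       formats = c("csv", "json"), min_prominence = 0.05) {
  fc <- figure_config(id, wiring = wiring)
  surface <- evaluate_surface(fc$config, grid)
  metrics <- breadth_metrics(surface, min_prominence = min_prominence)
  peaks <- find_local_maxima(surface, min_prominence)
  expectations <- check_expectations(surface, fc$expected_qualitative, min_prominence)
  files <- character(0)
  if (!is.null(output_dir)) {
    files <- write_surface(surface, output_dir, formats = formats,
                           prefix = paste0("figure_", id),
                           min_prominence = min_prominence)
  }
  list(figure = fc, surface = surface, metrics = metrics, peaks = peaks,
       expectations = expectations, files = files)
}

#' Export the full figure registry as an editable YAML document
#'
#' Writes every registered panel (id, notes, full pathway configuration) to a
#' single YAML file that users can copy-edit and feed back through
#' [read_run_config()] (each panel's `pathway` block is a valid `pathway`
#' section).
#'
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
export_figure_registry <- function(path) {
  reg <- figure_registry()
  doc <- lapply(reg, function(fc) {
    list(notes = fc$notes, pathway = config_to_list(fc$config))
  })
  atomic_write_lines(yaml::as.yaml(doc), path)
  invisible(path)
}
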