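#' @importFrom stats plogis
#' @importFrom utils read.csv write.csv
NULL

# ---- config (de)serialization ------------------------------------------------

sens_to_list <- function(s) {
  if (s$rate_below == s$rate_above) {
    list(optimum = s$optimum, rate = s$rate_below)
  } else {
    list(optimum = s$optimum, rate_below = s$rate_below, rate_above = s$rate_above)
  }
}

copy_to_list <- function(cp) {
  out <- list(e1 = sens_to_list(cp$response_e1), e2 = sens_to_list(cp$response_e2))
  if (nzchar(cp$label)) out$label <- cp$label
  out
}

link_to_list <- function(l) list(intercept = l$intercept, slope = l$slope)

config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "pathway_config"))
  wiring <- if (is.character(cfg$wiring)) cfg$wiring else lapply(cfg$wiring, as.integer)
  list(upstream = lapply(cfg$upstream, copy_to_list),
       downstream = lapply(cfg$downstream, copy_to_list),
       link_up_down = link_to_list(cfg$link_up_down),
       link_down_outcome = link_to_list(cfg$link_down_outcome),
       wiring = wiring,
       pooling = cfg$pooling)
}

known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop_schema(sprintf("unknown key '%s' in %s (allowed: %s)",
                        extra[1L], where, paste(allowed, collapse = ", ")))
  }
  invisible(x)
}

need_number <- function(x, key, where) {
  if (is.null(x)) stop_schema(sprintf("missing required key '%s' in %s", key, where))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_schema(sprintf("key '%s' in %s must be a single number", key, where))
  }
  as.numeric(x)
}

sens_from_list <- function(lst, where) {
  if (!is.list(lst)) stop_schema(sprintf("%s must be a mapping", where))
  known_keys(lst, c("optimum", "rate", "rate_below", "rate_above"), where)
  opt <- need_number(lst$optimum, "optimum", where)
  if (!is.null(lst$rate)) {
    if (!is.null(lst$rate_below) || !is.null(lst$rate_above)) {
      stop_schema(sprintf("%s: give either 'rate' or 'rate_below'/'rate_above', not both", where))
    }
    rb <- ra <- need_number(lst$rate, "rate", where)
  } else {
    rb <- need_number(lst$rate_below, "rate_below", where)
    ra <- need_number(lst$rate_above, "rate_above", where)
  }
  if (rb < 0) stop_value(sprintf("%s: 'rate_below' must be non-negative, got %g", where, rb))
  if (ra < 0) stop_value(sprintf("%s: 'rate_above' must be non-negative, got %g", where, ra))
  env_sensitivity(opt, rb, ra)
}

copy_from_list <- function(lst, where) {
  if (!is.list(lst)) stop_schema(sprintf("%s must be a mapping", where))
  known_keys(lst, c("e1", "e2", "label"), where)
  if (is.null(lst$e1) || is.null(lst$e2)) {
    stop_schema(sprintf("%s must define 'e1' and 'e2' sensitivities", where))
  }
  gene_copy(sens_from_list(lst$e1, paste0(where, ".e1")),
            sens_from_list(lst$e2, paste0(where, ".e2")),
            label = if (is.null(lst$label)) "" else as.character(lst$label))
}

link_from_list <- function(lst, where) {
  if (!is.list(lst)) stop_schema(sprintf("%s must be a mapping", where))
  known_keys(lst, c("intercept", "slope"), where)
  slope <- need_number(lst$slope, "slope", where)
  if (slope < 0) stop_value(sprintf("%s: 'slope' must be non-negative, got %g", where, slope))
  sigmoid_link(need_number(lst$intercept, "intercept", where), slope)
}

config_from_list <- function(lst, where = "pathway") {
  if (!is.list(lst)) stop_schema(sprintf("%s must be a mapping", where))
  known_keys(lst, c("upstream", "downstream", "link_up_down", "link_down_outcome",
                    "wiring", "pooling"), where)
  for (tier in c("upstream", "downstream")) {
    if (is.null(lst[[tier]]) || !is.list(lst[[tier]]) || length(lst[[tier]]) < 1L) {
      stop_schema(sprintf("%s must list at least one %s copy", where, tier))
    }
  }
  up <- lapply(seq_along(lst$upstream), function(i)
    copy_from_list(lst$upstream[[i]], sprintf("%s.upstream[%d]", where, i)))
  dn <- lapply(seq_along(lst$downstream), function(i)
    copy_from_list(lst$downstream[[i]], sprintf("%s.downstream[%d]", where, i)))
  if (is.null(lst$link_up_down) || is.null(lst$link_down_outcome)) {
    stop_schema(sprintf("%s must define 'link_up_down' and 'link_down_outcome'", where))
  }
  wiring <- if (is.null(lst$wiring)) "pooled" else lst$wiring
  pooling <- if (is.null(lst$pooling)) "mean" else lst$pooling
  if (!is.character(pooling) || !pooling %in% c("mean", "sum")) {
    stop_schema(sprintf("%s: 'pooling' must be \"mean\" or \"sum\"", where))
  }
  pathway_config(up, dn,
                 link_from_list(lst$link_up_down, paste0(where, ".link_up_down")),
                 link_from_list(lst$link_down_outcome, paste0(where, ".link_down_outcome")),
                 wiring = wiring, pooling = pooling)
}

# ---- run configuration -------------------------------------------------------

#' Read and validate a run configuration file
#'
#' Parses a YAML (`.yaml`/`.yml`) or JSON (`.json`) run configuration,
#' validates it fully before any computation, and fills defaults. Unknown keys
#' are rejected with the offending key named. Three error classes are
#' distinguished: `pathsurf_parse_error` (unreadable file),
#' `pathsurf_schema_error` (wrong structure or unknown/missing key), and
#' `pathsurf_value_error` (a well-formed but invalid parameter value, e.g. a
#' negative rate); all inherit `pathsurf_config_error`.
#'
#' Top-level keys: `pathway` (required; see [pathway_config()] for the
#' fields), `grid` (`e1_min`, `e1_max`, `e2_min`, `e2_max`, `step`; defaults
#' 1, 20, 1, 20, 1), `analysis` (`min_prominence`, default 0.05;
#' `query_cells`, a list of `[e1, e2]` pairs), `output` (`dir`, `formats`,
#' `render`), and `log_level` (`"info"` or `"quiet"`).
#'
#' @param path Path to the configuration file.
#' @return An object of class `"run_config"`: list with `pathway`
#'   ([pathway_config()]), `grid` ([env_grid()]), `analysis`, `output`,
#'   `log_level`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("config file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           yaml = , yml = yaml::read_yaml(path),
           json = jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
           stop_parse(sprintf("unsupported config extension '.%s' (use .yaml/.yml/.json)", ext))),
    error = function(e) {
      if (inherits(e, "pathsurf_config_error")) stop(e)
      stop_parse(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
    })
  if (!is.list(raw)) stop_schema("config root must be a mapping")
  known_keys(raw, c("pathway", "grid", "analysis", "output", "log_level"), "config root")
  if (is.null(raw$pathway)) stop_schema("missing required key 'pathway' in config root")
  pathway <- config_from_list(raw$pathway)

  g <- if (is.null(raw$grid)) list() else raw$grid
  known_keys(g, c("e1_min", "e1_max", "e2_min", "e2_max", "step"), "grid")
  gd <- function(key, default) if (is.null(g[[key]])) default else need_number(g[[key]], key, "grid")
  e1_min <- gd("e1_min", 1); e1_max <- gd("e1_max", 20)
  e2_min <- gd("e2_min", 1); e2_max <- gd("e2_max", 20)
  step <- gd("step", 1)
  if (step <= 0) stop_value(sprintf("grid: 'step' must be positive, got %g", step))
  if (e1_min >= e1_max) stop_value("grid: 'e1_min' must be smaller than 'e1_max'")
  if (e2_min >= e2_max) stop_value("grid: 'e2_min' must be smaller than 'e2_max'")
  grid <- env_grid(seq(e1_min, e1_max, by = step), seq(e2_min, e2_max, by = step))

  a <- if (is.null(raw$analysis)) list() else raw$analysis
  known_keys(a, c("min_prominence", "query_cells"), "analysis")
  min_prom <- if (is.null(a$min_prominence)) 0.05 else need_number(a$min_prominence, "min_prominence", "analysis")
  if (min_prom < 0) stop_value("analysis: 'min_prominence' must be non-negative")
  query_cells <- NULL
  if (!is.null(a$query_cells)) {
    query_cells <- lapply(seq_along(a$query_cells), function(i) {
      cell <- unlist(a$query_cells[[i]])
      if (!is.numeric(cell) || length(cell) != 2L) {
        stop_schema(sprintf("analysis.query_cells[%d] must be a pair [e1, e2]", i))
      }
      as.numeric(cell)
    })
  }

  o <- if (is.null(raw$output)) list() else raw$output
  known_keys(o, c("dir", "formats", "render"), "output")
  formats <- if (is.null(o$formats)) c("csv", "json") else unlist(o$formats)
  bad <- setdiff(formats, c("csv", "json", "png"))
  if (length(bad) > 0L) stop_schema(sprintf("output: unknown format '%s'", bad[1L]))
  output <- list(dir = if (is.null(o$dir)) "." else as.character(o$dir),
                 formats = formats,
                 render = isTRUE(o$render) || "png" %in% formats)

  log_level <- if (is.null(raw$log_level)) "info" else as.character(raw$log_level)
  if (!log_level %in% c("info", "quiet")) {
    stop_schema(sprintf("log_level must be \"info\" or \"quiet\", got \"%s\"", log_level))
  }
  structure(list(pathway = pathway, grid = grid,
                 analysis = list(min_prominence = min_prom, query_cells = query_cells),
                 output = output, log_level = log_level),
            class = "run_config")
}

#' Write a pathway configuration to YAML or JSON
#'
#' Serializes a [pathway_config()] (under a top-level `pathway` key, so the
#' file is a valid input for [read_run_config()]). Reading the file back
#' yields an identical configuration.
#'
#' @param cfg A [pathway_config()].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pathway_config"))
  doc <- list(pathway = config_to_list(cfg))
  ext <- tolower(tools::file_ext(path))
  txt <- switch(ext,
                yaml = , yml = yaml::as.yaml(doc),
                json = jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE),
                stop_parse(sprintf("unsupported config extension '.%s'", ext)))
  atomic_write_lines(as.character(txt), path)
  invisible(path)
}

# ---- surface serialization ---------------------------------------------------

atomic_write_lines <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(text, tmp)
  if (!file.rename(tmp, path)) stop(sprintf("cannot write '%s'", path))
  invisible(path)
}

surface_long_df <- function(surface) {
  e1 <- surface$grid$e1_values
  e2 <- surface$grid$e2_values
  n1 <- length(e1); n2 <- length(e2)
  # row-major by e1 then e2: e1 varies slowest
  i <- rep(seq_len(n1), each = n2)
  j <- rep(seq_len(n2), times = n1)
  df <- data.frame(e1 = e1[i], e2 = e2[j], P = surface$P[cbind(i, j)])
  for (k in seq_len(dim(surface$U)[1L])) df[[paste0("U_", k)]] <- surface$U[k, , ][cbind(i, j)]
  for (k in seq_len(dim(surface$D)[1L])) df[[paste0("D_", k)]] <- surface$D[k, , ][cbind(i, j)]
  df
}

#' Write an evaluated surface (and metrics) to disk
#'
#' Writes a long-format CSV with header `e1,e2,P,U_1..U_n,D_1..D_m` (one row
#' per grid cell, ordered by e1 then e2, full double precision so the surface
#' re-reads bit-identically), a metrics JSON, a peaks CSV, and optionally a
#' PNG heat map with axes in environment units and the sensitive copies'
#' optima marked (upstream white, downstream black). All writes are atomic
#' (temporary file, then rename).
#'
#' @param surface An evaluated [evaluate_surface()] object.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "png")`.
#' @param prefix Filename prefix, default `"surface"`.
#' @param min_prominence Passed to [breadth_metrics()].
#' @param query_cells Optional list of `c(e1, e2)` cells for the metrics JSON.
#' @return Named character vector of the files written.
#' @export
write_surface <- function(surface, dir, formats = c("csv", "json"),
                          prefix = "surface", min_prominence = 0.05,
                          query_cells = NULL) {
  stopifnot(inherits(surface, "outcome_surface"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  fmt17 <- function(x) sprintf("%.17g", x)
  if ("csv" %in% formats) {
    df <- surface_long_df(surface)
    lines <- c(paste(names(df), collapse = ","),
               do.call(paste, c(lapply(df, function(col)
                 if (is.numeric(col)) fmt17(col) else as.character(col)),
                 sep = ",")))
    f <- file.path(dir, paste0(prefix, ".csv"))
    atomic_write_lines(lines, f)
    files["csv"] <- f
  }
  if ("json" %in% formats || "csv" %in% formats) {
    m <- breadth_metrics(surface, value_at = query_cells, min_prominence = min_prominence)
    if ("json" %in% formats) {
      payload <- list(n_peaks = m$n_peaks, half_max_area = m$half_max_area,
                      axis_halfwidths = as.list(m$axis_halfwidths),
                      total_mass = m$total_mass, n_cells = m$n_cells,
                      max_P = m$max_P, floor = m$floor, degenerate = m$degenerate)
      if (!is.null(m$value_at)) payload$value_at <- as.list(m$value_at)
      f <- file.path(dir, paste0(prefix, "_metrics.json"))
      atomic_write_lines(as.character(
        jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)), f)
      files["metrics"] <- f
    }
    pk <- m$peaks
    lines <- c("e1,e2,P",
               if (nrow(pk) > 0L) paste(fmt17(pk$e1), fmt17(pk$e2), fmt17(pk$P), sep = ","))
    f <- file.path(dir, paste0(prefix, "_peaks.csv"))
    atomic_write_lines(lines, f)
    files["peaks"] <- f
  }
  if ("png" %in% formats) {
    f <- file.path(dir, paste0(prefix, ".png"))
    grDevices::png(f, width = 900, height = 800, res = 130)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(surface, main = prefix)
    files["png"] <- f
  }
  files
}

#' Re-read a surface CSV written by [write_surface()]
#'
#' @param path Path to the long-format CSV.
#' @return A list with `grid` ([env_grid()]), matrix `P`, and arrays `U`, `D`
#'   (copy x e1 x e2). Values round-trip bit-identically.
#' @export
read_surface_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  e1 <- sort(unique(df$e1))
  e2 <- sort(unique(df$e2))
  grid <- env_grid(e1, e2)
  i <- match(df$e1, e1); j <- match(df$e2, e2)
  fill <- function(col) {
    m <- matrix(NA_real_, length(e1), length(e2))
    m[cbind(i, j)] <- col
    m
  }
  ucols <- grep("^U_", names(df), value = TRUE)
  dcols <- grep("^D_", names(df), value = TRUE)
  as_arr <- function(cols) {
    a <- array(NA_real_, dim = c(length(cols), length(e1), length(e2)))
    for (k in seq_along(cols)) a[k, , ] <- fill(df[[cols[k]]])
    a
  }
  list(grid = grid, P = fill(df$P), U = as_arr(ucols), D = as_arr(dcols))
}

#' Heat map of an outcome surface
#'
#' Base-graphics heat map with axes in environment units. The optima of
#' environmentally sensitive copies are marked with stars: white for upstream
#' copies, black for downstream copies (insensitive copies, whose nominal
#' optima carry no information, are not marked).
#'
#' @param x An evaluated [evaluate_surface()] object.
#' @param stars Mark sensitive copies' optima.
#' @param ... Further arguments to [graphics::image()] (e.g. `main`).
#' @return `x`, invisibly.
#' @export
plot.outcome_surface <- function(x, stars = TRUE, ...) {
  cols <- grDevices::hcl.colors(64, "viridis")
  graphics::image(x$grid$e1_values, x$grid$e2_values, x$P, col = cols,
                  xlab = "environmental factor 1", ylab = "environmental factor 2",
                  zlim = c(0, 1), useRaster = TRUE, ...)
  if (stars) {
    sensitive <- function(cp) {
      cp$response_e1$rate_below > 0 || cp$response_e1$rate_above > 0 ||
        cp$response_e2$rate_below > 0 || cp$response_e2$rate_above > 0
    }
    mark <- function(copies, col) {
      for (cp in copies) {
        if (sensitive(cp)) {
          graphics::points(cp$response_e1$optimum, cp$response_e2$optimum,
                           pch = 8, col = col, cex = 1.4, lwd = 2)
        }
      }
    }
    mark(x$config$upstream, "white")
    mark(x$config$downstream, "black")
  }
  invisible(x)
}
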