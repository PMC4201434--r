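test_that("peak detection matches the exhaustive definition on every panel", {
  for (id in figure_ids()) {
    s <- evaluate_surface(figure_config(id)$config)
    got <- find_local_maxima(s, 0.05)
    want <- oracle_peaks(s$P, s$grid$e1_values, s$grid$e2_values,
                         surface_floor(s), 0.05)
    expect_equal(got$peaks, want, info = paste("panel", id))
  }
})

test_that("peak detection matches the exhaustive definition on random surfaces", {
  set.seed(7)
  for (rep in 1:6) {
    cc <- random_case()
    s <- evaluate_surface(cc$cfg)
    for (prom in c(0, 0.05, 0.2)) {
      got <- find_local_maxima(s, prom)
      want <- oracle_peaks(s$P, s$grid$e1_values, s$grid$e2_values,
                           surface_floor(s), prom)
      expect_equal(got$peaks, want)
    }
  }
})

test_that("plateaus merge to a single peak at the smallest cell", {
  cfg <- pathway_config(
    upstream = list(make_copy(10, 12, 0, 0)), downstream = list(make_copy(10, 12, 0, 0)),
    link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
  s <- evaluate_surface(cfg)  # exactly constant: one 400-cell plateau
  ps <- find_local_maxima(s, 0)
  expect_identical(nrow(ps$peaks), 1L)
  expect_equal(unlist(ps$peaks[1, c("e1", "e2")], use.names = FALSE), c(1, 1))
  # a constant surface sitting at the floor is discarded by the prominence rule
  dead <- pathway_config(
    upstream = list(make_copy(10, 12, 5, 5)), downstream = list(make_copy(10, 12, 5, 5)),
    link_up_down = sigmoid_link(20, 1), link_down_outcome = sigmoid_link(1, 2))
  expect_identical(nrow(find_local_maxima(evaluate_surface(dead), 0.05)$peaks), 0L)
})

test_that("breadth metrics honour the floor-relative half-maximum definition", {
  s <- evaluate_surface(figure_config("2D")$config)
  m <- breadth_metrics(s)
  fl <- surface_floor(s)
  level <- fl + (max(s$P) - fl) / 2
  expect_identical(m$half_max_area, sum(s$P >= level))
  am <- which(s$P == max(s$P), arr.ind = TRUE)[1, ]
  expect_identical(m$axis_halfwidths[["e1"]], sum(s$P[, am[2]] >= level))
  expect_identical(m$axis_halfwidths[["e2"]], sum(s$P[am[1], ] >= level))
  expect_equal(m$total_mass, sum(s$P))
  expect_identical(m$n_cells, 400L)
  expect_identical(m$n_peaks, 1L)
  # query cells read P directly, and off-grid queries are rejected
  m2 <- breadth_metrics(s, value_at = list(c(10, 12), c(1, 1)))
  expect_equal(unname(m2$value_at), c(max(s$P), s$P[1, 1]))
  expect_error(breadth_metrics(s, value_at = c(10.5, 12)), class = "pathsurf_value_error")
})

test_that("an insensitive pathway's flat surface spans the whole grid", {
  cfg <- pathway_config(
    upstream = list(make_copy(10, 12, 0, 0)), downstream = list(make_copy(10, 12, 0, 0)),
    link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
  expect_warning(m <- breadth_metrics(evaluate_surface(cfg)), "flat")
  expect_true(m$degenerate)
  expect_identical(m$half_max_area, 400L)
})

test_that("total mass is invariant to copy order and axis transposition", {
  copies <- list(list(u = c(5, 8, 0.01, 0.02), d = c(12, 3, 0.02, 0.01)),
                 list(u = c(15, 16, 0.01, 0.01), d = c(4, 18, 0.005, 0.01)))
  a <- build_case(copies, c(2, 3), c(1, 2))
  perm <- build_case(copies[2:1], c(2, 3), c(1, 2))
  expect_equal(breadth_metrics(evaluate_surface(a$cfg))$total_mass,
               breadth_metrics(evaluate_surface(perm$cfg))$total_mass)
  # swap the two environmental axes in every copy: the surface transposes
  swapped <- lapply(copies, function(cp) list(u = cp$u[c(2, 1, 4, 3)],
                                              d = cp$d[c(2, 1, 4, 3)]))
  b <- build_case(swapped, c(2, 3), c(1, 2))
  Sa <- evaluate_surface(a$cfg)
  Sb <- evaluate_surface(b$cfg)
  expect_equal(Sb$P, t(Sa$P))
  expect_equal(sum(Sb$P), sum(Sa$P))
})

test_that("comparing a surface with itself yields zero differences", {
  s <- evaluate_surface(figure_config("5B")$config)
  cmp <- compare_surfaces(s, s, query_cells = list(c(5, 8), c(15, 16)))
  expect_identical(cmp$delta_total_mass, 0)
  expect_identical(cmp$delta_max, 0)
  expect_identical(unname(cmp$delta_value_at), c(0, 0))
  expect_true(all(cmp$peak_matching$dist_to_other == 0))
  other <- evaluate_surface(figure_config("5B")$config,
                            env_grid(seq(1, 20, 0.5), 1:20))
  expect_error(compare_surfaces(s, other), class = "pathsurf_value_error")
})

test_that("peak-to-optimum distances are Euclidean in environment units", {
  s <- evaluate_surface(figure_config("5B")$config)
  pm <- peak_optimum_match(find_local_maxima(s), figure_config("5B")$config)
  # both peaks land exactly on a copy optimum pair in each tier
  for (k in 1:2) {
    expect_identical(min(pm$distance[pm$peak == k & pm$tier == "upstream"]), 0)
    expect_identical(min(pm$distance[pm$peak == k & pm$tier == "downstream"]), 0)
  }
  one <- pm[pm$peak == 1 & pm$tier == "upstream" & pm$copy == 2, ]
  expect_equal(one$distance, sqrt((one$peak_e1 - 15)^2 + (one$peak_e2 - 16)^2))
  # empty peak sets give an empty table
  dead <- pathway_config(
    upstream = list(make_copy(10, 12, 5, 5)), downstream = list(make_copy(10, 12, 5, 5)),
    link_up_down = sigmoid_link(20, 1), link_down_outcome = sigmoid_link(1, 2))
  empty <- peak_optimum_match(find_local_maxima(evaluate_surface(dead)),
                              figure_config("5B")$config)
  expect_identical(nrow(empty), 0L)
})

test_that("a one-value sweep reproduces direct evaluation and leaves the base intact", {
  fc <- figure_config("2C")
  before <- fc$config
  tab <- parameter_sweep(fc$config, "link_down_outcome.slope", 2)
  direct <- breadth_metrics(evaluate_surface(fc$config))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$half_max_area, direct$half_max_area)
  expect_identical(tab$total_mass, direct$total_mass)
  expect_identical(fc$config, before)
  expect_error(parameter_sweep(fc$config, "link_down_outcome.steepness", 1:2),
               class = "pathsurf_value_error")
  expect_error(parameter_sweep(fc$config, "upstream[9].response_e1.optimum", 1),
               class = "pathsurf_value_error")
})

test_that("growing upstream divergence splits one activity peak into two", {
  base <- pathway_config(
    upstream = list(make_copy(5, 8), make_copy(15, 8)),
    downstream = list(make_copy(10, 12), make_copy(10, 12)),
    link_up_down = sigmoid_link(5, 7), link_down_outcome = sigmoid_link(1, 2),
    wiring = "independent")
  tab <- parameter_sweep(base, "upstream[2].response_e2.optimum", c(8, 10, 12, 14, 16))
  expect_identical(tab$n_peaks[1], 1L)
  expect_identical(tab$n_peaks[nrow(tab)], 2L)
  expect_true(all(diff(tab$n_peaks) >= 0))
})
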