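fig5b_copies <- list(list(u = c(5, 8, 0.01, 0.01), d = c(5, 8, 0.01, 0.01)),
                     list(u = c(15, 16, 0.01, 0.01), d = c(15, 16, 0.01, 0.01)))

test_that("upstream activities are the copies' environmental weights", {
  cc <- build_case(fig5b_copies, delta = c(5, 7), gamma = c(1, 2), wiring = "independent")
  expect_equal(upstream_activities(cc$cfg, 5, 8), c(1, exp(-0.01 * (100 + 64))))
  expect_equal(upstream_activities(cc$cfg, 15, 16), c(exp(-0.01 * 164), 1))
  # an insensitive copy contributes 1 everywhere
  flat_cfg <- pathway_config(
    upstream = list(make_copy(10, 12, 0, 0)), downstream = list(make_copy(10, 12)),
    link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
  for (e in list(c(1, 1), c(7, 19), c(20, 20))) {
    expect_identical(upstream_activities(flat_cfg, e[1], e[2]), 1)
  }
})

test_that("wiring and pooling route upstream activities as defined", {
  two <- function(wiring, pooling) build_case(
    rep(list(list(u = c(10, 12, 0.01, 0.01), d = c(10, 12, 0.01, 0.01))), 2),
    delta = c(1, 2), gamma = c(1, 2), wiring = wiring, pooling = pooling)$cfg
  expect_equal(downstream_inputs(two("pooled", "sum"), c(1, 1)), c(2, 2))
  expect_equal(downstream_inputs(two("pooled", "mean"), c(1, 1)), c(1, 1))
  expect_equal(downstream_inputs(two("pooled", "mean"), c(0.7, 0.2)), c(0.45, 0.45))
  expect_equal(downstream_inputs(two("independent", "mean"), c(0.7, 0.2)), c(0.7, 0.2))
  expect_equal(downstream_inputs(two(list(c(1, 2), 2), "sum"), c(0.7, 0.2)), c(0.9, 0.2))
  expect_equal(downstream_inputs(two(list(c(1, 2), 2), "mean"), c(0.7, 0.2)), c(0.45, 0.2))
  expect_error(downstream_inputs(two("pooled", "mean"), c(1, 1, 1)),
               class = "pathsurf_value_error")
})

test_that("invalid architectures are rejected at construction", {
  up1 <- list(make_copy(10, 12))
  dn2 <- list(make_copy(10, 12), make_copy(5, 8))
  l <- sigmoid_link(1, 2)
  expect_error(pathway_config(up1, dn2, l, l, wiring = "independent"),
               class = "pathsurf_value_error")
  expect_error(pathway_config(up1, dn2, l, l, wiring = list(1, c(1, 5))),
               class = "pathsurf_value_error")
  expect_error(pathway_config(up1, dn2, l, l, wiring = list(1)),
               class = "pathsurf_value_error")
  expect_error(pathway_config(list(), dn2, l, l), class = "pathsurf_value_error")
  expect_error(pathway_config(up1, dn2, l, l, wiring = "ring"),
               class = "pathsurf_value_error")
})

test_that("downstream activity is the link output gated by the copy's weight", {
  cfg <- pathway_config(
    upstream = list(make_copy(10, 12)),
    downstream = list(make_copy(10, 12, 0, 0)),  # insensitive downstream
    link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
  # zero regulatory input leaves the link's baseline leakage
  expect_equal(downstream_activities(cfg, 0, 3, 17), 1 / (1 + exp(1)))
  # sensitive downstream copy at its optimum passes the link output through
  cfg2 <- pathway_config(
    upstream = list(make_copy(10, 12)), downstream = list(make_copy(10, 12)),
    link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
  expect_equal(downstream_activities(cfg2, 1, 10, 12), 1 / (1 + exp(-1)))
  # and the weight multiplies: far from the optimum the link output is scaled down
  expect_equal(downstream_activities(cfg2, 1, 1, 20),
               1 / (1 + exp(-1)) * exp(-0.01 * 81) * exp(-0.01 * 64))
})

test_that("the outcome probability equals the hand-chained composition", {
  # both tiers at (10, 12), two identical copies, normalized pooling:
  # per-copy input 1, delta output 1/(1+exp(-1)), two copies summed, gamma link
  cc <- build_case(rep(list(list(u = c(10, 12, 0.01, 0.01),
                                 d = c(10, 12, 0.01, 0.01))), 2),
                   delta = c(1, 2), gamma = c(1, 2))
  dsig <- 1 / (1 + exp(1 - 2 * 1))
  expect_equal(outcome_probability(cc$cfg, 10, 12), 1 / (1 + exp(1 - 2 * (2 * dsig))))
  # in the limit of vanishing environmental weight the surface floor remains
  far <- build_case(list(list(u = c(10, 12, 5, 5), d = c(10, 12, 5, 5))),
                    delta = c(1, 2), gamma = c(1, 2))
  expect_equal(outcome_probability(far$cfg, 20, 1), 1 / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(surface_floor(far$cfg), 1 / (1 + exp(1)))
})

test_that("vectorized surface evaluation matches the scalar chain everywhere", {
  cases <- list(
    build_case(fig5b_copies, c(5, 7), c(1, 2), wiring = "independent"),
    build_case(fig5b_copies, c(5, 7), c(1, 2), wiring = "pooled", pooling = "mean"),
    build_case(fig5b_copies, c(5, 7), c(1, 2), wiring = "pooled", pooling = "sum"),
    build_case(fig5b_copies, c(5, 7), c(1, 2), wiring = list(c(1, 2), 2))
  )
  for (cc in cases) {
    s <- evaluate_surface(cc$cfg)
    expect_equal(s$P, oracle_surface(cc$spec), tolerance = 1e-12)
    # spot-check the pointwise route through the package itself
    for (cell in list(c(5, 8), c(10, 12), c(1, 20), c(17, 3))) {
      expect_identical(s$P[cell[1], cell[2]],
                       outcome_probability(cc$cfg, cell[1], cell[2]))
    }
  }
})

test_that("random architectures agree between scalar oracle and surface", {
  set.seed(42)
  for (rep in 1:8) {
    cc <- random_case()
    g <- env_grid(seq(2, 18, by = 4), seq(1, 19, by = 3))
    s <- evaluate_surface(cc$cfg, g)
    expect_equal(s$P, oracle_surface(cc$spec, g$e1_values, g$e2_values),
                 tolerance = 1e-12)
    expect_true(all(s$P > 0 & s$P < 1))
    expect_true(all(s$U >= 0 & s$U <= 1))
    expect_true(all(s$D >= 0 & s$D <= 1))
  }
})

test_that("surface evaluation is deterministic and shaped by the grid", {
  cc <- build_case(fig5b_copies, c(5, 7), c(1, 2), wiring = "independent")
  a <- evaluate_surface(cc$cfg)
  b <- evaluate_surface(cc$cfg)
  expect_identical(a$P, b$P)
  expect_identical(dim(a$P), c(20L, 20L))
  expect_identical(dim(a$U), c(2L, 20L, 20L))
  g <- env_grid(seq(1, 20, by = 0.5), 1:20)
  expect_identical(dim(evaluate_surface(cc$cfg, g)$P), c(39L, 20L))
  expect_error(env_grid(c(3, 2, 1), 1:20), class = "pathsurf_value_error")
})

test_that("copy order is irrelevant under pooled wiring", {
  copies <- list(list(u = c(5, 8, 0.01, 0.01), d = c(12, 3, 0.02, 0.01)),
                 list(u = c(15, 16, 0.01, 0.02), d = c(4, 18, 0.01, 0.01)),
                 list(u = c(9, 2, 0, 0.01), d = c(19, 11, 0.01, 0)))
  a <- build_case(copies, c(2, 3), c(1, 2))$cfg
  b <- build_case(copies[c(3, 1, 2)], c(2, 3), c(1, 2))$cfg
  expect_equal(evaluate_surface(a)$P, evaluate_surface(b)$P)
})

test_that("raising one copy's activity never lowers the outcome under pooling", {
  # only copy 1 is e1-sensitive, so moving e1 toward its optimum raises U_1
  # while every other weight stays fixed
  copies <- list(list(u = c(10, 12, 0.01, 0.01), d = c(1, 12, 0, 0.01)),
                 list(u = c(15, 12, 0, 0.01), d = c(1, 12, 0, 0.01)))
  for (pooling in c("mean", "sum")) {
    cfg <- build_case(copies, c(1, 2), c(1, 2), pooling = pooling)$cfg
    p <- vapply(1:10, function(e1) outcome_probability(cfg, e1, 12), numeric(1))
    expect_true(all(diff(p) >= 0))
  }
})

test_that("a single matched pathway peaks exactly at the shared optimum", {
  for (opt in list(c(10, 12), c(4, 17), c(19, 2))) {
    cfg <- pathway_config(
      upstream = list(make_copy(opt[1], opt[2])),
      downstream = list(make_copy(opt[1], opt[2])),
      link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
    s <- evaluate_surface(cfg)
    am <- which(s$P == max(s$P), arr.ind = TRUE)
    expect_identical(nrow(am), 1L)
    expect_equal(c(s$grid$e1_values[am[1]], s$grid$e2_values[am[2]]), opt)
  }
})

test_that("insensitive pathways produce a constant surface", {
  cfg <- pathway_config(
    upstream = list(make_copy(10, 12, 0, 0), make_copy(3, 4, 0, 0)),
    downstream = list(make_copy(8, 8, 0, 0), make_copy(1, 19, 0, 0)),
    link_up_down = sigmoid_link(1, 2), link_down_outcome = sigmoid_link(1, 2))
  s <- evaluate_surface(cfg)
  expect_identical(max(s$P), min(s$P))
})
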