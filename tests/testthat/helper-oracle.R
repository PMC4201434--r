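# Independent oracles and small config builders shared across the tests.
#
# The oracle code deliberately avoids the package's vectorized machinery:
# plain scalar formulas, cell-by-cell loops, and igraph for plateau
# components, so that agreement with the package is a genuine dual-route
# check.

# scalar environmental response: exp(-rate (e - opt)^2), rate by side
oracle_response <- function(e, opt, rate_below, rate_above) {
  r <- if (e < opt) rate_below else rate_above
  exp(-r * (e - opt)^2)
}

# raw copy spec: list(u = c(o1, o2, r1, r2), d = c(o1, o2, r1, r2))
oracle_cell <- function(spec, e1, e2) {
  wt <- function(v) oracle_response(e1, v[1], v[3], v[3]) *
    oracle_response(e2, v[2], v[4], v[4])
  U <- vapply(spec$copies, function(cp) wt(cp$u), numeric(1))
  inputs <- if (identical(spec$wiring, "pooled")) {
    tot <- sum(U)
    if (spec$pooling == "mean") tot <- tot / length(U)
    rep(tot, length(spec$copies))
  } else if (identical(spec$wiring, "independent")) {
    U
  } else {
    vapply(spec$wiring, function(idx) {
      tot <- sum(U[idx])
      if (spec$pooling == "mean") tot / length(idx) else tot
    }, numeric(1))
  }
  D <- vapply(seq_along(spec$copies), function(j) {
    1 / (1 + exp(spec$delta[1] - spec$delta[2] * inputs[j])) * wt(spec$copies[[j]]$d)
  }, numeric(1))
  1 / (1 + exp(spec$gamma[1] - spec$gamma[2] * sum(D)))
}

oracle_surface <- function(spec, e1_values = 1:20, e2_values = 1:20) {
  M <- matrix(0, length(e1_values), length(e2_values))
  for (i in seq_along(e1_values)) for (j in seq_along(e2_values)) {
    M[i, j] <- oracle_cell(spec, e1_values[i], e2_values[j])
  }
  M
}

# exhaustive peak definition: candidates are cells >= all 8 neighbours;
# 8-connected equal-value candidates merge (igraph components) and report the
# lexicographically smallest member; peaks must exceed floor + prominence
oracle_peaks <- function(P, e1_values, e2_values, floor_value, min_prominence) {
  n1 <- nrow(P); n2 <- ncol(P)
  cand <- matrix(FALSE, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= n1 && nj >= 1 && nj <= n2 && P[ni, nj] > P[i, j]) ok <- FALSE
    }
    cand[i, j] <- ok
  }
  cells <- which(cand, arr.ind = TRUE)
  if (nrow(cells) == 0) return(data.frame(e1 = numeric(0), e2 = numeric(0), P = numeric(0)))
  id <- function(i, j) paste(i, j)
  edges <- character(0)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= n1 && nj >= 1 && nj <= n2 &&
          cand[ni, nj] && P[ni, nj] == P[i, j]) {
        edges <- c(edges, id(i, j), id(ni, nj))
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(apply(cells, 1, function(r) id(r[1], r[2])))
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(names(comp), comp), function(members) {
    ij <- do.call(rbind, lapply(strsplit(members, " "), as.integer))
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    c(ij[1, 1], ij[1, 2], P[ij[1, 1], ij[1, 2]])
  }))
  df <- data.frame(e1 = e1_values[out[, 1]], e2 = e2_values[out[, 2]], P = out[, 3])
  df <- df[df$P > floor_value + min_prominence, , drop = FALSE]
  df <- df[order(-df$P, df$e1, df$e2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# builders returning both a pathway_config and the matching raw oracle spec
make_copy <- function(o1, o2, r1 = 0.01, r2 = 0.01) {
  gene_copy(env_sensitivity(o1, r1), env_sensitivity(o2, r2))
}

build_case <- function(copies, delta, gamma, wiring = "pooled", pooling = "mean") {
  cfg <- pathway_config(
    upstream = lapply(copies, function(cp) make_copy(cp$u[1], cp$u[2], cp$u[3], cp$u[4])),
    downstream = lapply(copies, function(cp) make_copy(cp$d[1], cp$d[2], cp$d[3], cp$d[4])),
    link_up_down = sigmoid_link(delta[1], delta[2]),
    link_down_outcome = sigmoid_link(gamma[1], gamma[2]),
    wiring = wiring, pooling = pooling)
  spec <- list(copies = copies, delta = delta, gamma = gamma,
               wiring = wiring, pooling = pooling)
  list(cfg = cfg, spec = spec)
}

random_case <- function() {
  n <- sample(1:3, 1)
  copies <- lapply(seq_len(n), function(i) {
    list(u = c(sample(1:20, 1), sample(1:20, 1), sample(c(0, 0.005, 0.01, 0.02), 1),
               sample(c(0, 0.005, 0.01, 0.02), 1)),
         d = c(sample(1:20, 1), sample(1:20, 1), sample(c(0, 0.005, 0.01, 0.02), 1),
               sample(c(0, 0.005, 0.01, 0.02), 1)))
  })
  wiring <- sample(c("pooled", "independent"), 1)
  build_case(copies, delta = c(runif(1, 0, 5), runif(1, 0.5, 7)),
             gamma = c(runif(1, 0, 5), runif(1, 0.5, 7)),
             wiring = wiring, pooling = sample(c("mean", "sum"), 1))
}
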