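test_that("proportional thresholding keeps the top-k weights with lexical ties", {
  w4 <- matrix(0, 4, 4)
  w4[upper.tri(w4)] <- c(6, 5, 4, 3, 2, 1) / 10
  w4 <- w4 + t(w4)
  g <- proportional_threshold(w4, 0.5)
  expect_equal(g$m, 3)
  kept <- which(upper.tri(w4) & g$adj == 1)
  expect_setequal(w4[kept], c(0.6, 0.5, 0.4))
  # all-equal weights: first three upper-triangle positions in lexical order
  we <- matrix(0.5, 4, 4); diag(we) <- 0
  ge <- proportional_threshold(we, 0.5)
  expect_equal(ge$adj[1, 2:4], c(1, 1, 1))
  expect_equal(sum(ge$adj[2:4, 2:4]), 0)
  # random matrix vs an independent full-sort oracle
  set.seed(1)
  w <- rand_weights(20)
  g20 <- proportional_threshold(w, 0.1)
  k <- round(0.1 * 20 * 19 / 2)
  ut <- which(upper.tri(w))
  oracle <- sort(ut[order(w[ut], decreasing = TRUE)][seq_len(k)])
  expect_equal(which(upper.tri(w) & g20$adj == 1), oracle)
  # zero weights are never kept
  wz <- matrix(0, 6, 6); wz[1, 2] <- wz[2, 1] <- 1
  expect_warning(gz <- proportional_threshold(wz, 0.3), "positive weights")
  expect_equal(gz$m, 1)
  expect_error(proportional_threshold(w, 1.2), "cost")
  expect_error(proportional_threshold(matrix(1, 2, 2) - diag(2), 1e-4),
               "no edges")
})

test_that("degree, clustering, distances and eccentricity match closed forms", {
  path3 <- binary_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(graph_degree(path3), c(1L, 2L, 1L))
  expect_equal(graph_distances(path3)[1, 3], 2)
  k5 <- binary_graph(matrix(1, 5, 5) - diag(5))
  expect_equal(graph_degree(k5), rep(4L, 5))
  tri <- binary_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(graph_clustering(tri), rep(1, 3))
  star <- binary_graph(rbind(c(0, 1, 1, 1, 1), cbind(1, matrix(0, 4, 4))))
  expect_equal(graph_clustering(star), rep(0, 5))
  path4 <- binary_graph(stats::toeplitz(c(0, 1, 0, 0)))
  expect_equal(as.numeric(graph_eccentricity(path4)), c(3, 2, 2, 3))
  k6 <- binary_graph(matrix(1, 6, 6) - diag(6))
  expect_equal(as.numeric(graph_eccentricity(k6)), rep(1, 6))
  # disconnected: cross-component distances infinite, within-component ecc
  two_edges <- matrix(0, 4, 4); two_edges[1, 2] <- two_edges[3, 4] <- 1
  g2 <- binary_graph(two_edges + t(two_edges))
  expect_true(is.infinite(graph_distances(g2)[1, 3]))
  expect_equal(as.numeric(graph_eccentricity(g2)), rep(1, 4))
  expect_error(graph_eccentricity(g2, on_disconnected = "error"), "disconnected")
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- 1; two_tri[4:6, 4:6] <- 1; diag(two_tri) <- 0
  expect_equal(as.numeric(graph_eccentricity(binary_graph(two_tri))), rep(1, 6))
})

test_that("metrics agree with the igraph oracle on random graphs", {
  set.seed(2)
  for (rep in 1:20) {
    g <- rand_graph(sample(10:30, 1), stats::runif(1, 0.15, 0.5))
    ig <- as_igraph(g)
    expect_identical(graph_degree(g), as.integer(igraph::degree(ig)))
    cc_ref <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    cc_ref[igraph::degree(ig) < 2] <- 0
    expect_equal(graph_clustering(g), cc_ref, tolerance = 1e-10)
    d_ref <- igraph::distances(ig)
    expect_equal(graph_distances(g), unname(d_ref))
    expect_equal(global_efficiency(g), igraph::global_efficiency(ig),
                 tolerance = 1e-10)
    expect_equal(local_efficiency(g), local_efficiency_oracle(g),
                 tolerance = 1e-10)
  }
})

test_that("efficiency has the expected closed forms", {
  k7 <- binary_graph(matrix(1, 7, 7) - diag(7))
  expect_equal(global_efficiency(k7), 1)
  expect_equal(local_efficiency(k7), 1)
  path3 <- binary_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3, tolerance = 1e-12)
})

test_that("rewiring preserves degrees and moves efficiency the right way", {
  set.seed(3)
  for (rep in 1:5) {
    g <- rand_graph(25, 0.25)
    gr <- rewire_random(g, iter = 20, seed = rep)
    gl <- rewire_lattice(g, iter = 20, seed = rep)
    expect_identical(graph_degree(gr), graph_degree(g))
    expect_identical(graph_degree(gl), graph_degree(g))
    expect_equal(gr$m, g$m)
    # lattice rewiring never increases the diagonal-span cost
    expect_lte(connsweep:::edge_span(gl), connsweep:::edge_span(g))
  }
  # randomizing a ring lattice raises global efficiency, every seed
  ring <- ring_lattice(30, 2)
  e_ring <- global_efficiency(ring)
  e_rew <- vapply(1:20, function(s) {
    global_efficiency(rewire_random(ring, iter = 20, seed = s))
  }, numeric(1))
  expect_true(all(e_rew > e_ring))
  # determinism under a fixed seed, and sparse graphs return a copy
  expect_identical(rewire_random(ring, iter = 5, seed = 9)$adj,
                   rewire_random(ring, iter = 5, seed = 9)$adj)
  lone <- binary_graph(rbind(c(0, 1), c(1, 0)))
  expect_warning(same <- rewire_random(lone, seed = 1), "too sparse")
  expect_identical(same$adj, lone$adj)
})

test_that("realized densities stay within one edge of the rounding rule", {
  set.seed(4)
  w <- rand_weights(40)
  for (cost in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
    g <- proportional_threshold(w, cost)
    expect_lte(abs(g$m - round(cost * 40 * 39 / 2)), 1)
  }
})

test_that("small-world regime detection finds strict sandwich runs", {
  grid <- seq(0.1, 0.5, by = 0.1)
  real <- list(e_glob = c(1, 2, 3, 2, 1), e_loc = c(3, 3, 3, 1, 1))
  random <- list(e_glob = c(2, 3, 4, 3, 2), e_loc = c(1, 1, 1, 2, 2))
  lattice <- list(e_glob = c(0, 1, 2, 1, 0), e_loc = c(4, 4, 4, 0, 0))
  sw <- small_world_regime(real, random, lattice, grid)
  expect_equal(sw$interval, c(0.1, 0.3))
  expect_equal(sw$indices, 1:3)
  # strictness: identical curves yield an empty interval
  sw0 <- small_world_regime(random, random, lattice, grid)
  expect_equal(sw0$interval, numeric(0))
  # a single qualifying cost yields a width-one interval
  real1 <- list(e_glob = c(1, 3, 1, 1, 1), e_loc = c(0.2, 2, 0.2, 0.2, 0.2))
  random1 <- list(e_glob = rep(4, 5), e_loc = rep(0.5, 5))
  lattice1 <- list(e_glob = rep(0, 5), e_loc = rep(4, 5))
  sw1 <- small_world_regime(real1, random1, lattice1, grid)
  expect_equal(sw1$interval, c(0.2, 0.2))
  expect_error(small_world_regime(real, random, lattice, grid[-1]), "grid")
})

test_that("AUC integrates curves over the cost range", {
  grid <- cost_grid_main()
  expect_length(grid, 27L)
  expect_equal(auc_over_costs(rep(1, 27), grid), 0.26, tolerance = 1e-12)
  expect_equal(auc_over_costs(grid, grid), (0.30^2 - 0.04^2) / 2,
               tolerance = 1e-12)
  set.seed(5)
  v <- stats::rnorm(27)
  oracle <- 0
  for (i in 1:26) oracle <- oracle + (grid[i + 1] - grid[i]) * (v[i] + v[i + 1]) / 2
  expect_equal(auc_over_costs(v, grid), oracle, tolerance = 1e-12)
  expect_error(auc_over_costs(v[-1], grid), "one value per")
  expect_length(cost_grid_efficiency(), 30L)
})

test_that("random-graph normalization is an elementwise ratio", {
  v <- c(1, 2, 3); r <- c(1, 2, 3)
  expect_equal(normalize_to_random(v, r), c(1, 1, 1))
  expect_equal(normalize_to_random(2 * v, r), 2 * normalize_to_random(v, r))
  expect_warning(out <- normalize_to_random(v, c(1, 0, 3)), "undefined")
  expect_true(is.nan(out[2]))
  set.seed(6)
  a <- stats::runif(27); b <- stats::runif(27, 0.5, 1)
  expect_equal(auc_over_costs(normalize_to_random(a, b)),
               auc_over_costs(a / b), tolerance = 1e-12)
})
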