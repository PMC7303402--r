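# shared fixture builders (all generated in code, fixed seeds per test site)

# symmetric nonnegative random weight matrix, zero diagonal
rand_weights <- function(n, max_w = 1) {
  w <- matrix(stats::runif(n * n, 0, max_w), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# Erdos-Renyi binary graph as a connsweep_graph
rand_graph <- function(n, p) {
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- stats::rbinom(length(ut), 1, p)
  a <- a + t(a)
  binary_graph(a)
}

# ring lattice: each node connected to its k nearest neighbors per side
ring_lattice <- function(n, k) {
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  d <- pmin(d, n - d)
  binary_graph((d >= 1 & d <= k) * 1)
}

# modular ring weight matrix: ring neighborhoods plus module blocks;
# thresholds into small-world graphs at intermediate costs
modular_ring_weights <- function(n = 60, modules = 6) {
  w <- matrix(stats::runif(n * n, 0, 0.05), n)
  idx <- seq_len(n)
  ringd <- pmin(abs(outer(idx, idx, "-")), n - abs(outer(idx, idx, "-")))
  w <- w + (ringd <= 3) * 0.6 * (1 - ringd / 8)
  mod <- rep(seq_len(modules), each = n / modules)
  w <- w + outer(mod, mod, "==") * 0.25
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# tiny atlas for unit tests that do not need 160 nodes
tiny_atlas <- function(per_network = 3L) {
  nets <- atlas_networks()
  make_atlas(data.frame(
    x = seq_len(per_network * length(nets)), y = 0, z = 0,
    label = "node",
    network = rep(nets, each = per_network)
  ))
}

# igraph oracle from a connsweep_graph
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
}

# brute-force local-efficiency oracle: mean over nodes of the global
# efficiency of the neighbor-induced subgraph (igraph used only for the
# subgraph distances; igraph's own local_efficiency() follows a different,
# remove-the-vertex convention)
local_efficiency_oracle <- function(g) {
  a <- g$adj
  vals <- vapply(seq_len(g$n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2L) return(0)
    sub <- igraph::graph_from_adjacency_matrix(a[nb, nb], mode = "undirected")
    d <- igraph::distances(sub)
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  mean(vals)
}
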