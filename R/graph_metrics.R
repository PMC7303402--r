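#' Binary graph metrics over a proportional-threshold cost sweep
#'
#' Adjacency matrices are binarized by keeping the top fraction ("cost") of
#' weighted links, per cost in a fixed grid; degree centrality, clustering
#' coefficient and eccentricity are computed per node and per cost, then
#' summarized as area under the curve (AUC) over the cost range.  Degree-
#' preserving random and lattice rewiring provide null models for
#' small-world regime detection via global/local efficiency.
#'
#' @name graph_metrics
NULL

#' Cost grids
#'
#' The main grid (27 costs, 0.04 to 0.30 in steps of 0.01) is used for the
#' metric sweep and AUC; the efficiency grid (30 costs, 0.01 to 0.59 in
#' steps of 0.02) is used for small-world screening.
#'
#' @return Numeric vector of costs.
#' @export
cost_grid_main <- function() seq(0.04, 0.30, by = 0.01)

#' @rdname cost_grid_main
#' @export
cost_grid_efficiency <- function() seq(0.01, 0.59, by = 0.02)

#' Construct a binary graph object
#'
#' @param adj Symmetric 0/1 matrix (self-loops ignored).
#' @return Object of class `connsweep_graph`: list with `n`, `adj`
#'   (numeric 0/1 matrix, zero diagonal) and `m` (edge count).
#' @export
binary_graph <- function(adj) {
  a <- (as.matrix(adj) != 0) * 1
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  diag(a) <- 0
  structure(list(n = nrow(a), adj = a, m = sum(a) / 2),
            class = "connsweep_graph")
}

#' @export
print.connsweep_graph <- function(x, ...) {
  cat(sprintf("connsweep graph: %d nodes, %d edges (density %.3f)\n",
              x$n, x$m, x$m / (x$n * (x$n - 1) / 2)))
  invisible(x)
}

#' Proportional (density) thresholding
#'
#' Keeps the `k = round(cost * n * (n-1) / 2)` largest off-diagonal
#' upper-triangle weights as binary edges.  Ties are broken by (row,
#' column) lexical order so the result is deterministic.  Zero-weight
#' entries are never kept, even if `k` demands it (a warning reports the
#' shortfall).
#'
#' @param adjacency Symmetric nonnegative weight matrix.
#' @param cost Target density in (0, 1).
#' @return A `connsweep_graph`.
#' @export
proportional_threshold <- function(adjacency, cost) {
  w <- as.matrix(adjacency)
  n <- nrow(w)
  if (!is.finite(cost) || cost <= 0 || cost >= 1) stop("cost must be in (0, 1)")
  k <- round(cost * n * (n - 1) / 2)
  if (k == 0L) stop("cost too small: no edges would be kept")
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[ut]
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(min(k, length(ord)))]
  keep <- keep[vals[keep] > 0]
  if (length(keep) < k) {
    warning(sprintf("only %d positive weights available for %d requested edges",
                    length(keep), k))
  }
  a <- matrix(0, n, n)
  a[ut[keep, , drop = FALSE]] <- 1
  a <- a + t(a)
  binary_graph(a)
}

#' Degree centrality
#'
#' @param g A `connsweep_graph`.
#' @return Integer vector: number of edges attaching each node.
#' @export
graph_degree <- function(g) as.integer(rowSums(g$adj))

#' Clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected
#' (triangles over possible pairs); nodes with degree < 2 get 0.
#'
#' @param g A `connsweep_graph`.
#' @return Numeric vector in `[0, 1]`.
#' @export
graph_clustering <- function(g) {
  a <- g$adj
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)  # 2 * triangles per node
  cc <- ifelse(k < 2, 0, tri2 / (k * (k - 1)))
  as.numeric(cc)
}

#' All-pairs shortest hop counts
#'
#' Breadth-first hop distances via iterated reachability expansion;
#' unreachable pairs are `Inf`, the diagonal 0.
#'
#' @param g A `connsweep_graph`.
#' @return n x n symmetric numeric matrix.
#' @export
graph_distances <- function(g) {
  a <- g$adj
  n <- g$n
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  step <- 0L
  repeat {
    step <- step + 1L
    nxt <- (reach %*% a) > 0 | reach
    new <- nxt & !reach
    if (!any(new)) break
    d[new] <- step
    reach <- nxt
  }
  d
}

#' Eccentricity
#'
#' Maximum shortest-path hop distance from each node to any node it can
#' reach (within-component convention, so disconnected graphs still yield
#' finite values).  Isolated nodes get 0 and are flagged in the attribute
#' `isolated`.  Set `on_disconnected = "error"` to refuse disconnected
#' graphs instead.
#'
#' @param g A `connsweep_graph`.
#' @param on_disconnected `"finite"` (default) or `"error"`.
#' @return Numeric vector of hop counts.
#' @export
graph_eccentricity <- function(g, on_disconnected = c("finite", "error")) {
  on_disconnected <- match.arg(on_disconnected)
  d <- graph_distances(g)
  if (on_disconnected == "error" && any(is.infinite(d))) {
    stop("graph is disconnected: eccentricity undefined")
  }
  ecc <- apply(d, 1L, function(row) {
    fin <- row[is.finite(row)]
    if (length(fin) <= 1L) 0 else max(fin)
  })
  isolated <- rowSums(g$adj) == 0
  ecc[isolated] <- 0
  structure(as.numeric(ecc), isolated = which(isolated))
}

#' Global and local efficiency
#'
#' Global efficiency is the mean of inverse hop distances over all ordered
#' node pairs (unreachable pairs contribute 0).  Local efficiency is the
#' mean over nodes of the global efficiency of each node's neighbor-induced
#' subgraph (degree < 2 contributes 0).
#'
#' @param g A `connsweep_graph`.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  if (g$n < 2L) return(0)
  d <- graph_distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (g$n * (g$n - 1))
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(g) {
  a <- g$adj
  vals <- vapply(seq_len(g$n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(binary_graph(a[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

# shared double-edge-swap machinery; criterion: NULL for unconstrained
# random rewiring, or a function(a,b,c,d) returning TRUE to accept
rewire_swaps <- function(g, iter, seed, lattice = FALSE) {
  if (g$m < 2) {
    warning("graph too sparse to rewire; returning a copy")
    return(g)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  a <- g$adj
  ut <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  ei <- ut[, 1L]
  ej <- ut[, 2L]
  m <- length(ei)
  attempts <- ceiling(iter * m)
  pick <- sample.int(m, 2L * attempts, replace = TRUE)
  flip <- stats::runif(attempts) > 0.5
  for (s in seq_len(attempts)) {
    e1 <- pick[2L * s - 1L]
    e2 <- pick[2L * s]
    if (e1 == e2) next
    a1 <- ei[e1]; b1 <- ej[e1]
    c1 <- ei[e2]; d1 <- ej[e2]
    if (flip[s]) { tmp <- c1; c1 <- d1; d1 <- tmp }
    # proposed new edges: (a1,d1) and (c1,b1)
    if (a1 == d1 || a1 == c1 || b1 == d1 || b1 == c1) next
    if (a[a1, d1] > 0 || a[c1, b1] > 0) next
    if (lattice) {
      old_span <- abs(a1 - b1) + abs(c1 - d1)
      new_span <- abs(a1 - d1) + abs(c1 - b1)
      if (new_span >= old_span) next
    }
    a[a1, b1] <- 0; a[b1, a1] <- 0
    a[c1, d1] <- 0; a[d1, c1] <- 0
    a[a1, d1] <- 1; a[d1, a1] <- 1
    a[c1, b1] <- 1; a[b1, c1] <- 1
    ei[e1] <- min(a1, d1); ej[e1] <- max(a1, d1)
    ei[e2] <- min(c1, b1); ej[e2] <- max(c1, b1)
  }
  binary_graph(a)
}

#' Degree-preserving rewiring null models
#'
#' `rewire_random()` applies connected double-edge swaps (approximately
#' `iter` attempts per edge), destroying topology while preserving every
#' node's degree exactly.  `rewire_lattice()` accepts a swap only when it
#' strictly reduces the total `|i - j|` edge span, driving edges toward the
#' matrix diagonal (a lattice-like configuration) under the same degree
#' constraint.
#'
#' @param g A `connsweep_graph`.
#' @param iter Rewiring parameter: attempted swaps per edge (default 100).
#' @param seed Optional integer; when given, rewiring is deterministic and
#'   the caller's RNG state is restored afterwards.
#' @return A rewired `connsweep_graph` with the same degree sequence.
#' @export
rewire_random <- function(g, iter = 100, seed = NULL) {
  rewire_swaps(g, iter, seed, lattice = FALSE)
}

#' @rdname rewire_random
#' @export
rewire_lattice <- function(g, iter = 100, seed = NULL) {
  rewire_swaps(g, iter, seed, lattice = TRUE)
}

# total |i-j| edge span (lattice cost)
edge_span <- function(g) {
  ut <- which(upper.tri(g$adj) & g$adj > 0, arr.ind = TRUE)
  sum(abs(ut[, 1L] - ut[, 2L]))
}

#' Efficiency curves over a cost grid
#'
#' Thresholds a weight matrix at every cost of the grid and computes global
#' and local efficiency of the real graph and, on request, of its random
#' and lattice rewired nulls.
#'
#' @param adjacency Symmetric nonnegative weight matrix.
#' @param grid Cost grid (default [cost_grid_efficiency()]).
#' @param nulls Compute rewired null curves too (default TRUE).
#' @param iter Rewiring parameter (default 100).
#' @param seed Seed for the rewiring.
#' @return List of curves (`real`, and with `nulls`, `random`, `lattice`),
#'   each a list with numeric `e_glob` and `e_loc` of `length(grid)`.
#' @export
efficiency_curves <- function(adjacency, grid = cost_grid_efficiency(),
                              nulls = TRUE, iter = 100, seed = NULL) {
  res <- list(real = list(e_glob = numeric(0), e_loc = numeric(0)))
  if (nulls) {
    res$random <- list(e_glob = numeric(0), e_loc = numeric(0))
    res$lattice <- list(e_glob = numeric(0), e_loc = numeric(0))
  }
  for (i in seq_along(grid)) {
    g <- proportional_threshold(adjacency, grid[i])
    res$real$e_glob[i] <- global_efficiency(g)
    res$real$e_loc[i] <- local_efficiency(g)
    if (nulls) {
      sd_i <- if (is.null(seed)) NULL else seed + i
      gr <- rewire_random(g, iter = iter, seed = sd_i)
      gl <- rewire_lattice(g, iter = iter,
                           seed = if (is.null(sd_i)) NULL else sd_i + 10000L)
      res$random$e_glob[i] <- global_efficiency(gr)
      res$random$e_loc[i] <- local_efficiency(gr)
      res$lattice$e_glob[i] <- global_efficiency(gl)
      res$lattice$e_loc[i] <- local_efficiency(gl)
    }
  }
  res
}

#' Small-world regime detection
#'
#' The longest contiguous run of costs where the real graph's global
#' efficiency lies strictly between the lattice and random nulls
#' (`E_lat < E_real < E_rand`) and its local efficiency strictly between
#' the random and lattice nulls (`E_rand < E_real < E_lat`).
#'
#' @param real,random,lattice Curves: lists with `e_glob` and `e_loc`
#'   vectors on the same grid.
#' @param grid The cost grid the curves were evaluated on.
#' @return List with `interval` (`c(low, high)` costs, or `numeric(0)` when
#'   empty) and `indices` (grid positions of the run).
#' @export
small_world_regime <- function(real, random, lattice, grid) {
  lens <- vapply(list(real$e_glob, real$e_loc, random$e_glob, random$e_loc,
                      lattice$e_glob, lattice$e_loc), length, integer(1))
  if (any(lens != length(grid))) stop("curve lengths must match the cost grid")
  ok <- lattice$e_glob < real$e_glob & real$e_glob < random$e_glob &
    random$e_loc < real$e_loc & real$e_loc < lattice$e_loc
  if (!any(ok)) return(list(interval = numeric(0), indices = integer(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- seq(starts[best], ends[best])
  list(interval = c(grid[idx[1L]], grid[idx[length(idx)]]), indices = idx)
}

#' Area under a metric-vs-cost curve
#'
#' Trapezoidal integral of one value per grid cost over the grid range
#' (so a constant curve c integrates to `c * (max(grid) - min(grid))`).
#'
#' @param values Numeric vector, one finite value per grid cost.
#' @param grid Strictly increasing cost grid.
#' @return Scalar AUC in measure-units times cost.
#' @export
auc_over_costs <- function(values, grid = cost_grid_main()) {
  if (length(values) != length(grid)) {
    stop("need exactly one value per grid cost")
  }
  if (anyNA(values)) stop("missing value in metric curve")
  sum(diff(grid) * (utils::head(values, -1L) + utils::tail(values, -1L)) / 2)
}

#' Normalize metric curves to a random-graph reference
#'
#' Elementwise ratio real/random per cost (applied before AUC).  Costs with
#' a zero random value yield `NaN` and a warning.
#'
#' @param values,random_values Numeric vectors on matched grids.
#' @return Numeric vector of ratios.
#' @export
normalize_to_random <- function(values, random_values) {
  if (length(values) != length(random_values)) stop("grids must match")
  if (any(random_values == 0)) {
    warning("zero random-graph value: ratio undefined at some cost(s)")
  }
  out <- values / random_values
  out[random_values == 0] <- NaN
  out
}

#' Node metric curves over the main cost grid
#'
#' For each cost, thresholds the adjacency and computes per-node degree
#' centrality (dc), clustering coefficient (cc) and eccentricity (ecc).
#'
#' @param adjacency Symmetric nonnegative weight matrix.
#' @param grid Cost grid (default [cost_grid_main()]).
#' @return List with `grid` and n x length(grid) matrices `dc`, `cc`, `ecc`.
#' @export
node_metric_curves <- function(adjacency, grid = cost_grid_main()) {
  n <- nrow(adjacency)
  dc <- cc <- ecc <- matrix(NA_real_, n, length(grid))
  for (i in seq_along(grid)) {
    g <- proportional_threshold(adjacency, grid[i])
    dc[, i] <- graph_degree(g)
    cc[, i] <- graph_clustering(g)
    ecc[, i] <- as.numeric(graph_eccentricity(g))
  }
  list(grid = grid, dc = dc, cc = cc, ecc = ecc)
}

#' Per-node AUC table
#'
#' @param curves Output of [node_metric_curves()].
#' @return data.frame with `node` (0-based), `auc_dc`, `auc_cc`, `auc_ecc`.
#' @export
auc_table <- function(curves) {
  n <- nrow(curves$dc)
  data.frame(
    node = seq_len(n) - 1L,
    auc_dc = apply(curves$dc, 1L, auc_over_costs, grid = curves$grid),
    auc_cc = apply(curves$cc, 1L, auc_over_costs, grid = curves$grid),
    auc_ecc = apply(curves$ecc, 1L, auc_over_costs, grid = curves$grid)
  )
}
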