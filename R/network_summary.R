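#' Six-network summaries, condition deltas and connectivity decomposition
#'
#' Node-level AUC values are averaged (unweighted) within each of the six
#' functional networks, giving 6 networks x 3 measures = 18 summary values
#' per condition (36 per participant across motion and static).  Condition
#' deltas are motion minus static.  The decomposition splits a focal
#' network's connectivity into within-network, sensorimotor<->cerebellar,
#' and rest-of-brain partitions, each thresholded at its own admissible-pair
#' density.
#'
#' @name network_summary
NULL

#' Network mean AUC summary (one condition)
#'
#' @param auc data.frame from [auc_table()] covering every atlas node.
#' @param atlas A `connsweep_atlas`.
#' @return data.frame with `network`, `auc_dc`, `auc_cc`, `auc_ecc` (one row
#'   per network, 18 values total).
#' @export
network_means <- function(auc, atlas) {
  if (nrow(auc) != nrow(atlas)) stop("AUC table does not cover the atlas")
  nets <- atlas_networks()
  out <- data.frame(network = nets, auc_dc = NA_real_,
                    auc_cc = NA_real_, auc_ecc = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(nets)) {
    idx <- network_nodes(atlas, nets[i])
    out$auc_dc[i] <- mean(auc$auc_dc[idx])
    out$auc_cc[i] <- mean(auc$auc_cc[idx])
    out$auc_ecc[i] <- mean(auc$auc_ecc[idx])
  }
  out
}

#' Condition delta of network summaries
#'
#' Motion minus static per network and measure; positive means higher
#' during visual motion.
#'
#' @param motion,static Network summary data.frames from [network_means()]
#'   for the same participant.
#' @param participant_motion,participant_static Optional participant ids;
#'   when both are given they must match.
#' @return data.frame with `network`, `delta_dc`, `delta_cc`, `delta_ecc`.
#' @export
condition_delta <- function(motion, static,
                            participant_motion = NULL,
                            participant_static = NULL) {
  if (!is.null(participant_motion) && !is.null(participant_static) &&
      !identical(participant_motion, participant_static)) {
    stop("condition summaries belong to different participants")
  }
  if (!identical(motion$network, static$network)) {
    stop("network rows do not align between conditions")
  }
  data.frame(
    network = motion$network,
    delta_dc = motion$auc_dc - static$auc_dc,
    delta_cc = motion$auc_cc - static$auc_cc,
    delta_ecc = motion$auc_ecc - static$auc_ecc,
    stringsAsFactors = FALSE
  )
}

# admissible node-pair index sets for a decomposition partition
decomposition_pairs <- function(atlas, focal, partition) {
  focal <- match.arg(focal, c("sensorimotor", "cerebellum"))
  partition <- match.arg(partition, c("within", "pair", "rest"))
  f_idx <- network_nodes(atlas, focal)
  other <- setdiff(c("sensorimotor", "cerebellum"), focal)
  switch(partition,
    within = list(rows = f_idx, cols = f_idx, square = TRUE),
    pair = list(rows = f_idx, cols = network_nodes(atlas, other),
                square = FALSE),
    rest = list(rows = f_idx,
                cols = which(!atlas$network %in%
                               c("sensorimotor", "cerebellum")),
                square = FALSE)
  )
}

#' Focal-network degree on a reduced adjacency block
#'
#' Reduces the weighted adjacency to one partition of a focal network's
#' connectivity (`within` the focal network, the sensorimotor-cerebellar
#' `pair` block, or the `rest` of the brain), proportionally thresholds the
#' reduced block at each cost — keeping `round(cost * n_admissible_pairs)`
#' entries, the natural density extension for rectangular blocks — counts
#' retained edges per focal node, and integrates over the cost grid.
#'
#' @param adjacency Full weighted adjacency matrix.
#' @param atlas A `connsweep_atlas` covering its nodes.
#' @param focal `"sensorimotor"` or `"cerebellum"`.
#' @param partition `"within"`, `"pair"` or `"rest"`.
#' @param grid Cost grid (default [cost_grid_main()]).
#' @return data.frame with `node` (0-based atlas id of each focal node) and
#'   `auc_dc` of the partition-restricted degree.
#' @export
submatrix_degree <- function(adjacency, atlas, focal, partition,
                             grid = cost_grid_main()) {
  pp <- decomposition_pairs(atlas, focal, partition)
  w <- as.matrix(adjacency)[pp$rows, pp$cols, drop = FALSE]
  n1 <- nrow(w); n2 <- ncol(w)
  dc <- matrix(NA_real_, n1, length(grid))
  if (pp$square) {
    vals_idx <- which(upper.tri(w), arr.ind = TRUE)
    n_pairs <- n1 * (n1 - 1) / 2
  } else {
    vals_idx <- as.matrix(expand.grid(row = seq_len(n1), col = seq_len(n2)))
    n_pairs <- n1 * n2
  }
  vals <- w[vals_idx]
  ord <- order(-vals, vals_idx[, 1L], vals_idx[, 2L])
  warned <- FALSE
  for (ci in seq_along(grid)) {
    k <- round(grid[ci] * n_pairs)
    keep <- ord[seq_len(min(k, length(ord)))]
    keep <- keep[vals[keep] > 0]
    if (length(keep) < k && !warned) {
      warning(sprintf("only %d positive weights available for %d requested edges",
                      length(keep), k))
      warned <- TRUE
    }
    cnt <- tabulate(vals_idx[keep, 1L], nbins = n1)
    if (pp$square) cnt <- cnt + tabulate(vals_idx[keep, 2L], nbins = n1)
    dc[, ci] <- cnt
  }
  data.frame(
    node = atlas$node_id[pp$rows],
    auc_dc = apply(dc, 1L, auc_over_costs, grid = grid)
  )
}

#' Connectivity decomposition table for a focal network
#'
#' Mean partition-restricted degree AUC over the focal network's nodes, for
#' all three partitions.
#'
#' @inheritParams submatrix_degree
#' @return data.frame with `partition` and `mean_auc_dc` (3 rows).
#' @export
decompose_connectivity <- function(adjacency, atlas, focal,
                                   grid = cost_grid_main()) {
  parts <- c("within", "pair", "rest")
  data.frame(
    partition = parts,
    mean_auc_dc = vapply(parts, function(p) {
      mean(submatrix_degree(adjacency, atlas, focal, p, grid)$auc_dc)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
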