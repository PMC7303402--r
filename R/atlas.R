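#' Functional atlas handling
#'
#' The analysis frame is a 160-node functional atlas in which every node
#' carries MNI coordinates, an anatomical label and exactly one of six
#' functional network assignments: cingulo-opercular, fronto-parietal,
#' default-mode, sensorimotor, occipital, cerebellum.  All network-level
#' aggregation in the package is defined relative to this frame.
#'
#' @name atlas
NULL

#' Valid functional network labels
#'
#' @return Character vector of the six admissible network names.
#' @export
atlas_networks <- function() {
  c("cingulo-opercular", "fronto-parietal", "default-mode",
    "sensorimotor", "occipital", "cerebellum")
}

#' Construct an atlas object from a node table
#'
#' Mainly used internally and by tests; most users will call [load_atlas()]
#' on a TSV file or [default_atlas()] for the packaged 160-node fixture.
#'
#' @param nodes data.frame with columns `x`, `y`, `z` (MNI mm), `label`
#'   (anatomical text) and `network` (one of [atlas_networks()]).
#' @param expected_nodes integer or NULL; if non-NULL the node count must
#'   match exactly.
#' @return An object of class `connsweep_atlas`: the node data.frame with a
#'   0-based `node_id` column prepended, row order preserved as node order.
#' @export
make_atlas <- function(nodes, expected_nodes = NULL) {
  required <- c("x", "y", "z", "label", "network")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("atlas table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (cc in c("x", "y", "z")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(nodes[[cc]]))))
    if (length(bad) > 0L) {
      stop(sprintf("atlas: non-numeric %s coordinate at line %d", cc, bad[1L] + 1L))
    }
    nodes[[cc]] <- as.numeric(nodes[[cc]])
  }
  unknown <- which(!nodes$network %in% atlas_networks())
  if (length(unknown) > 0L) {
    stop(sprintf(
      "atlas: unknown network label '%s' at line %d; valid networks: %s",
      nodes$network[unknown[1L]], unknown[1L] + 1L,
      paste(atlas_networks(), collapse = ", ")
    ))
  }
  if (!is.null(expected_nodes) && nrow(nodes) != expected_nodes) {
    stop(sprintf("atlas: expected %d nodes, found %d", expected_nodes, nrow(nodes)))
  }
  out <- data.frame(
    node_id = seq_len(nrow(nodes)) - 1L,
    x = nodes$x, y = nodes$y, z = nodes$z,
    label = as.character(nodes$label),
    network = as.character(nodes$network),
    stringsAsFactors = FALSE
  )
  class(out) <- c("connsweep_atlas", "data.frame")
  out
}

#' Load an atlas from a tab-separated node table
#'
#' The file must be a UTF-8 TSV with a header line and columns
#' `x`, `y`, `z`, `label`, `network`.  Row order is preserved as node order
#' (node ids are 0-based row indices).
#'
#' @param path Path to the TSV file.
#' @param expected_nodes Required node count (default 160; set NULL to skip).
#' @return A `connsweep_atlas` object.
#' @export
load_atlas <- function(path, expected_nodes = 160L) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  nodes <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             fileEncoding = "UTF-8")
  if (ncol(nodes) != 5L) {
    stop(sprintf("atlas: expected 5 tab-separated columns, found %d in %s",
                 ncol(nodes), path))
  }
  make_atlas(nodes, expected_nodes = expected_nodes)
}

#' The packaged 160-node atlas
#'
#' Loads `inst/extdata/atlas160_synthetic.tsv`.  Its sensorimotor (33 nodes)
#' and cerebellar (18 nodes) entries are the published node tables of the
#' Dosenbach 160-ROI atlas; the coordinates of the remaining four networks
#' (cingulo-opercular 32, fronto-parietal 21, default-mode 34, occipital 22
#' — the published per-network counts) are synthetic stand-ins, adequate for
#' network-membership bookkeeping but not for spatial interpretation.
#'
#' @return A `connsweep_atlas` with 160 nodes.
#' @export
default_atlas <- function() {
  load_atlas(system.file("extdata", "atlas160_synthetic.tsv",
                         package = "connsweep", mustWork = TRUE))
}

#' @export
print.connsweep_atlas <- function(x, ...) {
  cat(sprintf("connsweep atlas: %d nodes\n", nrow(x)))
  print(table(network = x$network))
  invisible(x)
}

#' Node ids belonging to a network
#'
#' @param atlas A `connsweep_atlas`.
#' @param network One of [atlas_networks()].
#' @return Integer vector of 1-based row indices of the member nodes.
#' @export
network_nodes <- function(atlas, network) {
  network <- match.arg(network, atlas_networks())
  idx <- which(atlas$network == network)
  if (length(idx) == 0L) stop("atlas has no nodes in network: ", network)
  idx
}
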