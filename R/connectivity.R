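#' Condition-weighted correlation networks
#'
#' Per condition, every node pair's association is the weighted Pearson
#' correlation of the cleaned series under the HRF-derived scan weights,
#' Fisher z-transformed; anticorrelations are zeroed (not absolute-valued),
#' giving a symmetric nonnegative adjacency matrix with zero diagonal.
#'
#' @name connectivity
NULL

#' Weighted Pearson correlation
#'
#' Frequency-weight semantics: `r = cov_w(x, y) / sqrt(var_w(x) var_w(y))`
#' with weighted means; invariant to rescaling of the weights.  Uniform
#' weights reduce to the ordinary Pearson correlation; 0/1 indicator
#' weights reduce to the correlation over the selected scans.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Nonnegative weights, same length, positive sum.
#' @return r in `[-1, 1]`, or `NA` (with warning) when a weighted variance
#'   is zero.
#' @export
weighted_correlation <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y, w must have equal length")
  }
  if (any(w < 0)) stop("weights must be nonnegative")
  sw <- sum(w)
  if (sw <= 0) stop("weights must have positive sum")
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx == 0 || vy == 0) {
    warning("zero weighted variance: correlation undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

# full weighted correlation matrix, vectorized
weighted_correlation_matrix <- function(ts, w) {
  x <- as.matrix(ts)
  sw <- sum(w)
  xc <- sweep(x, 2L, colSums(w * x) / sw)
  cov_w <- crossprod(xc * sqrt(w)) / sw
  v <- diag(cov_w)
  r <- cov_w / sqrt(outer(v, v))
  r[!is.finite(r)] <- NA_real_
  r
}

#' Build a per-condition adjacency matrix
#'
#' Pairwise weighted correlations over all node pairs, Fisher-transformed
#' (`z = atanh(r)`, with |r| capped at `1 - cap_eps` first so degenerate
#' near-duplicate nodes cannot produce infinities), negatives set to zero,
#' diagonal zero.
#'
#' @param ts T x N cleaned time-series matrix.
#' @param weights A `connsweep_weights` object or a nonnegative vector.
#' @param cap_eps Correlation cap distance from 1 (default 1e-7).
#' @return N x N matrix of class `connsweep_adjacency` with attribute
#'   `condition` when available.
#' @export
build_adjacency <- function(ts, weights, cap_eps = 1e-7) {
  condition <- NULL
  if (inherits(weights, "connsweep_weights")) {
    condition <- weights$condition
    weights <- weights$weights
  }
  if (nrow(ts) != length(weights)) stop("weights length must match time points")
  r <- weighted_correlation_matrix(ts, weights)
  if (anyNA(r)) {
    bad <- which(is.na(r), arr.ind = TRUE)[1L, ]
    stop(sprintf("undefined correlation between nodes %d and %d (zero weighted variance)",
                 bad[1L], bad[2L]))
  }
  r <- pmin(pmax(r, -(1 - cap_eps)), 1 - cap_eps)
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- 0
  z <- (z + t(z)) / 2  # guard symmetry against rounding
  structure(z, class = c("connsweep_adjacency", "matrix", "array"),
            condition = condition)
}
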