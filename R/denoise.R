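#' Time-series denoising
#'
#' Cleaning follows a fixed order: confound regression (5 nuisance
#' principal components, 6 realignment parameters, HRF-convolved task
#' regressors for both conditions, optional motion-spike indicators), then
#' discrete-cosine high-pass at 0.008 Hz, then per-node linear detrend and
#' robust soft-clip despiking.  No low-pass is applied anywhere, so signal
#' above the drift band is preserved.
#'
#' @name denoise
NULL

#' Principal components of nuisance channels
#'
#' aCompCor-style: channels are mean-centered, components are ordered by
#' explained variance, and each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param nuisance_signals T x M numeric matrix (M >= n, T > M).
#' @param n Number of components requested (default 5).
#' @return T x n matrix of component score series (fewer columns, with a
#'   warning, when the channel rank is below `n`).
#' @export
nuisance_pca <- function(nuisance_signals, n = 5L) {
  x <- as.matrix(nuisance_signals)
  x <- sweep(x, 2L, colMeans(x))
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank < n) {
    warning(sprintf("nuisance channels have rank %d < %d; returning %d components",
                    rank, n, rank))
    n <- rank
  }
  if (n == 0L) return(matrix(numeric(0), nrow = nrow(x), ncol = 0L))
  scores <- sv$u[, seq_len(n), drop = FALSE] %*% diag(sv$d[seq_len(n)], n, n)
  loadings <- sv$v[, seq_len(n), drop = FALSE]
  for (j in seq_len(n)) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Build the confound design matrix
#'
#' @param nuisance_pcs T x K1 matrix from [nuisance_pca()].
#' @param realignment T x 6 realignment parameters.
#' @param task_regressors T x K2 matrix of HRF-convolved task regressors.
#' @param spikes Optional T x K3 spike indicator matrix.
#' @return T x K numeric matrix (no intercept column; the regression adds
#'   one), constant columns dropped.
#' @export
confound_matrix <- function(nuisance_pcs, realignment, task_regressors,
                            spikes = NULL) {
  parts <- list(as.matrix(nuisance_pcs), as.matrix(realignment),
                as.matrix(task_regressors))
  if (!is.null(spikes) && ncol(as.matrix(spikes)) > 0L) {
    parts <- c(parts, list(as.matrix(spikes)))
  }
  x <- do.call(cbind, parts)
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  x[, keep, drop = FALSE]
}

#' Regress confounds out of time series
#'
#' Ordinary least-squares residuals of every column of `ts` on the confound
#' matrix plus an intercept (always included).
#'
#' @param ts T x N numeric matrix.
#' @param confounds T x K confound matrix.
#' @return T x N residual matrix.
#' @export
regress_confounds <- function(ts, confounds) {
  y <- as.matrix(ts)
  x <- cbind(1, as.matrix(confounds))
  if (nrow(y) <= ncol(x)) stop("more confounds (plus intercept) than time points")
  qr_x <- qr(x)
  y - x %*% qr.coef(qr_x, y)
}

#' Discrete-cosine high-pass filter
#'
#' Regresses out a discrete cosine basis spanning all frequencies below the
#' cutoff (plus the constant).  The DCT basis function k over T samples of
#' spacing tr has frequency k / (2 T tr); all k with frequency < cutoff are
#' removed.  No low-pass is applied.
#'
#' @param ts T x N matrix.
#' @param tr Repetition time in seconds.
#' @param cutoff Cutoff frequency in Hz (default 0.008).
#' @return Filtered T x N matrix.
#' @export
highpass_dct <- function(ts, tr, cutoff = 0.008) {
  y <- as.matrix(ts)
  T_ <- nrow(y)
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive")
  k_max <- floor(2 * T_ * tr * cutoff)
  if (k_max >= T_ - 1L) stop("cutoff too high: DCT basis would span the data")
  if (k_max < 1L) {
    return(sweep(y, 2L, colMeans(y)))
  }
  t_idx <- seq_len(T_) - 0.5
  basis <- vapply(seq_len(k_max),
                  function(k) cos(pi * k * t_idx / T_),
                  numeric(T_))
  regress_confounds(y, basis)
}

#' Linear detrend and robust despike
#'
#' Per node: remove a linear trend (least squares), then soft-clip
#' excursions with `x <- m + s * tanh((x - m) / s)` where `m` is the node
#' median and `s = despike_sd * 1.4826 * MAD`.  Nodes with zero MAD skip the
#' despike (warning).
#'
#' @param ts T x N matrix.
#' @param despike_sd Clip scale in robust sd units (default 3).
#' @return T x N matrix.
#' @export
detrend_despike <- function(ts, despike_sd = 3) {
  y <- as.matrix(ts)
  if (nrow(y) < 3L) stop("need at least 3 time points")
  t_idx <- seq_len(nrow(y))
  x <- cbind(1, t_idx)
  y <- y - x %*% qr.coef(qr(x), y)
  zero_mad <- FALSE
  for (j in seq_len(ncol(y))) {
    m <- stats::median(y[, j])
    s <- despike_sd * stats::mad(y[, j])
    if (s == 0) { zero_mad <- TRUE; next }
    y[, j] <- m + s * tanh((y[, j] - m) / s)
  }
  if (zero_mad) warning("zero MAD for some node(s); despike skipped there")
  y
}

#' Motion-spike indicator regressors
#'
#' One one-hot column per frame whose FD exceeds the threshold; appended to
#' the confound matrix when spike regression is enabled, which forces the
#' residuals at the flagged frames to zero.
#'
#' @param fd FD series.
#' @param threshold FD threshold in mm (default 0.5).
#' @return T x K indicator matrix (K = number of flagged frames; zero
#'   columns when none).
#' @export
spike_regressors <- function(fd, threshold = 0.5) {
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be positive")
  flagged <- which(fd > threshold)
  if (length(flagged) == length(fd)) {
    stop("all frames exceed the FD threshold: nothing left to analyze")
  }
  out <- matrix(0, nrow = length(fd), ncol = length(flagged))
  for (j in seq_along(flagged)) out[flagged[j], j] <- 1
  out
}

#' Clean a session bundle's ROI time series
#'
#' Applies the full denoising chain in fixed order: confound regression,
#' high-pass, detrend, despike.
#'
#' @param bundle A session bundle (see [simulate_cohort()]).
#' @param n_compcor Number of nuisance components (default 5).
#' @param hp_cutoff_hz High-pass cutoff (default 0.008).
#' @param despike_sd Despike clip scale (default 3).
#' @param spike_fd_mm FD spike threshold in mm, or NULL to disable spike
#'   regression (default NULL; 0.5 is the conventional choice when on).
#' @return T x N cleaned matrix.
#' @export
clean_timeseries <- function(bundle, n_compcor = 5L, hp_cutoff_hz = 0.008,
                             despike_sd = 3, spike_fd_mm = NULL) {
  design <- bundle$design
  task <- cbind(
    motion = block_regressor(design, "motion"),
    static = block_regressor(design, "static")
  )
  pcs <- nuisance_pca(bundle$nuisance_signals, n = n_compcor)
  spikes <- NULL
  if (!is.null(spike_fd_mm)) {
    fd <- framewise_displacement(bundle$realignment)
    spikes <- spike_regressors(fd, spike_fd_mm)
  }
  conf <- confound_matrix(pcs, bundle$realignment, task, spikes)
  res <- regress_confounds(bundle$roi_signals, conf)
  res <- highpass_dct(res, design$tr, hp_cutoff_hz)
  detrend_despike(res, despike_sd)
}
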