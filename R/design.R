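#' Block design and hemodynamic regressors
#'
#' The experiment alternates 27.5 s blocks of coherent visual motion with
#' 27.5 s of a static dot pattern, 12 cycles, sampled at TR = 2.45 s over
#' 260 volumes.  Regressors are boxcars sampled at scan midpoints and
#' convolved with a canonical double-gamma hemodynamic response function
#' (HRF); clipped convolved regressors serve as per-scan condition weights
#' for the weighted-correlation connectivity.
#'
#' @name design
NULL

design_conditions <- c("motion", "static")

#' Build an alternating block design
#'
#' Blocks alternate motion/static starting with motion.  Blocks (or block
#' tails) extending past the scanned interval `n_volumes * tr` are truncated
#' to it, never dropped, so a nominal 12-cycle 27.5 s design clips to the
#' 260-volume run.
#'
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes (scans).
#' @param block_duration Duration of each block in seconds (default 27.5).
#' @param n_cycles Number of motion/static cycles (default 12).
#' @return A `connsweep_design`: list with `tr`, `n_volumes` and a `blocks`
#'   data.frame (`onset`, `duration`, `condition`).
#' @export
make_design <- function(tr, n_volumes, block_duration = 27.5, n_cycles = 12L) {
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive")
  if (!is.finite(n_volumes) || n_volumes < 1) stop("n_volumes must be positive")
  if (!is.finite(block_duration) || block_duration <= 0) {
    stop("block_duration must be positive")
  }
  if (!is.finite(n_cycles) || n_cycles < 1) stop("n_cycles must be positive")
  total <- n_volumes * tr
  onsets <- (seq_len(2L * n_cycles) - 1L) * block_duration
  cond <- rep(design_conditions, times = n_cycles)
  keep <- onsets < total
  onsets <- onsets[keep]
  cond <- cond[keep]
  durations <- pmin(block_duration, total - onsets)
  design <- list(
    tr = tr,
    n_volumes = as.integer(n_volumes),
    blocks = data.frame(onset = onsets, duration = durations,
                        condition = cond, stringsAsFactors = FALSE)
  )
  class(design) <- "connsweep_design"
  design
}

#' Default session design
#'
#' TR 2.45 s, 260 volumes, 27.5 s blocks, 12 motion/static cycles.
#' @return A `connsweep_design`.
#' @export
default_design <- function() make_design(2.45, 260L, 27.5, 12L)

#' @export
print.connsweep_design <- function(x, ...) {
  cat(sprintf("connsweep design: TR %.3g s, %d volumes, %d blocks (%s)\n",
              x$tr, x$n_volumes, nrow(x$blocks),
              paste(sprintf("%d %s", table(x$blocks$condition)[design_conditions],
                            design_conditions), collapse = ", ")))
  invisible(x)
}

#' Canonical double-gamma HRF kernel
#'
#' The canonical double-gamma impulse response (response peak 6 s,
#' undershoot peak 16 s, peak-to-undershoot ratio 6, both gamma densities
#' with unit rate), sampled at the TR and scaled to unit peak.  The kernel
#' vanishes at t = 0 and has decayed to ~0 by 32 s.
#'
#' @param tr Sample spacing in seconds.
#' @param length Kernel length in seconds (>= 32).
#' @return Object of class `connsweep_hrf`: list with `tr` and `values`.
#' @export
hrf_kernel <- function(tr, length = 32) {
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive")
  if (length < 32) stop("kernel length must be at least 32 s")
  t <- seq(0, length, by = tr)
  v <- hrf_shape(t)
  v <- v / max(v)
  structure(list(tr = tr, values = v), class = "connsweep_hrf")
}

# double-gamma shape on arbitrary time points (unnormalized)
hrf_shape <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Unconvolved condition boxcar at scan resolution
#'
#' Volume t (0-based) covers the interval `[t*tr, (t+1)*tr)`; a scan is "on"
#' if its acquisition midpoint `(t + 0.5) * tr` falls inside a block of the
#' requested condition.
#'
#' @param design A `connsweep_design`.
#' @param condition `"motion"` or `"static"`.
#' @param tr,n_volumes Optional overrides; default to the design's values.
#' @return 0/1 numeric vector of length `n_volumes`.
#' @export
block_boxcar <- function(design, condition, tr = design$tr,
                         n_volumes = design$n_volumes) {
  condition <- match.arg(condition, design_conditions)
  blocks <- design$blocks[design$blocks$condition == condition, , drop = FALSE]
  if (nrow(blocks) == 0L) stop("condition not present in design: ", condition)
  mid <- (seq_len(n_volumes) - 0.5) * tr
  on <- rep(0, n_volumes)
  for (b in seq_len(nrow(blocks))) {
    on[mid >= blocks$onset[b] & mid < blocks$onset[b] + blocks$duration[b]] <- 1
  }
  on
}

#' HRF-convolved block regressor
#'
#' The condition boxcar convolved with the canonical HRF kernel, truncated
#' to the scan count.
#'
#' @inheritParams block_boxcar
#' @param hrf Optional `connsweep_hrf`; defaults to `hrf_kernel(tr)`.
#' @return Numeric vector of length `n_volumes`.
#' @export
block_regressor <- function(design, condition, tr = design$tr,
                            n_volumes = design$n_volumes, hrf = NULL) {
  box <- block_boxcar(design, condition, tr, n_volumes)
  if (is.null(hrf)) hrf <- hrf_kernel(tr)
  convolve_truncate(box, hrf$values, n_volumes)
}

convolve_truncate <- function(x, kernel, n_out) {
  full <- stats::convolve(c(x, rep(0, length(kernel))),
                          rev(kernel), type = "open")
  full[seq_len(n_out)]
}

#' Per-scan condition weights
#'
#' The HRF-convolved boxcar with negative values clipped to zero, usable as
#' nonnegative frequency weights in the weighted correlation.  Weights are
#' not renormalized (the weighted correlation is invariant to their scale).
#'
#' @inheritParams block_regressor
#' @return Object of class `connsweep_weights`: list with `condition` and
#'   nonnegative `weights` of length `n_volumes`.
#' @export
condition_weights <- function(design, condition, tr = design$tr,
                              n_volumes = design$n_volumes, hrf = NULL) {
  reg <- block_regressor(design, condition, tr, n_volumes, hrf)
  w <- pmax(reg, 0)
  if (!any(w > 0)) stop("condition never occurs within the scanned interval: ",
                        condition)
  structure(list(condition = condition, weights = w),
            class = "connsweep_weights")
}
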