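#' Head-motion quality control
#'
#' Framewise displacement (FD) in the Jenkinson sense — the RMS displacement
#' of points on an 80 mm sphere under the frame-to-frame rigid-body
#' transform — plus the Pearson correlation of FD with the raw task boxcar,
#' and within-group z-score exclusion rules.
#'
#' @name motion_qc
NULL

# 4x4 rigid-body transform from a realignment row
# (tx, ty, tz in mm; rx, ry, rz rotations in radians, applied as Rz Ry Rx)
rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  M <- diag(4)
  M[1:3, 1:3] <- Rz %*% Ry %*% Rx
  M[1:3, 4] <- p[1:3]
  M
}

#' Framewise displacement (Jenkinson)
#'
#' For each consecutive pair of realignment rows, the relative rigid-body
#' transform `M_t %*% solve(M_{t-1})` is formed; with `A` its linear part
#' minus identity and `t` its translation, FD is the RMS displacement of a
#' uniform 80 mm sphere centered at the origin:
#' `sqrt((R^2/5) * tr(A'A) + t't)`.  The first element is 0.
#'
#' Rotations must be in radians (three translations mm, then three rotations;
#' degrees cannot be detected and are a contract violation).
#'
#' @param realignment T x 6 numeric matrix.
#' @param radius Sphere radius in mm (default 80, the Jenkinson convention).
#' @return Nonnegative numeric vector of length T, first element 0.
#' @export
framewise_displacement <- function(realignment, radius = 80) {
  rp <- as.matrix(realignment)
  if (nrow(rp) < 2L || ncol(rp) != 6L) {
    stop("realignment must be a T x 6 matrix with T >= 2")
  }
  fd <- numeric(nrow(rp))
  M_prev <- rigid_transform(rp[1L, ])
  for (t in 2:nrow(rp)) {
    M_t <- rigid_transform(rp[t, ])
    rel <- M_t %*% solve(M_prev) - diag(4)
    A <- rel[1:3, 1:3]
    tt <- rel[1:3, 4]
    fd[t] <- sqrt(radius^2 / 5 * sum(A * A) + sum(tt * tt))
    M_prev <- M_t
  }
  fd
}

#' Correlation between task timing and framewise displacement
#'
#' Pearson correlation between the raw (unconvolved) 0/1 motion-condition
#' boxcar and the FD series.  Set `convolved = TRUE` to correlate against
#' the HRF-convolved regressor instead.
#'
#' @param fd Numeric FD series.
#' @param design A `connsweep_design`.
#' @param tr Repetition time (defaults to the design's).
#' @param convolved Use the HRF-convolved regressor instead of the boxcar.
#' @return Pearson r, or `NA` (with a warning) when either series has zero
#'   variance.
#' @export
task_motion_correlation <- function(fd, design, tr = design$tr,
                                    convolved = FALSE) {
  task <- if (convolved) {
    block_regressor(design, "motion", tr, length(fd))
  } else {
    block_boxcar(design, "motion", tr, length(fd))
  }
  if (stats::sd(fd) == 0 || stats::sd(task) == 0) {
    warning("zero-variance series: task-FD correlation undefined")
    return(NA_real_)
  }
  stats::cor(fd, task)
}

#' Within-group z-score outlier flags
#'
#' Standardizes values within each group (mean and n-1 sd) and flags
#' |z| > threshold.  A group with zero sd yields no exclusions there (with a
#' warning).  Exclusion is single-pass: the rule is not re-applied to the
#' surviving cohort.
#'
#' @param values Numeric vector, one per participant.
#' @param groups Group labels, same length.
#' @param z_threshold Default 3.
#' @return data.frame with `value`, `group`, `z`, `flag`.
#' @export
flag_outliers <- function(values, groups, z_threshold = 3) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (any(table(groups) < 2L)) stop("need at least 2 participants per group")
  z <- numeric(length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- stats::sd(values[idx])
    if (s == 0) {
      warning("zero within-group sd in group ", g, "; no exclusions there")
      z[idx] <- 0
    } else {
      z[idx] <- (values[idx] - mean(values[idx])) / s
    }
  }
  data.frame(value = values, group = groups, z = z,
             flag = abs(z) > z_threshold, stringsAsFactors = FALSE)
}

#' Cohort motion QC
#'
#' Runs the full motion-screening battery on a cohort of session bundles:
#' a pre-filter on maximum absolute realignment parameters (3 mm / 3
#' degrees), then mean FD and task-FD correlation with within-group
#' z > +-3 exclusion (union of the two flags; single pass).
#'
#' @param cohort A `connsweep_cohort` (see [simulate_cohort()]) or a list of
#'   session bundles plus a `participants` data.frame.
#' @param z_threshold z-score exclusion threshold (default 3).
#' @param max_translation_mm,max_rotation_deg Absolute-motion inclusion
#'   limits (defaults 3 mm / 3 degrees).
#' @param convolved Passed to [task_motion_correlation()].
#' @return data.frame of class `connsweep_motion_qc`: one row per
#'   participant with `participant_id`, `group`, `mean_fd`, `task_fd_corr`,
#'   `z_mean_fd`, `z_task_corr`, `excluded`, `reason`; the per-participant
#'   FD series are attached as attribute `fd_series`.
#' @export
motion_qc <- function(cohort, z_threshold = 3,
                      max_translation_mm = 3, max_rotation_deg = 3,
                      convolved = FALSE) {
  bundles <- cohort$bundles
  part <- cohort$participants
  n <- length(bundles)
  mean_fd <- task_r <- numeric(n)
  gross <- logical(n)
  fd_list <- vector("list", n)
  for (i in seq_len(n)) {
    b <- bundles[[i]]
    fd <- framewise_displacement(b$realignment)
    fd_list[[i]] <- fd
    mean_fd[i] <- mean(fd)
    task_r[i] <- task_motion_correlation(fd, b$design, convolved = convolved)
    gross[i] <- max(abs(b$realignment[, 1:3])) > max_translation_mm ||
      max(abs(b$realignment[, 4:6])) > max_rotation_deg * pi / 180
  }
  zf <- flag_outliers(mean_fd, part$group, z_threshold)
  zc <- flag_outliers(task_r, part$group, z_threshold)
  reason <- character(n)
  reason[zc$flag] <- "task-FD correlation z"
  reason[zf$flag] <- ifelse(reason[zf$flag] == "", "mean FD z",
                            paste(reason[zf$flag], "+ mean FD z"))
  reason[gross] <- ifelse(reason[gross] == "", "max motion > 3mm/3deg",
                          paste(reason[gross], "+ max motion"))
  out <- data.frame(
    participant_id = part$participant_id,
    group = part$group,
    mean_fd = mean_fd,
    task_fd_corr = task_r,
    z_mean_fd = zf$z,
    z_task_corr = zc$z,
    excluded = gross | zf$flag | zc$flag,
    reason = reason,
    stringsAsFactors = FALSE
  )
  attr(out, "fd_series") <- fd_list
  class(out) <- c("connsweep_motion_qc", "data.frame")
  out
}
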