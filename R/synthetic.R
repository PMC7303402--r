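#' Synthetic cohort generation
#'
#' Generates cohorts of session bundles with known group- and
#' condition-dependent connectivity structure, so every downstream stage
#' of the pipeline can be validated against ground truth.  The signal
#' model is a latent-factor construction: each functional network has a
#' shared latent series, and a member node's signal is
#' `sqrt(c_t) * latent + sqrt(1 - c_t) * idiosyncratic`, where both parts
#' are unit-variance AR(1) processes and the coupling `c_t` is modulated
#' around its base value through the HRF-convolved block regressors by
#' per-(group, network, condition) deltas.  This keeps every latent
#' correlation matrix positive semi-definite by construction and makes the
#' within-network correlation equal the coupling.  Low-frequency cosine
#' drift, white measurement noise, aCompCor-style nuisance channels, and
#' random-walk realignment traces whose position and step variance carry an
#' optional task-locked component complete the bundles.
#'
#' @name synthetic_data
NULL

#' Effect configuration for the cohort generator
#'
#' @param base_coupling Baseline within-network coupling (correlation
#'   scale), default 0.3.
#' @param deltas data.frame with columns `group`, `network`, `condition`,
#'   `delta`: additive coupling modulation applied through the normalized
#'   HRF-convolved regressor of that condition.  The default encodes the
#'   qualitative group differences the analysis is meant to recover:
#'   patients couple the sensorimotor network more strongly under visual
#'   motion and the cerebellar network less, with the reverse bias during
#'   static vision.
#' @param noise_sd White measurement-noise sd on the unit-variance node
#'   signals (default 0.1).
#' @param drift_amplitude Cosine drift amplitude (default 0.3).
#' @param ar_rho AR(1) coefficient of latent and idiosyncratic series
#'   (default 0.3, mimicking BOLD autocorrelation).
#' @param motion_task_coupling Scale in `[0, 1]` of the task-locked
#'   realignment component (default 0.3).
#' @param n_hc,n_ppv Group sizes (defaults 18 and 17).
#' @param n_nuisance Number of nuisance channels (default 10).
#' @param rw_step_mm,rw_step_rad Random-walk step sds of the realignment
#'   traces (defaults 0.02 mm, 2e-4 rad).
#' @param seed Integer root seed.
#' @return Object of class `connsweep_effects` (a list).
#' @export
effect_config <- function(base_coupling = 0.3,
                          deltas = default_effect_deltas(),
                          noise_sd = 0.1,
                          drift_amplitude = 0.3,
                          ar_rho = 0.3,
                          motion_task_coupling = 0.3,
                          n_hc = 18L, n_ppv = 17L,
                          n_nuisance = 10L,
                          rw_step_mm = 0.02, rw_step_rad = 2e-4,
                          seed = 1L) {
  if (motion_task_coupling < 0 || motion_task_coupling > 1) {
    stop("motion_task_coupling must be in [0, 1]")
  }
  structure(list(
    base_coupling = base_coupling, deltas = deltas, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, ar_rho = ar_rho,
    motion_task_coupling = motion_task_coupling,
    n_hc = as.integer(n_hc), n_ppv = as.integer(n_ppv),
    n_nuisance = as.integer(n_nuisance),
    rw_step_mm = rw_step_mm, rw_step_rad = rw_step_rad,
    seed = as.integer(seed)
  ), class = "connsweep_effects")
}

#' @rdname effect_config
#' @export
default_effect_deltas <- function() {
  data.frame(
    group = c("PPV", "PPV", "PPV", "PPV", "HC"),
    network = c("sensorimotor", "cerebellum", "sensorimotor",
                "default-mode", "cerebellum"),
    condition = c("motion", "motion", "static", "static", "motion"),
    delta = c(0.15, -0.10, -0.10, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

# unit-variance stationary AR(1) series (columns independent)
ar1_series <- function(T_, ncol, rho) {
  e <- matrix(stats::rnorm(T_ * ncol), T_, ncol)
  if (rho == 0) return(e)
  x <- e
  s <- sqrt(1 - rho^2)
  for (t in 2:T_) x[t, ] <- rho * x[t - 1L, ] + s * e[t, ]
  x
}

#' Simulate a cohort of session bundles
#'
#' Deterministic given the config seed (per-participant substreams are
#' derived from it).  Healthy controls come first, then patients.
#'
#' @param atlas A `connsweep_atlas`.
#' @param design A `connsweep_design`.
#' @param effects A `connsweep_effects` from [effect_config()].
#' @return Object of class `connsweep_cohort`: list with `bundles` (one
#'   per participant: `participant_id`, `group`, `age`, `roi_signals`,
#'   `nuisance_signals`, `realignment`, `design`), a `participants`
#'   data.frame, and the `atlas`, `design`, `effects` used.
#' @export
simulate_cohort <- function(atlas = default_atlas(),
                            design = default_design(),
                            effects = effect_config()) {
  T_ <- design$n_volumes
  nets <- atlas_networks()
  net_of <- match(atlas$network, nets)
  n_nodes <- nrow(atlas)
  groups <- c(rep("HC", effects$n_hc), rep("PPV", effects$n_ppv))
  n <- length(groups)

  # normalized (unit peak) clipped condition regressors
  s_cond <- lapply(c(motion = "motion", static = "static"), function(cc) {
    w <- condition_weights(design, cc)$weights
    w / max(w)
  })

  delta_of <- function(group, network, condition) {
    d <- effects$deltas
    hit <- d$group == group & d$network == network & d$condition == condition
    if (any(hit)) sum(d$delta[hit]) else 0
  }

  set.seed(effects$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ages <- stats::runif(n, 20, 60)

  bundles <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    g <- groups[i]
    # time-varying coupling per network
    c_t <- vapply(nets, function(nv) {
      effects$base_coupling +
        delta_of(g, nv, "motion") * s_cond$motion +
        delta_of(g, nv, "static") * s_cond$static
    }, numeric(T_))
    if (any(c_t < 0) || any(c_t >= 1)) {
      stop("coupling outside [0, 1) after condition modulation")
    }
    latent <- ar1_series(T_, length(nets), effects$ar_rho)
    idio <- ar1_series(T_, n_nodes, effects$ar_rho)
    sqc <- sqrt(c_t[, net_of, drop = FALSE])
    roi <- sqc * latent[, net_of, drop = FALSE] + sqrt(1 - sqc^2) * idio
    roi <- roi + effects$noise_sd * matrix(stats::rnorm(T_ * n_nodes), T_)
    # per-node low-frequency cosine drift, random frequency and phase
    freq <- stats::runif(n_nodes, 0.002, 0.006)
    phase <- stats::runif(n_nodes, 0, 2 * pi)
    tt <- (seq_len(T_) - 1L) * design$tr
    roi <- roi + effects$drift_amplitude *
      cos(outer(tt, 2 * pi * freq) + matrix(phase, T_, n_nodes, byrow = TRUE))
    colnames(roi) <- atlas$node_id

    # nuisance channels: mixtures of a shared drift and global noise
    g_noise <- ar1_series(T_, 1L, effects$ar_rho)[, 1L]
    common_drift <- cos(2 * pi * 0.004 * tt + stats::runif(1, 0, 2 * pi))
    nuis <- vapply(seq_len(effects$n_nuisance), function(j) {
      stats::runif(1, 0.3, 1) * common_drift +
        stats::runif(1, 0.3, 1) * g_noise +
        0.3 * stats::rnorm(T_)
    }, numeric(T_))

    # realignment: random walks with task-modulated step variance (heads
    # are more restless under the motion stimulus, which is what makes FD
    # covary with the task blocks) plus a task-locked positional component
    amp <- abs(stats::rnorm(6, 0, c(rep(0.05, 3), rep(5e-4, 3))))
    restless <- sqrt(1 + 3 * effects$motion_task_coupling * s_cond$motion)
    steps <- cbind(
      matrix(stats::rnorm(T_ * 3, 0, effects$rw_step_mm), T_),
      matrix(stats::rnorm(T_ * 3, 0, effects$rw_step_rad), T_)
    ) * restless
    rp <- apply(steps, 2L, cumsum) +
      outer(s_cond$motion, effects$motion_task_coupling * amp)

    bundles[[i]] <- list(
      participant_id = sprintf("sub-%03d", i),
      group = g, age = ages[i],
      roi_signals = roi, nuisance_signals = nuis,
      realignment = rp, design = design
    )
  }
  participants <- data.frame(
    participant_id = vapply(bundles, `[[`, character(1), "participant_id"),
    group = groups, age = ages, stringsAsFactors = FALSE
  )
  structure(list(bundles = bundles, participants = participants,
                 atlas = atlas, design = design, effects = effects),
            class = "connsweep_cohort")
}

#' @export
print.connsweep_cohort <- function(x, ...) {
  cat(sprintf("connsweep cohort: %d participants (%s), %d volumes, %d nodes\n",
              nrow(x$participants),
              paste(sprintf("%s n=%d", names(table(x$participants$group)),
                            table(x$participants$group)), collapse = ", "),
              x$design$n_volumes, nrow(x$atlas)))
  invisible(x)
}

#' Simulate a network-summary long table
#'
#' Generates AUC-scale summary values directly at the statistical-table
#' level (participant x network), for calibration and power studies of the
#' group statistics: value = subject intercept + network effect + injected
#' group x network effect + residual.  The default variance split
#' (subject sd^2 = 0.7, residual sd^2 = 0.3; total cell variance 1) gives
#' an intraclass correlation of 0.7, in line with the high between-subject
#' stability of connectome summary measures.
#'
#' @param n_hc,n_ppv Group sizes (defaults 18, 17).
#' @param networks Within-factor level names (default the six networks).
#' @param subject_sd,resid_sd Random-intercept and residual sds
#'   (defaults `sqrt(0.7)`, `sqrt(0.3)`).
#' @param network_effects Optional named numeric vector of within-level
#'   means.
#' @param group_network_effect Optional list
#'   `list(group =, network =, delta =)` adding `delta` to that group's
#'   mean in that network (the injected interaction effect; `delta` is in
#'   within-cell sd units when the default unit cell variance is kept).
#' @param age_slope Linear age effect on all values (default 0).
#' @param measure_names When not NULL, generates one independent replicate
#'   per measure name and returns them stacked with a `measure` column.
#' @return Long data.frame: `participant`, `group`, `age`, `network`,
#'   (`measure`,) `value`.
#' @export
simulate_summary_table <- function(n_hc = 18L, n_ppv = 17L,
                                   networks = atlas_networks(),
                                   subject_sd = sqrt(0.7),
                                   resid_sd = sqrt(0.3),
                                   network_effects = NULL,
                                   group_network_effect = NULL,
                                   age_slope = 0,
                                   measure_names = NULL) {
  k <- length(networks)
  n <- n_hc + n_ppv
  group <- c(rep("HC", n_hc), rep("PPV", n_ppv))
  age <- stats::runif(n, 20, 60)
  ids <- sprintf("sub-%03d", seq_len(n))
  if (is.null(network_effects)) network_effects <- stats::setNames(rep(0, k), networks)
  one_measure <- function() {
    intercepts <- stats::rnorm(n, 0, subject_sd)
    tab <- expand.grid(participant = ids, network = networks,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pi_ <- match(tab$participant, ids)
    tab$group <- group[pi_]
    tab$age <- age[pi_]
    tab$value <- intercepts[pi_] + network_effects[tab$network] +
      age_slope * (tab$age - mean(age)) +
      stats::rnorm(nrow(tab), 0, resid_sd)
    if (!is.null(group_network_effect)) {
      e <- group_network_effect
      hit <- tab$group == e$group & tab$network == e$network
      tab$value[hit] <- tab$value[hit] + e$delta
    }
    tab
  }
  if (is.null(measure_names)) return(one_measure())
  out <- lapply(measure_names, function(mm) {
    tt <- one_measure()
    tt$measure <- mm
    tt
  })
  do.call(rbind, out)
}
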