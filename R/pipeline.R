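#' Pipeline orchestration and file formats
#'
#' Readers and writers for the interchange formats (TSV matrices with 6
#' significant digits, BIDS-style events, six-column realignment text) and
#' the end-to-end driver that runs motion QC, denoising, per-condition
#' adjacency construction, the graph sweep, network summaries, deltas,
#' decomposition and the statistics battery in a fixed, reproducible order.
#'
#' @name cli_io
NULL

interchange_digits <- 6L

#' Read and write ROI time-series TSV
#'
#' Tab-separated, header of node ids, one row per volume.
#'
#' @param path File path.
#' @param expected_nodes Optional column-count check (e.g. the atlas size).
#' @return Numeric matrix.
#' @export
read_timeseries <- function(path, expected_nodes = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(x)
  if (!is.null(expected_nodes) && ncol(m) != expected_nodes) {
    stop(sprintf("time series has %d columns but the atlas has %d nodes",
                 ncol(m), expected_nodes))
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite value at row %d, column %s",
                 bad[1L, 1L], colnames(m)[bad[1L, 2L]]))
  }
  m
}

#' @rdname read_timeseries
#' @param x Numeric matrix to write.
#' @export
write_timeseries <- function(x, path) {
  m <- signif(as.matrix(x), interchange_digits)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = if (is.null(colnames(m)))
                       seq_len(ncol(m)) - 1L else colnames(m))
  invisible(path)
}

#' Read a six-column realignment parameter file
#'
#' Whitespace-delimited, one row per volume: three translations (mm) then
#' three rotations (radians).
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_realignment <- function(path) {
  if (!file.exists(path)) stop("realignment file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("realignment file must have 6 columns")
  storage.mode(m) <- "double"
  m
}

#' Read a BIDS-style events table into a design
#'
#' TSV with columns `onset`, `duration`, `trial_type` (seconds; trial
#' types `motion` and `static`).
#'
#' @param path File path.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @return A `connsweep_design`.
#' @export
read_events <- function(path, tr, n_volumes) {
  if (!file.exists(path)) stop("events file not found: ", path)
  ev <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev))) {
    stop("events table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(ev$trial_type), c("motion", "static"))
  if (length(bad) > 0L) stop("unknown trial_type: ", paste(bad, collapse = ", "))
  design <- list(tr = tr, n_volumes = as.integer(n_volumes),
                 blocks = data.frame(onset = ev$onset, duration = ev$duration,
                                     condition = ev$trial_type,
                                     stringsAsFactors = FALSE))
  class(design) <- "connsweep_design"
  design
}

#' Write a long results table as CSV
#'
#' Numeric columns rounded to 6 significant digits (the interchange
#' precision).
#'
#' @param records data.frame.
#' @param path Output path.
#' @export
write_long_csv <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], interchange_digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# tiny polynomial string hash for the manifest (config fingerprint only;
# double arithmetic keeps every intermediate exact below 2^53)
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages, in order: motion QC and exclusion; denoising; per-condition
#' weighted-correlation adjacency matrices; graph sweep with per-node AUC;
#' six-network summaries, condition deltas and sensorimotor/cerebellar
#' decomposition; group statistics (omnibus MANCOVA, per-measure mixed
#' ANCOVAs, gated Tukey post hoc contrasts) for the static, motion and
#' delta families.  All intermediates are persisted under `output_dir` and
#' a run manifest records configuration, counts, exclusions and wall-clock
#' per stage.  Re-running with the same cohort and config reproduces all
#' numeric outputs bit-identically.
#'
#' @param cohort A `connsweep_cohort`.
#' @param output_dir Output directory (created if needed).
#' @param grid Cost grid for the metric sweep (default [cost_grid_main()]).
#' @param z_threshold Motion-QC z exclusion threshold (default 3).
#' @param spike_fd_mm Optional FD spike-regressor threshold (default NULL:
#'   off).
#' @param alpha Significance level gating the post hoc contrasts.
#' @param write_adjacency Persist per-participant adjacency TSVs (default
#'   TRUE).
#' @param write_metrics Also persist the per-cost node metric curves as a
#'   long CSV (`metrics.csv`: participant, condition, cost, node, dc, cc,
#'   ecc; default FALSE — the table is large).
#' @return Invisibly, a list with the in-memory results (`qc`, `auc`,
#'   `summary`, `delta`, `decomposition`, `stats`, `manifest`).
#' @export
run_pipeline <- function(cohort, output_dir, grid = cost_grid_main(),
                         z_threshold = 3, spike_fd_mm = NULL, alpha = 0.05,
                         write_adjacency = TRUE, write_metrics = FALSE) {
  stopifnot(inherits(cohort, "connsweep_cohort"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (write_metrics) unlink(file.path(output_dir, "metrics.csv"))
  atlas <- cohort$atlas
  manifest <- list(package_version = as.character(utils::packageVersion("connsweep")),
                   stages = list())
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    r
  }

  qc <- clock("motion_qc", motion_qc(cohort, z_threshold = z_threshold))
  write_long_csv(as.data.frame(qc), file.path(output_dir, "qc.csv"))
  manifest$exclusions <- qc[qc$excluded, c("participant_id", "reason")]
  keep <- which(!qc$excluded)
  if (length(keep) == 0L) stop("stage 'motion_qc' failed: all participants excluded")

  conditions <- c("motion", "static")
  auc_rows <- list()
  summary_rows <- list()
  decomp_rows <- list()
  adj_store <- list()
  for (i in keep) {
    b <- cohort$bundles[[i]]
    cleaned <- clock(paste0("denoise:", b$participant_id),
                     clean_timeseries(b, spike_fd_mm = spike_fd_mm))
    per_cond <- list()
    for (cond in conditions) {
      w <- condition_weights(b$design, cond)
      adj <- build_adjacency(cleaned, w)
      if (write_adjacency) {
        write_timeseries(unclass(adj), file.path(
          output_dir, sprintf("%s_%s_adj.tsv", b$participant_id, cond)))
      }
      curves <- node_metric_curves(adj, grid)
      if (write_metrics) {
        n_nodes <- nrow(curves$dc)
        long <- data.frame(
          participant = b$participant_id, condition = cond,
          cost = rep(grid, each = n_nodes),
          node = rep(seq_len(n_nodes) - 1L, times = length(grid)),
          dc = as.vector(curves$dc), cc = as.vector(curves$cc),
          ecc = as.vector(curves$ecc)
        )
        metrics_path <- file.path(output_dir, "metrics.csv")
        utils::write.table(long, metrics_path, sep = ",", quote = FALSE,
                           row.names = FALSE,
                           col.names = !file.exists(metrics_path),
                           append = file.exists(metrics_path))
      }
      auc <- auc_table(curves)
      auc$participant <- b$participant_id
      auc$condition <- cond
      auc_rows[[length(auc_rows) + 1L]] <- auc
      nm <- network_means(auc, atlas)
      nm$participant <- b$participant_id
      nm$group <- b$group
      nm$age <- b$age
      nm$condition <- cond
      summary_rows[[length(summary_rows) + 1L]] <- nm
      per_cond[[cond]] <- list(adj = adj, nm = nm)
      for (focal in c("sensorimotor", "cerebellum")) {
        dc <- decompose_connectivity(adj, atlas, focal, grid)
        dc$participant <- b$participant_id
        dc$group <- b$group
        dc$condition <- cond
        dc$focal <- focal
        decomp_rows[[length(decomp_rows) + 1L]] <- dc
      }
    }
    adj_store[[b$participant_id]] <- per_cond
  }
  auc_all <- do.call(rbind, auc_rows)
  summary_all <- do.call(rbind, summary_rows)
  write_long_csv(auc_all, file.path(output_dir, "auc.csv"))
  write_long_csv(summary_all, file.path(output_dir, "summary.csv"))

  # condition deltas per participant
  delta_rows <- list()
  for (pid in unique(summary_all$participant)) {
    mo <- summary_all[summary_all$participant == pid &
                        summary_all$condition == "motion", ]
    st <- summary_all[summary_all$participant == pid &
                        summary_all$condition == "static", ]
    dd <- condition_delta(mo, st, pid, pid)
    dd$participant <- pid
    dd$group <- mo$group[1L]
    dd$age <- mo$age[1L]
    delta_rows[[length(delta_rows) + 1L]] <- dd
  }
  delta_all <- do.call(rbind, delta_rows)
  write_long_csv(delta_all, file.path(output_dir, "delta.csv"))
  decomp_all <- do.call(rbind, decomp_rows)
  write_long_csv(decomp_all, file.path(output_dir, "decomposition.csv"))

  # statistics battery per analysis family
  long_from_summary <- function(df, cols, meas) {
    do.call(rbind, lapply(seq_along(meas), function(j) {
      data.frame(participant = df$participant, group = df$group,
                 age = df$age, network = df$network, measure = meas[j],
                 value = df[[cols[j]]], stringsAsFactors = FALSE)
    }))
  }
  meas <- c("dc", "cc", "ecc")
  families <- list(
    static = long_from_summary(summary_all[summary_all$condition == "static", ],
                               c("auc_dc", "auc_cc", "auc_ecc"), meas),
    motion = long_from_summary(summary_all[summary_all$condition == "motion", ],
                               c("auc_dc", "auc_cc", "auc_ecc"), meas),
    delta = long_from_summary(delta_all, c("delta_dc", "delta_cc", "delta_ecc"),
                              meas)
  )
  stats_out <- list()
  for (fam in names(families)) {
    tab <- families[[fam]]
    fam_out <- list()
    fam_out$omnibus <- tryCatch(
      as.data.frame(omnibus_mancova(tab, measures = meas)),
      error = function(e) list(error = conditionMessage(e)))
    for (mm in meas) {
      fit <- tryCatch(mixed_ancova(tab[tab$measure == mm, ]),
                      error = function(e) NULL)
      if (is.null(fit)) {
        fam_out[[mm]] <- list(error = "ANCOVA not estimable")
        next
      }
      ph <- tryCatch(as.data.frame(posthoc_contrasts(fit, alpha = alpha)),
                     error = function(e) conditionMessage(e))
      fam_out[[mm]] <- list(
        effects = fit$effects,
        sphericity = fit$sphericity[c("W", "p", "epsilon")],
        posthoc = ph
      )
    }
    stats_out[[fam]] <- fam_out
  }
  jsonlite::write_json(stats_out, file.path(output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  manifest$n_participants <- nrow(cohort$participants)
  manifest$n_analyzed <- length(keep)
  manifest$rows <- list(auc = nrow(auc_all), summary = nrow(summary_all),
                        delta = nrow(delta_all),
                        decomposition = nrow(decomp_all))
  manifest$config <- list(grid = grid, z_threshold = z_threshold,
                          spike_fd_mm = spike_fd_mm, alpha = alpha,
                          seed = cohort$effects$seed)
  manifest$config_hash <- config_hash(paste(deparse(manifest$config),
                                            collapse = ""))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(qc = qc, auc = auc_all, summary = summary_all,
                 delta = delta_all, decomposition = decomp_all,
                 stats = stats_out, manifest = manifest,
                 adjacency = adj_store))
}
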