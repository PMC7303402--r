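#' Mixed-design group statistics
#'
#' The statistical battery applied to the network summary tables: a
#' doubly-multivariate omnibus test (Pillai's trace) over the three graph
#' measures, univariate mixed-design ANCOVAs (between factor group,
#' within factor network, covariate age) with Mauchly sphericity testing
#' and conditional Greenhouse-Geisser correction, Tukey-adjusted
#' within-network group contrasts, and the connectivity-decomposition
#' mixed ANOVA.
#'
#' Sums of squares follow the classical split-plot decomposition (exact
#' F tests under the usual assumptions), not REML mixed models.  The
#' between-subject stratum is the ANCOVA on subject means (group + centered
#' age); the within stratum operates on orthonormal contrast scores and
#' contains network, group x network and age x network, leaving error
#' degrees of freedom (k-1)(n-3) with the covariate present.
#'
#' @name group_stats
NULL

# orthonormal within-factor contrasts (k x (k-1)), orthogonal to the constant
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2L, sqrt(colSums(C^2)), "/")
}

#' Pillai's trace and its F approximation
#'
#' `V = trace(H (H + E)^-1) = sum lambda_i / (1 + lambda_i)` over the
#' eigenvalues of `E^-1 H`.
#'
#' @param H p x p hypothesis SSCP matrix.
#' @param E p x p error SSCP matrix (positive definite).
#' @return Pillai's trace V.
#' @export
pillai_trace <- function(H, E) {
  H <- as.matrix(H); E <- as.matrix(E)
  HE <- H + E
  if (rcond(HE) < .Machine$double.eps) stop("H + E is singular")
  sum(diag(H %*% solve(HE)))
}

# standard Pillai F approximation; q = hypothesis df, ne = error df, p = #DVs
pillai_f <- function(V, p, q, ne) {
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (ne - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fv <- (df2 / df1) * (V / (s - V))
  list(statistic = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Mauchly's W and Greenhouse-Geisser epsilon
#'
#' Projects a k x k repeated-measures covariance onto k-1 orthonormal
#' contrasts; on that matrix S, `W = det(S) / (trace(S)/(k-1))^(k-1)` and
#' `epsilon = (sum lambda)^2 / ((k-1) sum lambda^2)` from the eigenvalues
#' of S.  The chi-square approximation for W uses the error degrees of
#' freedom `df` of the covariance estimate.
#'
#' @param within_cov k x k covariance matrix of the repeated measures (or,
#'   with `contrast_scale = TRUE`, an already contrast-projected
#'   (k-1) x (k-1) matrix).
#' @param df Error degrees of freedom behind the covariance estimate.
#' @param contrast_scale Set TRUE when `within_cov` is already on the
#'   contrast scale.
#' @return List with `W`, `chisq`, `df` (of the chi-square), `p`, and
#'   `epsilon` (Greenhouse-Geisser, in `[1/(k-1), 1]`).
#' @export
sphericity <- function(within_cov, df, contrast_scale = FALSE) {
  S <- as.matrix(within_cov)
  if (!contrast_scale) {
    k <- nrow(S)
    C <- orthonormal_contrasts(k)
    S <- t(C) %*% S %*% C
  }
  p <- nrow(S)  # = k - 1
  k <- p + 1L
  if (p < 1L) stop("need at least 2 repeated measures")
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  eps <- if (p == 1L) 1 else sum(lam)^2 / (p * sum(lam^2))
  if (p == 1L) {
    return(list(W = 1, chisq = 0, df = 0, p = 1, epsilon = 1))
  }
  detS <- prod(lam)
  W <- detS / (sum(lam) / p)^p
  chi_df <- p * (p + 1) / 2 - 1
  if (W <= 0) {
    warning("singular contrast covariance: Mauchly W at boundary 0")
    return(list(W = 0, chisq = Inf, df = chi_df, p = 0, epsilon = eps))
  }
  mult <- df - (2 * p^2 + p + 2) / (6 * p)
  chisq <- -mult * log(W)
  list(W = W, chisq = chisq, df = chi_df,
       p = stats::pchisq(chisq, chi_df, lower.tail = FALSE),
       epsilon = eps)
}

# reshape a long table into subject-wise structures
# returns Y (n x k wide), group factor, age (or NULL), ids, level names
table_to_wide <- function(table, value, within, between, id, covariate) {
  needed <- c(id, between, within, value)
  if (!is.null(covariate)) needed <- c(needed, covariate)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- unique(table[[id]])
  levels_w <- unique(as.character(table[[within]]))
  n <- length(ids)
  k <- length(levels_w)
  if (nrow(table) != n * k) {
    stop("incomplete crossing: expected one row per participant x level")
  }
  Y <- matrix(NA_real_, n, k, dimnames = list(as.character(ids), levels_w))
  pos_i <- match(table[[id]], ids)
  pos_j <- match(as.character(table[[within]]), levels_w)
  Y[cbind(pos_i, pos_j)] <- table[[value]]
  if (anyNA(Y)) stop("incomplete crossing: missing participant x level cells")
  first <- match(ids, table[[id]])
  grp <- factor(as.character(table[[between]])[first])
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  if (any(table(grp) < 2L)) stop("need at least 2 participants per group")
  age <- if (is.null(covariate)) NULL else as.numeric(table[[covariate]])[first]
  list(Y = Y, group = grp, age = age, ids = ids, levels = levels_w,
       n = n, k = k)
}

# Type III SS / SSCP machinery on a fitted multi-response linear model
term_sscp <- function(B, XtXinv, rows) {
  L <- matrix(0, length(rows), nrow(B))
  L[cbind(seq_along(rows), rows)] <- 1
  LB <- L %*% B
  M <- solve(L %*% XtXinv %*% t(L))
  t(LB) %*% M %*% LB
}

#' Mixed-design ANCOVA (split-plot with covariate)
#'
#' Between-subject stratum: group and centered age tested against the
#' subject-within-group error.  Within-subject stratum (on orthonormal
#' contrast scores): network, group x network and age x network tested
#' against the network x subject error.  Mauchly's test is computed from
#' the contrast residual covariance; per `gg` policy, Greenhouse-Geisser
#' adjusted p-values are reported for within effects when Mauchly's
#' p < .05 (the default), always, or never.
#'
#' @param table Long data.frame; one row per participant x within level.
#' @param value,within,between,id,covariate Column names (covariate may be
#'   NULL for a plain mixed ANOVA).
#' @param gg Greenhouse-Geisser reporting policy: `"mauchly"` (default),
#'   `"always"`, `"never"`.
#' @return Object of class `connsweep_anova` with an `effects` table (SS,
#'   df, F, raw and GG-adjusted p, reported p), the `sphericity` results,
#'   and the components the post hoc contrasts need.
#' @export
mixed_ancova <- function(table, value = "value", within = "network",
                         between = "group", id = "participant",
                         covariate = "age", gg = c("mauchly", "always", "never")) {
  gg <- match.arg(gg)
  w <- table_to_wide(table, value, within, between, id, covariate)
  Y <- w$Y; n <- w$n; k <- w$k
  if (stats::var(as.vector(Y)) == 0) {
    stop("degenerate input: all values identical, F undefined")
  }
  grp <- w$group
  age_c <- if (is.null(w$age)) NULL else w$age - mean(w$age)
  Xb <- stats::model.matrix(~grp, contrasts.arg = list(grp = "contr.sum"))
  g_rows <- 1L + seq_len(nlevels(grp) - 1L)
  a_row <- NULL
  if (!is.null(age_c)) {
    Xb <- cbind(Xb, age_c = age_c)
    a_row <- ncol(Xb)
  }
  pb <- ncol(Xb)
  if (n - pb < 1L) stop("zero between-stratum error df")
  XtXinv <- solve(crossprod(Xb))

  # --- between stratum: subject means (x k to reach observation scale)
  m_i <- rowMeans(Y)
  Bb <- XtXinv %*% crossprod(Xb, m_i)
  res_b <- m_i - Xb %*% Bb
  ss_err_b <- sum(res_b^2) * k
  df_err_b <- n - pb
  between <- list(
    group = list(ss = as.numeric(term_sscp(Bb, XtXinv, g_rows)) * k,
                 df = length(g_rows))
  )
  if (!is.null(a_row)) {
    between$age <- list(ss = as.numeric(term_sscp(Bb, XtXinv, a_row)) * k,
                        df = 1L)
  }

  # --- within stratum: orthonormal contrast scores
  C <- orthonormal_contrasts(k)
  Z <- Y %*% C
  Bw <- XtXinv %*% crossprod(Xb, Z)
  resid_w <- Z - Xb %*% Bw
  E <- crossprod(resid_w)
  df_err_w <- (n - pb) * (k - 1L)
  ss_err_w <- sum(diag(E))
  within_eff <- list(
    network = list(H = term_sscp(Bw, XtXinv, 1L), df_l = 1L),
    `group:network` = list(H = term_sscp(Bw, XtXinv, g_rows),
                           df_l = length(g_rows))
  )
  if (!is.null(a_row)) {
    within_eff$`age:network` <- list(H = term_sscp(Bw, XtXinv, a_row), df_l = 1L)
  }

  sph <- sphericity(E / (n - pb), df = n - pb, contrast_scale = TRUE)
  use_gg <- switch(gg, mauchly = isTRUE(sph$p < 0.05), always = TRUE,
                   never = FALSE)

  rows <- list()
  add_row <- function(effect, ss, df, ss_err, df_err, stratum, eps = NA_real_) {
    if (ss_err <= 0 || df_err <= 0) stop("degenerate input: zero error SS")
    Fv <- (ss / df) / (ss_err / df_err)
    p_raw <- stats::pf(Fv, df, df_err, lower.tail = FALSE)
    if (!is.na(eps)) {
      p_gg <- stats::pf(Fv, eps * df, eps * df_err, lower.tail = FALSE)
      df1_adj <- eps * df; df2_adj <- eps * df_err
      p_rep <- if (use_gg) p_gg else p_raw
    } else {
      p_gg <- NA_real_; df1_adj <- df; df2_adj <- df_err; p_rep <- p_raw
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, stratum = stratum, ss = ss, df = df,
      ss_error = ss_err, df_error = df_err, F = Fv,
      p = p_raw, p_gg = p_gg, df1_adj = df1_adj, df2_adj = df2_adj,
      p_reported = p_rep, stringsAsFactors = FALSE
    )
  }
  add_row("group", between$group$ss, between$group$df,
          ss_err_b, df_err_b, "between")
  if (!is.null(a_row)) {
    add_row("age", between$age$ss, between$age$df, ss_err_b, df_err_b, "between")
  }
  for (nm in names(within_eff)) {
    eff <- within_eff[[nm]]
    add_row(nm, sum(diag(eff$H)), eff$df_l * (k - 1L),
            ss_err_w, df_err_w, "within", eps = sph$epsilon)
  }
  effects <- do.call(rbind, rows)

  slope <- if (is.null(a_row)) 0 else Bb[a_row, 1L]
  out <- list(
    effects = effects,
    sphericity = sph,
    gg_applied = use_gg,
    k = k, n = n, levels = w$levels,
    group_levels = levels(grp), group = grp,
    group_n = as.integer(table(grp)),
    Y = Y, age_c = age_c, slope_age = slope,
    ms_between = ss_err_b / df_err_b,  # observation scale (subject-mean SS x k)
    ms_within = ss_err_w / df_err_w,
    df_between = df_err_b, df_within = df_err_w,
    within_name = within
  )
  class(out) <- "connsweep_anova"
  out
}

#' @export
print.connsweep_anova <- function(x, ...) {
  cat(sprintf("Mixed-design AN(C)OVA: %d participants (%s), %d within levels\n",
              x$n, paste(sprintf("%s n=%d", x$group_levels, x$group_n),
                         collapse = ", "), x$k))
  eff <- x$effects
  cat(sprintf("Mauchly W = %.3f (p = %.4f), GG epsilon = %.3f%s\n",
              x$sphericity$W, x$sphericity$p, x$sphericity$epsilon,
              if (x$gg_applied) " [GG correction applied]" else ""))
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-16s F(%.2f, %.2f) = %7.3f, p = %.4g\n",
                eff$effect[i],
                if (eff$stratum[i] == "within" && x$gg_applied)
                  eff$df1_adj[i] else eff$df[i],
                if (eff$stratum[i] == "within" && x$gg_applied)
                  eff$df2_adj[i] else eff$df_error[i],
                eff$F[i], eff$p_reported[i]))
  }
  invisible(x)
}

#' @export
summary.connsweep_anova <- function(object, ...) {
  list(effects = object$effects, sphericity = object$sphericity)
}

#' Doubly-multivariate omnibus MANCOVA
#'
#' Pillai's trace tests for group, age, network and group x network on the
#' vector of graph measures.  Between-subject effects are tested on
#' subject-mean measure vectors; within-subject effects on the orthonormal
#' network-contrast scores of every measure stacked into one multivariate
#' response.  Linearly dependent measure columns (e.g., a duplicated
#' measure) are dropped before testing, so degenerate inputs reduce to the
#' corresponding lower-dimensional analysis.
#'
#' @param table Long data.frame with one row per participant x network x
#'   measure: columns `participant`, `group`, `age`, `network`, `measure`,
#'   `value` (names configurable).
#' @param measures Character vector of measure names to include.
#' @param value,within,between,id,covariate,measure Column names.
#' @param n_families When > 1, an extra report column
#'   `sig_across_families` flags p-values below 0.05 / n_families (a
#'   Bonferroni note across parallel analysis families — a report flag,
#'   never a gate).
#' @return Object of class `connsweep_mancova`: a data.frame of effects
#'   with Pillai's V, approximate F, dfs and p.
#' @export
omnibus_mancova <- function(table, measures = c("dc", "cc", "ecc"),
                            value = "value", within = "network",
                            between = "group", id = "participant",
                            covariate = "age", measure = "measure",
                            n_families = 1L) {
  wides <- lapply(measures, function(mm) {
    sub <- table[table[[measure]] == mm, , drop = FALSE]
    if (nrow(sub) == 0L) stop("measure absent from table: ", mm)
    table_to_wide(sub, value, within, between, id, covariate)
  })
  w1 <- wides[[1L]]
  n <- w1$n; k <- w1$k
  for (ww in wides[-1L]) {
    if (!identical(ww$ids, w1$ids) || !identical(ww$levels, w1$levels)) {
      stop("measures do not share the same participant x level structure")
    }
  }
  # drop linearly dependent measures (rank handling for degenerate DV sets)
  flat <- vapply(wides, function(ww) as.vector(scale(as.vector(ww$Y),
                                                     scale = FALSE)),
                 numeric(n * k))
  qr_flat <- qr(flat)
  keep <- sort(qr_flat$pivot[seq_len(qr_flat$rank)])
  if (length(keep) < length(measures)) {
    warning("linearly dependent measures dropped: ",
            paste(measures[setdiff(seq_along(measures), keep)], collapse = ", "))
  }
  wides <- wides[keep]
  measures <- measures[keep]
  p_m <- length(measures)

  grp <- w1$group
  age_c <- if (is.null(w1$age)) NULL else w1$age - mean(w1$age)
  Xb <- stats::model.matrix(~grp, contrasts.arg = list(grp = "contr.sum"))
  g_rows <- 1L + seq_len(nlevels(grp) - 1L)
  a_row <- NULL
  if (!is.null(age_c)) {
    Xb <- cbind(Xb, age_c = age_c)
    a_row <- ncol(Xb)
  }
  pb <- ncol(Xb)
  ne <- n - pb
  XtXinv <- solve(crossprod(Xb))

  run_tests <- function(Zmat, label_map) {
    B <- XtXinv %*% crossprod(Xb, Zmat)
    E <- crossprod(Zmat - Xb %*% B)
    pdim <- ncol(Zmat)
    out <- list()
    for (nm in names(label_map)) {
      rowsel <- label_map[[nm]]
      H <- term_sscp(B, XtXinv, rowsel)
      V <- pillai_trace(H, E)
      fa <- pillai_f(V, pdim, length(rowsel), ne)
      out[[length(out) + 1L]] <- data.frame(
        effect = nm, pillai = V, F = fa$statistic,
        df1 = fa$df1, df2 = fa$df2, p = fa$p, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }

  M <- vapply(wides, function(ww) rowMeans(ww$Y), numeric(n))
  between_map <- list(group = g_rows)
  if (!is.null(a_row)) between_map$age <- a_row
  res_b <- run_tests(M, between_map)
  res_b$stratum <- "between"

  C <- orthonormal_contrasts(k)
  Zbig <- do.call(cbind, lapply(wides, function(ww) ww$Y %*% C))
  within_map <- list(network = 1L, `group:network` = g_rows)
  if (!is.null(a_row)) within_map$`age:network` <- a_row
  res_w <- run_tests(Zbig, within_map)
  res_w$stratum <- "within"

  out <- rbind(res_b, res_w)
  if (n_families > 1L) out$sig_across_families <- out$p < 0.05 / n_families
  attr(out, "measures") <- measures
  class(out) <- c("connsweep_mancova", "data.frame")
  out
}

#' @export
print.connsweep_mancova <- function(x, ...) {
  cat(sprintf("Omnibus MANCOVA (Pillai) on measures: %s\n",
              paste(attr(x, "measures"), collapse = ", ")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s V = %.3f, F(%g, %g) = %6.3f, p = %.4g\n",
                x$effect[i], x$pillai[i], x$df1[i], x$df2[i], x$F[i], x$p[i]))
  }
  invisible(x)
}

#' Tukey-adjusted within-level group contrasts
#'
#' Covariate-adjusted cell means per group x within-level; the contrast is
#' the first group level minus the second within each level.  The standard
#' error pools both error strata (`(MS_between + (k-1) MS_within) / k`)
#' with Satterthwaite degrees of freedom; the family of k contrasts is
#' adjusted by the studentized-range (Tukey) method with the number of
#' means chosen so its implied pairwise family matches the contrast count.
#'
#' By policy (mirroring the analysis pipeline), contrasts are refused
#' unless the upstream fit showed a significant group main effect or
#' group x within interaction; pass `force = TRUE` to override.
#'
#' @param fit A `connsweep_anova` from [mixed_ancova()] or
#'   [decomposition_anova()].
#' @param alpha Upstream significance gate (default 0.05).
#' @param force Skip the gate.
#' @return Object of class `connsweep_contrasts`: data.frame with `level`,
#'   `estimate`, `se`, `t`, `df`, `p`, `p_adj`.
#' @export
posthoc_contrasts <- function(fit, alpha = 0.05, force = FALSE) {
  stopifnot(inherits(fit, "connsweep_anova"))
  eff <- fit$effects
  gate <- eff$p_reported[eff$effect == "group"] < alpha ||
    any(eff$p_reported[grepl("^group:", eff$effect)] < alpha)
  if (!force && !isTRUE(gate)) {
    stop("no significant group main effect or group x within interaction; ",
         "post hoc contrasts refused (use force = TRUE to override)")
  }
  if (length(fit$group_levels) != 2L) {
    stop("post hoc group contrasts require exactly 2 groups")
  }
  g1 <- fit$group == fit$group_levels[1L]
  g2 <- fit$group == fit$group_levels[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  k <- fit$k
  # covariate-adjusted cell means (common between-stratum slope)
  adj1 <- if (is.null(fit$age_c)) 0 else fit$slope_age * mean(fit$age_c[g1])
  adj2 <- if (is.null(fit$age_c)) 0 else fit$slope_age * mean(fit$age_c[g2])
  mu1 <- colMeans(fit$Y[g1, , drop = FALSE]) - adj1
  mu2 <- colMeans(fit$Y[g2, , drop = FALSE]) - adj2
  est <- mu1 - mu2
  a <- 1 / k; b <- (k - 1) / k
  v_cell <- a * fit$ms_between + b * fit$ms_within
  df_sat <- v_cell^2 / ((a * fit$ms_between)^2 / fit$df_between +
                          (b * fit$ms_within)^2 / fit$df_within)
  v_contrast <- (1 / n1 + 1 / n2) * v_cell
  if (!is.null(fit$age_c)) {
    sxx <- sum(fit$age_c^2)
    v_slope <- (fit$ms_between / k) / sxx
    v_contrast <- v_contrast +
      (mean(fit$age_c[g1]) - mean(fit$age_c[g2]))^2 * v_slope
  }
  se <- sqrt(v_contrast)
  tval <- est / se
  m_fam <- k
  nmeans <- (1 + sqrt(1 + 8 * m_fam)) / 2
  p_unadj <- 2 * stats::pt(-abs(tval), df_sat)
  p_adj <- stats::ptukey(sqrt(2) * abs(tval), nmeans, df_sat,
                         lower.tail = FALSE)
  p_adj <- pmax(p_adj, p_unadj)
  out <- data.frame(
    level = fit$levels, estimate = as.numeric(est), se = se,
    t = as.numeric(tval), df = df_sat, p = as.numeric(p_unadj),
    p_adj = as.numeric(p_adj), stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- paste(fit$group_levels, collapse = " - ")
  attr(out, "family_size") <- m_fam
  class(out) <- c("connsweep_contrasts", "data.frame")
  out
}

#' @export
print.connsweep_contrasts <- function(x, ...) {
  cat(sprintf("Group contrasts (%s), Tukey-adjusted family of %d:\n",
              attr(x, "contrast"), attr(x, "family_size")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-20s %8.4f (SE %.4f)  t(%.1f) = %6.3f, p_adj = %.4g\n",
                x$level[i], x$estimate[i], x$se[i], x$df[i], x$t[i],
                x$p_adj[i]))
  }
  invisible(x)
}

#' Connectivity-decomposition mixed ANOVA
#'
#' The same split-plot machinery with the three connectivity types
#' (within, pair, rest) as the repeated-measure factor and group as the
#' between factor; no covariate.
#'
#' @param table Long data.frame with columns `participant`, `group`,
#'   `partition`, `value` (names configurable).
#' @param value,within,between,id Column names.
#' @param gg Greenhouse-Geisser policy, as in [mixed_ancova()].
#' @return A `connsweep_anova`.
#' @export
decomposition_anova <- function(table, value = "value", within = "partition",
                                between = "group", id = "participant",
                                gg = c("mauchly", "always", "never")) {
  mixed_ancova(table, value = value, within = within, between = between,
               id = id, covariate = NULL, gg = match.arg(gg))
}
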