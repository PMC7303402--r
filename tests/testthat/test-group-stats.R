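test_that("Pillai's trace matches closed forms and the eigenvalue oracle", {
  expect_equal(pillai_trace(matrix(0, 2, 2), diag(2)), 0)
  # single DV: V = SSH / (SSH + SSE)
  expect_equal(pillai_trace(matrix(3), matrix(1)), 0.75)
  set.seed(1)
  H <- crossprod(matrix(stats::rnorm(15), 5, 3))
  E <- crossprod(matrix(stats::rnorm(60), 20, 3))
  lam <- Re(eigen(solve(E) %*% H, only.values = TRUE)$values)
  expect_equal(pillai_trace(H, E), sum(lam / (1 + lam)), tolerance = 1e-10)
  # invariance under invertible linear transformation of the DVs
  M <- matrix(stats::rnorm(9), 3) + diag(3)
  expect_equal(pillai_trace(t(M) %*% H %*% M, t(M) %*% E %*% M),
               pillai_trace(H, E), tolerance = 1e-10)
  expect_error(pillai_trace(matrix(0, 2, 2), matrix(0, 2, 2)), "singular")
})

test_that("sphericity statistics match their eigenvalue oracles", {
  # compound symmetry: sphericity holds exactly
  cs <- 0.5 + diag(0.5, 5)
  sp <- sphericity(cs, df = 30)
  expect_equal(sp$epsilon, 1, tolerance = 1e-12)
  expect_equal(sp$W, 1, tolerance = 1e-12)
  # k = 2: a single contrast, epsilon 1 by construction
  sp2 <- sphericity(diag(c(1, 3)), df = 30)
  expect_equal(sp2$epsilon, 1)
  expect_equal(sp2$p, 1)
  # AR(1) covariances, k = 3..6: direct eigenvalue oracle
  for (k in 3:6) {
    S <- 0.8^abs(outer(seq_len(k), seq_len(k), "-"))
    sp_k <- sphericity(S, df = 40)
    C <- connsweep:::orthonormal_contrasts(k)
    lam <- eigen(t(C) %*% S %*% C, only.values = TRUE)$values
    expect_equal(sp_k$epsilon, sum(lam)^2 / ((k - 1) * sum(lam^2)),
                 tolerance = 1e-10)
    expect_equal(sp_k$W, prod(lam) / (mean(lam))^(k - 1), tolerance = 1e-10)
    expect_gte(sp_k$epsilon, 1 / (k - 1))
    expect_lte(sp_k$epsilon, 1)
  }
})

test_that("the split-plot ANCOVA reproduces the car Type III oracle", {
  set.seed(42)
  tab <- simulate_summary_table()
  fit <- mixed_ancova(tab)
  # independent oracle: multivariate lm + car::Anova with idata
  ids <- unique(tab$participant)
  nets <- unique(tab$network)
  Y <- matrix(NA_real_, length(ids), length(nets))
  for (i in seq_along(ids)) {
    sub <- tab[tab$participant == ids[i], ]
    Y[i, ] <- sub$value[match(nets, sub$network)]
  }
  first <- match(ids, tab$participant)
  grp <- factor(tab$group[first])
  age_c <- tab$age[first] - mean(tab$age[first])
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mod <- stats::lm(Y ~ grp + age_c)
  av <- car::Anova(mod, idata = data.frame(network = factor(nets, levels = nets)),
                   idesign = ~network, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  eff <- fit$effects
  pick <- function(e, col) eff[[col]][eff$effect == e]
  expect_equal(pick("group", "ss"), ut["grp", "Sum Sq"], tolerance = 1e-8)
  expect_equal(pick("age", "ss"), ut["age_c", "Sum Sq"], tolerance = 1e-8)
  expect_equal(pick("network", "ss"), ut["network", "Sum Sq"], tolerance = 1e-8)
  expect_equal(pick("group:network", "ss"), ut["grp:network", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(pick("group:network", "F"), ut["grp:network", "F value"],
               tolerance = 1e-8)
  expect_equal(pick("network", "p"), ut["network", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(fit$sphericity$W,
               unname(s$sphericity.tests["network", "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(fit$sphericity$epsilon,
               unname(s$pval.adjustments["network", "GG eps"]), tolerance = 1e-8)
  expect_equal(pick("group:network", "p_gg"),
               unname(s$pval.adjustments["grp:network", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  # error dfs of the documented layout
  expect_equal(pick("group", "df_error"), fit$n - 3)
  expect_equal(pick("group:network", "df_error"), (fit$n - 3) * (fit$k - 1))
})

test_that("between-factor F equals the squared pooled t on subject means", {
  set.seed(7)
  tab <- simulate_summary_table(n_hc = 10, n_ppv = 12)
  fit <- mixed_ancova(tab, covariate = NULL)
  ids <- unique(tab$participant)
  m <- vapply(ids, function(p) mean(tab$value[tab$participant == p]), numeric(1))
  g <- vapply(ids, function(p) tab$group[tab$participant == p][1], character(1))
  tt <- stats::t.test(m[g == "HC"], m[g == "PPV"], var.equal = TRUE)
  expect_equal(fit$effects$F[fit$effects$effect == "group"],
               unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("degenerate inputs are refused", {
  tab <- simulate_summary_table(n_hc = 4, n_ppv = 4)
  tab$value <- 1
  expect_error(mixed_ancova(tab), "degenerate")
  tab2 <- simulate_summary_table(n_hc = 4, n_ppv = 4)
  expect_error(mixed_ancova(tab2[-1, ]), "incomplete crossing")
})

test_that("the omnibus MANCOVA reduces duplicated measures by rank", {
  set.seed(8)
  tab <- simulate_summary_table(measure_names = c("dc", "cc", "ecc"))
  om <- omnibus_mancova(tab)
  expect_s3_class(om, "connsweep_mancova")
  expect_setequal(om$effect, c("group", "age", "network", "group:network",
                               "age:network"))
  expect_true(all(om$p >= 0 & om$p <= 1))
  expect_true(all(om$pillai >= 0))
  # the multi-family Bonferroni note is a report flag, not a gate
  om3 <- omnibus_mancova(tab, n_families = 3L)
  expect_equal(om3$sig_across_families, om3$p < 0.05 / 3)
  expect_equal(om3$p, om$p)
  # duplicated DV set collapses to the single-measure analysis
  dup <- tab[tab$measure == "dc", ]
  dup2 <- dup; dup2$measure <- "dc2"
  dup3 <- dup; dup3$measure <- "dc3"
  both <- rbind(dup, dup2, dup3)
  expect_warning(om_dup <- omnibus_mancova(both, measures = c("dc", "dc2", "dc3")),
                 "dependent")
  om_one <- omnibus_mancova(dup, measures = "dc")
  expect_equal(om_dup$pillai, om_one$pillai, tolerance = 1e-10)
  expect_equal(om_dup$F, om_one$F, tolerance = 1e-10)
  expect_equal(om_dup$p, om_one$p, tolerance = 1e-10)
})

test_that("omnibus interaction keeps nominal size and gains power from any DV", {
  set.seed(9)
  rej_null <- replicate(200, {
    tab <- simulate_summary_table(n_hc = 12, n_ppv = 12,
                                  measure_names = c("dc", "cc", "ecc"))
    om <- omnibus_mancova(tab)
    om$p[om$effect == "group:network"] < 0.05
  })
  # 200-rep binomial band around 0.05
  expect_gte(mean(rej_null), qbinom(0.005, 200, 0.05) / 200)
  expect_lte(mean(rej_null), qbinom(0.995, 200, 0.05) / 200)
  # effect present only in ecc: omnibus detects, dc-only univariate does not
  res <- replicate(100, {
    tab <- simulate_summary_table(measure_names = c("dc", "cc"))
    ecc <- simulate_summary_table(
      measure_names = "ecc",
      group_network_effect = list(group = "PPV", network = "sensorimotor",
                                  delta = 1.2))
    tab <- rbind(tab, ecc)
    om <- omnibus_mancova(tab)
    fit_dc <- mixed_ancova(tab[tab$measure == "dc", ])
    c(omni = om$p[om$effect == "group:network"] < 0.05,
      dc = fit_dc$effects$p_reported[fit_dc$effects$effect == "group:network"] < 0.05)
  })
  expect_gt(mean(res["omni", ]), mean(res["dc", ]) + 0.3)
})

test_that("post hoc contrasts are gated, adjusted monotonically, and FWER-controlling", {
  set.seed(10)
  # a null fit will usually fail the gate
  tab <- simulate_summary_table()
  fit <- mixed_ancova(tab)
  if (all(fit$effects$p_reported[fit$effects$effect %in%
                                 c("group", "group:network")] >= 0.05)) {
    expect_error(posthoc_contrasts(fit), "refused")
  }
  ph <- posthoc_contrasts(fit, force = TRUE)
  expect_s3_class(ph, "connsweep_contrasts")
  expect_equal(nrow(ph), 6L)
  expect_true(all(ph$p_adj >= ph$p - 1e-12))
  expect_true(all(ph$p_adj <= 1))
  # family-wise error under the null across the 6 contrasts
  fam <- replicate(400, {
    t0 <- simulate_summary_table(n_hc = 10, n_ppv = 10)
    f0 <- mixed_ancova(t0)
    any(posthoc_contrasts(f0, force = TRUE)$p_adj < 0.05)
  })
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lte(mean(fam), 0.05 + 3 * mc_se)  # controls FWER
  expect_gte(mean(fam), 0.001)             # and is not vacuous
})

test_that("the interaction ANCOVA is calibrated and recovers injected effects", {
  set.seed(11)
  rej <- replicate(300, {
    tab <- simulate_summary_table()
    fit <- mixed_ancova(tab)
    fit$effects$p_reported[fit$effects$effect == "group:network"] < 0.05
  })
  expect_gte(mean(rej), qbinom(0.005, 300, 0.05) / 300)
  expect_lte(mean(rej), qbinom(0.995, 300, 0.05) / 300)
  pow <- replicate(100, {
    tab <- simulate_summary_table(
      group_network_effect = list(group = "PPV", network = "sensorimotor",
                                  delta = 1))
    fit <- mixed_ancova(tab)
    fit$effects$p_reported[fit$effects$effect == "group:network"] < 0.05
  })
  expect_gte(mean(pow), 0.8)
})

test_that("the decomposition ANOVA runs the same machinery without covariate", {
  set.seed(12)
  tab <- simulate_summary_table(networks = c("within", "pair", "rest"))
  names(tab)[names(tab) == "network"] <- "partition"
  fit <- decomposition_anova(tab)
  expect_setequal(fit$effects$effect, c("group", "network", "group:network"))
  expect_equal(fit$k, 3L)
  tab$value <- 0
  expect_error(decomposition_anova(tab), "degenerate")
  # an injected within-type group gap drives the interaction, and the
  # post hoc contrast localizes it to the right connectivity type
  res <- replicate(100, {
    t1 <- simulate_summary_table(networks = c("within", "pair", "rest"),
                                 group_network_effect = list(
                                   group = "PPV", network = "within",
                                   delta = 1))
    names(t1)[names(t1) == "network"] <- "partition"
    f1 <- decomposition_anova(t1)
    ph <- posthoc_contrasts(f1, force = TRUE)
    c(int = f1$effects$p_reported[f1$effects$effect == "group:network"] < 0.05,
      right = ph$p_adj[ph$level == "within"] < 0.05,
      wrong = any(ph$p_adj[ph$level != "within"] < 0.05))
  })
  expect_gte(mean(res["int", ]), 0.8)
  expect_gt(mean(res["right", ]), mean(res["wrong", ]) + 0.2)
})
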