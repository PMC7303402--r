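test_that("nuisance PCA recovers a known signal subspace", {
  set.seed(1)
  T_ <- 200
  tt <- seq_len(T_)
  sins <- vapply(1:5, function(k) sin(2 * pi * k * tt / T_), numeric(T_))
  mix <- matrix(stats::rnorm(5 * 8), 5, 8)
  x <- sins %*% mix + 1e-6 * matrix(stats::rnorm(T_ * 8), T_)
  pcs <- nuisance_pca(x, 5)
  expect_equal(dim(pcs), c(T_, 5L))
  # principal angles between recovered and true subspaces
  qa <- qr.Q(qr(pcs)); qb <- qr.Q(qr(scale(sins, scale = FALSE)))
  angles <- acos(pmin(1, svd(crossprod(qa, qb))$d))
  expect_lt(max(angles), 1e-3)
  # components ordered by explained variance
  expect_true(all(diff(apply(pcs, 2, stats::var)) <= 1e-12))
})

test_that("nuisance PCA handles rank deficiency and channel duplication", {
  const <- matrix(5, 50, 6)
  expect_warning(pcs <- nuisance_pca(const, 5), "rank 0")
  expect_equal(ncol(pcs), 0L)
  set.seed(2)
  x <- matrix(stats::rnorm(50 * 6), 50)
  p1 <- nuisance_pca(x, 5)
  p2 <- nuisance_pca(cbind(x, x), 5)
  # duplication rescales but does not rotate the components
  expect_equal(abs(diag(stats::cor(p1, p2))), rep(1, 5), tolerance = 1e-10)
})

test_that("confound regression produces exact OLS residuals", {
  set.seed(3)
  T_ <- 80
  conf <- matrix(stats::rnorm(T_ * 4), T_)
  # a series equal to a confound column is annihilated
  res <- regress_confounds(conf[, 2, drop = FALSE], conf)
  expect_lt(max(abs(res)), 1e-10)
  # confounds orthogonal to a centered series leave it unchanged
  y <- stats::rnorm(T_)
  yc <- y - mean(y)
  X <- qr.Q(qr(cbind(1, conf)))[, -1]  # orthonormal, orthogonal to constant
  yo <- yc - X %*% crossprod(X, yc)    # orthogonalize
  expect_equal(as.numeric(regress_confounds(yo, X)), as.numeric(yo),
               tolerance = 1e-10)
  # residuals orthogonal to every confound column (normal equations)
  ts <- matrix(stats::rnorm(T_ * 5), T_)
  r <- regress_confounds(ts, conf)
  expect_lt(max(abs(crossprod(conf, r))), 1e-8)
  expect_lt(max(abs(colSums(r))), 1e-8)  # intercept always included
  # invariance to invertible recombination of the confounds
  M <- matrix(stats::rnorm(16), 4) + diag(4)
  expect_equal(r, regress_confounds(ts, conf %*% M), tolerance = 1e-8)
  expect_error(regress_confounds(ts[1:4, ], conf[1:4, ]), "confounds")
})

test_that("DCT high-pass removes drift and preserves signal, with no low-pass", {
  T_ <- 260; tr <- 2.45
  tt <- (seq_len(T_) - 1) * tr
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- highpass_dct(matrix(x), tr, 0.008)
    stats::sd(y) / stats::sd(x)
  }
  expect_lt(amp_ratio(0.002), 0.05)            # drift attenuated > 95%
  expect_equal(amp_ratio(0.05), 1, tolerance = 0.05)   # passband preserved
  expect_equal(amp_ratio(0.15), 1, tolerance = 0.05)   # no low-pass
  expect_equal(as.numeric(highpass_dct(matrix(3, T_), tr)), rep(0, T_))
  expect_error(highpass_dct(matrix(stats::rnorm(20)), tr = 100, cutoff = 0.1),
               "cutoff too high")
})

test_that("detrend removes lines and despike soft-clips large excursions", {
  tt <- 1:100
  line <- matrix(2 + 0.3 * tt)
  expect_lt(max(abs(detrend_despike(line))), 1e-10)
  set.seed(4)
  x <- stats::rnorm(200)
  x[100] <- 10
  rsd_in <- 1.4826 * stats::mad(x - stats::median(x))
  y <- detrend_despike(matrix(x))[, 1]
  expect_lt(abs(y[100] - stats::median(y)), 3.5 * rsd_in)
  # values within one sd are nearly unchanged (tanh(x) ~ x there)
  z <- stats::rnorm(500)
  zd <- detrend_despike(matrix(z))[, 1]
  zl <- z - cbind(1, 1:500) %*% qr.coef(qr(cbind(1, 1:500)), z)  # detrend only
  s_z <- stats::sd(zl)
  inner <- abs(zl - stats::median(zl)) <= s_z
  expect_lt(max(abs(zd - zl)[inner]) / s_z, 0.06)
  expect_warning(detrend_despike(cbind(stats::rnorm(10), rep(1, 10))),
                 "zero MAD")
  expect_error(detrend_despike(matrix(1:2)), "at least 3")
})

test_that("spike regressors are one-hot and zero their frames' residuals", {
  fd <- rep(0.1, 30)
  expect_equal(ncol(spike_regressors(fd)), 0L)
  fd[c(5, 12, 20)] <- 1
  sp <- spike_regressors(fd, 0.5)
  expect_equal(dim(sp), c(30L, 3L))
  expect_equal(colSums(sp), rep(1, 3))
  expect_equal(which(rowSums(sp) == 1), c(5L, 12L, 20L))
  set.seed(5)
  ts <- matrix(stats::rnorm(30 * 3), 30)
  res <- regress_confounds(ts, cbind(matrix(stats::rnorm(30 * 2), 30), sp))
  expect_lt(max(abs(res[c(5, 12, 20), ])), 1e-10)
  expect_error(spike_regressors(rep(2, 5), 0.5), "nothing left")
  expect_error(spike_regressors(fd, -1), "positive")
})

test_that("the full cleaning chain runs in fixed order and annihilates task signal", {
  set.seed(6)
  co <- simulate_cohort(atlas = tiny_atlas(2L),
                        design = make_design(2.45, 120, 27.5, 2),
                        effects = effect_config(n_hc = 1, n_ppv = 1, seed = 3))
  b <- co$bundles[[1]]
  cleaned <- clean_timeseries(b)
  expect_equal(dim(cleaned), dim(b$roi_signals))
  # task regressors and realignment parameters are no longer in the data
  task <- cbind(block_regressor(b$design, "motion"),
                block_regressor(b$design, "static"))
  proj <- crossprod(scale(task, scale = FALSE), scale(cleaned, scale = FALSE))
  norm1 <- sqrt(colSums(scale(task, scale = FALSE)^2))
  norm2 <- sqrt(colSums(scale(cleaned, scale = FALSE)^2))
  cors <- abs(proj / outer(norm1, norm2))
  expect_lt(max(cors), 0.2)  # regression happened before the nonlinear steps
  # spike-regression mode runs
  expect_silent(clean_timeseries(b, spike_fd_mm = 10))
})
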