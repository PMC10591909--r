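test_that("stratified resampling preserves group sizes, balanced or not", {
  ds <- exp_study(n = 3)
  set.seed(1)
  expect_equal(group_sizes(stratified_resample(ds)),
               c(C = 3L, A = 3L, B = 3L, AB = 3L))

  rows <- list()
  sizes <- c(C = 10, A = 8, B = 9, AB = 10)
  for (g in names(sizes)) {
    for (i in seq_len(sizes[[g]])) {
      rows[[length(rows) + 1L]] <- exp_curve(paste0(g, i), g, 0.05)
    }
  }
  ds2 <- as_study_dataset(dplyr::bind_rows(rows))
  set.seed(2)
  expect_equal(group_sizes(stratified_resample(ds2)),
               c(C = 10L, A = 8L, B = 9L, AB = 10L))
})

test_that("resampling is deterministic given the RNG state", {
  ds <- jitter_study(21)
  set.seed(77)
  r1 <- stratified_resample(ds)
  set.seed(77)
  r2 <- stratified_resample(ds)
  expect_equal(r1, r2)
})

test_that("BCa matches the independent Efron-formula oracle on random sets", {
  set.seed(31)
  for (i in 1:25) {
    # skewed synthetic bootstrap and jackknife distributions
    boot <- exp(rnorm(400, 0, runif(1, 0.2, 1.5))) + rnorm(1)
    jack <- exp(rnorm(sample(8:25, 1), 0, 0.5))
    obs <- quantile(boot, runif(1, 0.2, 0.8), names = FALSE)
    lvl <- sample(c(0.8, 0.9, 0.95), 1)
    got <- bca_interval(boot, obs, jack, lvl)
    want <- bca_oracle(boot, obs, jack, lvl)
    expect_equal(got$lower, want[["lower"]], tolerance = 1e-10)
    expect_equal(got$upper, want[["upper"]], tolerance = 1e-10)
  }
})

test_that("with no bias or acceleration BCa reduces to the percentile interval", {
  boot <- seq(-1, 1, length.out = 1001)  # symmetric, obs at the median
  jack <- seq(-0.1, 0.1, length.out = 11)  # zero skewness
  got <- bca_interval(boot, 0, jack, 0.95)
  expect_equal(got$z0, 0, tolerance = 1e-12)
  expect_equal(got$a, 0, tolerance = 1e-12)
  expect_equal(got$lower, quantile(boot, 0.025, names = FALSE), tolerance = 1e-9)
  expect_equal(got$upper, quantile(boot, 0.975, names = FALSE), tolerance = 1e-9)
})

test_that("a point-mass bootstrap distribution collapses to a flagged point interval", {
  got <- bca_interval(rep(3.2, 100), 3.2, rep(3.2, 5), 0.95)
  expect_true(got$degenerate)
  expect_equal(c(got$lower, got$upper), c(3.2, 3.2))
  p <- bootstrap_pvalue(rep(3.2, 100), 3.2, rep(3.2, 5), 0)
  expect_true(p$degenerate)
  expect_true(is.na(p$p))
})

test_that("P value floors at 1/n_boot under complete separation and is ~1 for a central null", {
  set.seed(32)
  boot <- rnorm(500, 10, 1)
  jack <- rnorm(12, 10, 0.3)
  p <- bootstrap_pvalue(boot, 10, jack, null_value = 0)
  expect_equal(p$p, 1 / 500)
  p2 <- bootstrap_pvalue(boot, 10, jack, null_value = median(boot))
  expect_gt(p2$p, 0.9)
})

test_that("P < alpha exactly when the null lies outside the 1-alpha BCa interval", {
  set.seed(33)
  for (i in 1:20) {
    boot <- exp(rnorm(300, 0, 0.7)) - 1
    jack <- exp(rnorm(10, 0, 0.4)) - 1
    obs <- median(boot)
    null_value <- rnorm(1, 0, 0.8)
    p <- bootstrap_pvalue(boot, obs, jack, null_value)$p
    for (alpha in c(0.01, 0.05, 0.2)) {
      int <- bca_interval(boot, obs, jack, level = 1 - alpha)
      outside <- null_value < int$lower || null_value > int$upper
      if (abs(p - alpha) > 1e-6) expect_equal(p < alpha, outside)
    }
  }
})

test_that("bootstrap_synergy is reproducible and internally consistent", {
  ds <- jitter_study(51, n = 5)
  i1 <- bootstrap_synergy(ds, "bliss", n_boot = 300, seed = 9)
  i2 <- bootstrap_synergy(ds, "bliss", n_boot = 300, seed = 9)
  expect_equal(i1$boot, i2$boot)
  expect_equal(i1$p, i2$p)
  expect_equal(i1$intervals, i2$intervals)
  # every replicate satisfies sign(ci - 1) == sign(-ss)
  expect_equal(sign(i1$boot$ci - 1), sign(-i1$boot$ss))
  # interval ordering
  expect_true(all(i1$intervals$lower <= i1$intervals$upper))
})

test_that("the fast eGR-level resampling equals resampling whole curves", {
  ds <- jitter_study(52, n = 4)
  per <- group_egr(ds)$mouse
  # one replicate by hand through stratified_resample, same seed path
  set.seed(123)
  rs <- stratified_resample(ds)
  est_curves <- synergy_estimate(group_egr(rs), "bliss", 21)
  set.seed(123)
  means <- sapply(c("C", "A", "B", "AB"), function(g) {
    v <- per$egr[per$group == g]
    mean(v[sample.int(length(v), length(v), replace = TRUE)])
  })
  est_egrs <- synergy_estimate(means, "bliss", 21)
  expect_equal(est_curves$ci, est_egrs$ci, tolerance = 1e-12)
  expect_equal(est_curves$ss, est_egrs$ss, tolerance = 1e-12)
})

test_that("identical additive curves in every arm give a degenerate point-mass bootstrap", {
  k <- c(C = 0.10, A = 0.06, B = 0.07, AB = 0.03)  # AB = A + B - C
  ds <- exp_study(k = k, n = 4)
  inf <- bootstrap_synergy(ds, "bliss", n_boot = 100, seed = 3)
  expect_equal(inf$observed$ci, 1, tolerance = 1e-10)
  expect_equal(inf$observed$ss, 0, tolerance = 1e-8)
  expect_true(all(inf$degenerate))
  expect_true(all(inf$intervals$degenerate))
})

test_that("the CI P value is exactly invariant to the evaluation time", {
  ds <- jitter_study(53, n = 5)
  runs <- lapply(c(7, 14, 21, 42), function(t_eval) {
    bootstrap_synergy(ds, "bliss", t_eval = t_eval, n_boot = 400, seed = 17)
  })
  ps <- sapply(runs, function(r) r$p[["ci"]])
  expect_equal(ps, rep(ps[1], 4), tolerance = 1e-12)
  cis <- sapply(runs, function(r) r$observed$ci)
  expect_equal(length(unique(round(cis, 6))), 4)  # magnitudes do change
  # SS keeps its sign across t
  expect_equal(length(unique(sign(sapply(runs, function(r) r$observed$ss)))), 1)
})
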