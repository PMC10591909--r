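egr_example <- c(C = 0.099, A = 0.066, B = 0.073, AB = 0.030)

test_that("relative survival evaluates the exponential contrast", {
  s <- relative_survival(c(C = 0.099, A = 0.066, B = 0.099, AB = 0.05), 21)
  expect_equal(s[["A"]], exp(-0.693), tolerance = 1e-3)
  expect_equal(s[["B"]], 1)  # no-effect drug
  s2 <- relative_survival(c(C = 0.05, A = 0.08, B = 0.04, AB = 0.03), 21)
  expect_gt(s2[["A"]], 1)    # growth acceleration allowed
  expect_error(relative_survival(egr_example, 0), "positive")
  expect_error(relative_survival(c(C = 0.1, A = 0.05, B = 0.06)), "AB")
})

test_that("worked example: CI and SS under both models", {
  s <- relative_survival(egr_example, 21)
  expect_equal(unname(s), c(0.500, 0.579, 0.235), tolerance = 2e-3)
  est_b <- synergy_estimate(egr_example, "bliss", 21)
  expect_equal(est_b$ci, 0.811, tolerance = 1e-3)
  expect_equal(est_b$ss, 5.5, tolerance = 0.02)
  expect_equal(est_b$verdict, "synergy")
  est_h <- synergy_estimate(egr_example, "hsa", 21)
  expect_equal(est_h$ci, 0.470, tolerance = 1e-3)
})

test_that("Bliss CI equals its closed form through the survival path", {
  set.seed(7)
  for (i in 1:25) {
    e <- stats::rnorm(4, 0.07, 0.04)
    names(e) <- c("C", "A", "B", "AB")
    t_eval <- stats::runif(1, 1, 60)
    expect_equal(combination_index(e, "bliss", t_eval),
                 exp(t_eval * (e[["C"]] + e[["AB"]] - e[["A"]] - e[["B"]])),
                 tolerance = 1e-12)
  }
})

test_that("exact additivity gives CI = 1 and SS = 0", {
  e <- c(C = 0.10, A = 0.06, B = 0.07, AB = 0.06 + 0.07 - 0.10)
  expect_equal(combination_index(e, "bliss"), 1, tolerance = 1e-12)
  expect_equal(synergy_score(e, "bliss"), 0, tolerance = 1e-12)
  expect_equal(synergy_estimate(e, "bliss")$verdict, "additivity")
})

test_that("sign consistency: (ci - 1) and -ss always share sign", {
  set.seed(8)
  for (i in 1:50) {
    e <- stats::rnorm(4, 0.06, 0.05)
    names(e) <- c("C", "A", "B", "AB")
    for (m in c("bliss", "hsa")) {
      est <- synergy_estimate(e, m, 21)
      expect_equal(sign(est$ci - 1), sign(-est$ss))
    }
  }
})

test_that("HSA is at most Bliss when both single agents are effective", {
  set.seed(9)
  for (i in 1:50) {
    kc <- stats::runif(1, 0.05, 0.15)
    e <- c(C = kc, A = stats::runif(1, 0, kc), B = stats::runif(1, 0, kc),
           AB = stats::rnorm(1, 0.02, 0.03))
    expect_lte(combination_index(e, "hsa"),
               combination_index(e, "bliss") + 1e-12)
  }
})

test_that("evaluation time scales CI/SS magnitude but never flips the verdict", {
  set.seed(10)
  for (i in 1:30) {
    e <- stats::rnorm(4, 0.06, 0.04)
    names(e) <- c("C", "A", "B", "AB")
    for (m in c("bliss", "hsa")) {
      c1 <- combination_index(e, m, 7)
      c2 <- combination_index(e, m, 42)
      expect_equal(sign(c1 - 1), sign(c2 - 1))
      expect_equal(sign(synergy_score(e, m, 7)), sign(synergy_score(e, m, 42)))
    }
  }
})

test_that("local single-day Bliss index reproduces the log-ratio example", {
  # construct one mouse per arm with relative TV exactly mu at day 7
  mk <- function(g, mu) tibble::tibble(mouse = paste0(g, 1), group = g,
                                       day = c(0, 7), tv = c(100, 100 * mu))
  ds <- as_study_dataset(dplyr::bind_rows(
    mk("C", 8), mk("A", 4), mk("B", 4.63), mk("AB", 1.88)
  ))
  l <- local_bliss_ci(ds, 7)
  expect_equal(l$local_ci, log(4 * 4.63 / (8 * 1.88)), tolerance = 1e-12)
  expect_equal(l$local_ci, 0.208, tolerance = 1e-3)
  expect_gt(l$local_ci, 0)  # baseline orientation: > 0 is synergy
  # delta bookkeeping
  expect_equal(l$delta[["A"]], (8 - 4) / 8, tolerance = 1e-12)

  # additive: mu_AB = mu_A * mu_B / mu_C -> local CI 0
  ds2 <- as_study_dataset(dplyr::bind_rows(
    mk("C", 8), mk("A", 4), mk("B", 4.63), mk("AB", 4 * 4.63 / 8)
  ))
  expect_equal(local_bliss_ci(ds2, 7)$local_ci, 0, tolerance = 1e-12)
})

test_that("the baseline is not computable past any arm's last measurement", {
  rows <- dplyr::bind_rows(
    exp_curve("C1", "C", 0.12, days = c(0, 4, 7, 10, 14)),  # euthanized early
    exp_curve("A1", "A", 0.06), exp_curve("B1", "B", 0.07),
    exp_curve("AB1", "AB", 0.02)
  )
  ds <- as_study_dataset(rows)
  expect_false(local_bliss_ci(ds, 21)$computable)
  g <- global_ci(ds)
  expect_equal(g$days_used, c(0, 4, 7, 10, 14))
  expect_equal(g$gci,
               mean(g$per_day$local_ci[g$per_day$computable]))
})

test_that("identical curves in all arms give all-zero local values and gCI 0", {
  k <- 0.08
  rows <- dplyr::bind_rows(lapply(c("C", "A", "B", "AB"), function(g) {
    exp_curve(paste0(g, 1), g, k)
  }))
  g <- global_ci(as_study_dataset(rows))
  expect_equal(g$gci, 0, tolerance = 1e-12)
  expect_equal(max(abs(g$per_day$local_ci)), 0, tolerance = 1e-12)
})

test_that("a delayed combo effect visible to eGR is missed by the early-truncated baseline", {
  # control drops out by ~day 18; A and AB kick in only at day 10
  sc <- sim_scenario(n_per_group = 6, tgi = c(A = 0.5, B = 0.4, AB = 0.9),
                     t_ki = c(A = 10, AB = 10), dt = 5, t_obs = 42,
                     cvk = 0.05, sigma = 0.05, tv_max = 2000)
  ds <- simulate_study(sc, seed = 12)
  g <- global_ci(ds)
  expect_lt(max(g$days_used), sc$t_obs)  # late days not usable
  est <- synergy_estimate(suppressWarnings(group_egr(ds)), "bliss", 21)
  expect_lt(est$ci, 1)  # the rate-based metric still sees the combo effect
})
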