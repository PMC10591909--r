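#' Empirical power at one design point
#'
#' Simulates `n_sim` independent studies under the scenario, analyzes each
#' with the stratified BCa bootstrap, and reports the proportion with
#' P < `alpha` — the empirical power (or, under an additive scenario, the
#' empirical type-I error). Replicate seeds are derived deterministically
#' from `seed`, so a run is exactly reproducible. A simulated study in which
#' some arm has no analyzable curve (extreme truncation) is regenerated from
#' the next seed in the stream and counted; replicates with a degenerate
#' bootstrap distribution are excluded from the denominator and counted.
#'
#' @param scenario a [sim_scenario()].
#' @param n_sim number of simulated studies (default 100).
#' @param alpha significance threshold (default 0.05).
#' @param model `"bliss"` or `"hsa"`.
#' @param statistic which P value to count, `"ss"` (default, the synergy
#'   score) or `"ci"`.
#' @param n_boot bootstrap replicates per analysis (default 1000; reduced
#'   values trade accuracy of each P value for speed and are labeled in the
#'   output).
#' @param t_eval evaluation time in days.
#' @param seed master seed for the replicate stream.
#' @return one-row tibble: `power`, `successes`, `n_effective`, `n_sim`,
#'   `ci_low`/`ci_high` (Clopper-Pearson 95% interval for the power),
#'   `n_regenerated`, `n_degenerate`, plus `alpha`, `model`, `statistic`,
#'   `n_boot`.
#' @export
estimate_power <- function(scenario, n_sim = 100, alpha = 0.05,
                           model = "bliss", statistic = c("ss", "ci"),
                           n_boot = 1000, t_eval = 21, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(scenario, "sim_scenario"), n_sim >= 1,
            alpha > 0, alpha < 1)
  set.seed(seed)
  seeds <- sample.int(2147483646L, 4L * n_sim)
  ptr <- 0L
  next_seed <- function() {
    ptr <<- ptr + 1L
    if (ptr > length(seeds)) stop("seed stream exhausted", call. = FALSE)
    seeds[ptr]
  }

  pvals <- rep(NA_real_, n_sim)
  n_regen <- 0L
  for (i in seq_len(n_sim)) {
    repeat {
      ds <- simulate_study(scenario, seed = next_seed())
      if (all(group_sizes(ds, analyzable_only = TRUE) >= 1)) break
      n_regen <- n_regen + 1L
    }
    inf <- suppressWarnings(
      bootstrap_synergy(ds, model = model, t_eval = t_eval,
                        n_boot = n_boot, seed = next_seed())
    )
    pvals[i] <- inf$p[[statistic]]
  }
  n_degen <- sum(is.na(pvals))
  n_eff <- n_sim - n_degen
  succ <- sum(pvals < alpha, na.rm = TRUE)
  bt <- stats::binom.test(succ, max(n_eff, 1))
  tibble(
    power = if (n_eff > 0) succ / n_eff else NA_real_,
    successes = succ, n_effective = n_eff, n_sim = n_sim,
    ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
    n_regenerated = n_regen, n_degenerate = n_degen,
    alpha = alpha, model = model, statistic = statistic, n_boot = n_boot
  )
}

# Rebuild a scenario with some design parameters replaced; the schedule is
# regenerated when t_obs changes.
update_scenario <- function(scenario, n_per_group = NULL, dt = NULL,
                            tv_max = NULL, t_obs = NULL) {
  s <- scenario
  if (!is.null(n_per_group)) s$n_per_group <- as.integer(n_per_group)
  if (!is.null(dt)) s$k_mean <- log(2) / dt
  if (!is.null(tv_max)) s$tv_max <- tv_max
  if (!is.null(t_obs)) {
    s$t_obs <- t_obs
    s$schedule <- default_schedule(t_obs)
  }
  class(s) <- "sim_scenario"
  s
}

#' Empirical power over a design grid
#'
#' Runs [estimate_power()] at every combination of the supplied design
#' parameters (mice per group, doubling time, euthanasia cutoff, study
#' duration). Each grid point gets its own child seed derived from the
#' master seed, so points are independent and the whole grid is reproducible.
#'
#' @param scenario the template [sim_scenario()].
#' @param grid named list with any of `n_per_group`, `dt`, `tv_max`,
#'   `t_obs`, each a vector of values; the full factorial crossing is
#'   evaluated.
#' @inheritParams estimate_power
#' @return a `power_result` tibble: one row per grid point with the grid
#'   values and the [estimate_power()] columns.
#' @export
power_grid <- function(scenario, grid, n_sim = 100, alpha = 0.05,
                       model = "bliss", statistic = "ss", n_boot = 1000,
                       t_eval = 21, seed = 1) {
  stopifnot(is.list(grid), length(grid) >= 1)
  bad <- setdiff(names(grid), c("n_per_group", "dt", "tv_max", "t_obs"))
  if (length(bad) > 0 || is.null(names(grid)) || any(names(grid) == "")) {
    stop("grid entries must be named n_per_group, dt, tv_max or t_obs",
         call. = FALSE)
  }
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  point_seeds <- sample.int(2147483646L, nrow(points))
  rows <- lapply(seq_len(nrow(points)), function(i) {
    pt <- as.list(points[i, , drop = FALSE])
    sc <- update_scenario(scenario,
                          n_per_group = pt$n_per_group, dt = pt$dt,
                          tv_max = pt$tv_max, t_obs = pt$t_obs)
    res <- estimate_power(sc, n_sim = n_sim, alpha = alpha, model = model,
                          statistic = statistic, n_boot = n_boot,
                          t_eval = t_eval, seed = point_seeds[i])
    dplyr::bind_cols(as_tibble(points[i, , drop = FALSE]), res)
  })
  structure(dplyr::bind_rows(rows),
            class = c("power_result", class(tibble())))
}
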