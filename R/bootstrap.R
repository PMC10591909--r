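#' Stratified resample of a study dataset
#'
#' Resamples mice (whole growth curves) with replacement within each
#' treatment arm, the arm serving as the stratum, so every resample keeps the
#' original group sizes and within-mouse correlation. Groups are drawn in the
#' fixed order C, A, B, AB so results are reproducible from the RNG state. A
#' mouse drawn twice becomes two curves with distinct synthetic ids.
#'
#' @param ds a `study_dataset`.
#' @return a `study_dataset` of the same group sizes.
#' @export
stratified_resample <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  x <- as_tibble(ds)
  curves <- split(x, x$mouse)
  mice <- study_mice(ds)
  pieces <- list()
  for (g in GROUPS) {
    ids <- mice$mouse[mice$group == g]
    idx <- sample.int(length(ids), length(ids), replace = TRUE)
    for (j in seq_along(idx)) {
      cv <- curves[[ids[idx[j]]]]
      cv$mouse <- paste0(g, "_bs", j, ".", cv$mouse[1])
      pieces[[length(pieces) + 1L]] <- cv
    }
  }
  new_study_dataset(dplyr::bind_rows(pieces))
}

# Interpolated quantile of sorted values (R type-7 convention).
sorted_quantile <- function(xs, p) {
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

bca_terms <- function(boot_values, observed, jackknife_values) {
  b <- boot_values[is.finite(boot_values)]
  n_b <- length(b)
  frac <- (sum(b < observed) + 0.5 * sum(b == observed)) / n_b
  clamped <- frac <= 0 || frac >= 1
  frac <- min(max(frac, 1 / (n_b + 1)), n_b / (n_b + 1))
  z0 <- stats::qnorm(frac)
  jm <- mean(jackknife_values)
  dev <- jm - jackknife_values
  denom <- sum(dev^2)^1.5
  a <- if (denom == 0) 0 else sum(dev^3) / (6 * denom)
  list(z0 = z0, a = a, clamped = clamped)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard Efron BCa interval: the bias-correction `z0` is the normal
#' quantile of the fraction of bootstrap values below the observed estimate
#' (ties counted half), the acceleration `a` is the jackknife skewness
#' `sum((m - x_i)^3) / (6 * sum((m - x_i)^2)^{3/2})`, and the endpoints are
#' the bootstrap distribution's quantiles at the adjusted levels
#' `pnorm(z0 + (z0 + z_alpha) / (1 - a (z0 + z_alpha)))` (linear
#' interpolation of order statistics). Degenerate bootstrap distributions
#' (all values identical) collapse to a point interval with a diagnostic
#' flag; adjusted levels that fall outside the achievable range are clamped
#' to the extreme order statistics, also flagged.
#'
#' @param boot_values bootstrap replicates of the statistic.
#' @param observed the observed (full-data) statistic.
#' @param jackknife_values leave-one-out re-estimates of the statistic.
#' @param level confidence level in (0, 1), default 0.95.
#' @return list with `lower`, `upper`, `z0`, `a`, `degenerate`, `clamped`.
#' @export
bca_interval <- function(boot_values, observed, jackknife_values, level = 0.95) {
  stopifnot(level > 0, level < 1, length(boot_values) >= 2)
  if (max(boot_values) == min(boot_values)) {
    v <- boot_values[1]
    return(list(lower = v, upper = v, z0 = NA_real_, a = NA_real_,
                degenerate = TRUE, clamped = FALSE))
  }
  terms <- bca_terms(boot_values, observed, jackknife_values)
  xs <- sort(boot_values)
  alpha <- (1 - level) / 2
  adj <- function(p) {
    zl <- terms$z0 + stats::qnorm(p)
    stats::pnorm(terms$z0 + zl / (1 - terms$a * zl))
  }
  p_lo <- adj(alpha)
  p_hi <- adj(1 - alpha)
  clamped <- terms$clamped || !is.finite(p_lo) || !is.finite(p_hi) ||
    p_lo <= 0 || p_hi >= 1
  p_lo <- min(max(p_lo, 0, na.rm = TRUE), 1)
  p_hi <- min(max(p_hi, 0, na.rm = TRUE), 1)
  list(lower = sorted_quantile(xs, p_lo), upper = sorted_quantile(xs, p_hi),
       z0 = terms$z0, a = terms$a, degenerate = FALSE, clamped = clamped)
}

#' Bootstrap P value by BCa interval inversion
#'
#' The two-sided P value for a point null is the smallest `alpha` at which
#' the null value falls outside the `1 - alpha` BCa interval, found by
#' bisection, so the P value and the reported interval can never disagree
#' (null inside the 95% interval if and only if P > 0.05). Floored at
#' `1 / n_boot`; a degenerate (point-mass) bootstrap distribution gives
#' `NA` with a flag.
#'
#' @inheritParams bca_interval
#' @param null_value the null value of the statistic (1 for a combination
#'   index on its natural scale, 0 for its log or for a synergy score).
#' @param tol bisection tolerance on `alpha`.
#' @return list with `p` and `degenerate`.
#' @export
bootstrap_pvalue <- function(boot_values, observed, jackknife_values,
                             null_value, tol = 1e-8) {
  if (max(boot_values) == min(boot_values)) {
    return(list(p = NA_real_, degenerate = TRUE))
  }
  n_b <- length(boot_values)
  floor_p <- 1 / n_b
  terms <- bca_terms(boot_values, observed, jackknife_values)
  xs <- sort(boot_values)
  inside <- function(alpha) {
    adj <- function(p) {
      zl <- terms$z0 + stats::qnorm(p)
      stats::pnorm(terms$z0 + zl / (1 - terms$a * zl))
    }
    p_lo <- min(max(adj(alpha / 2), 0), 1)
    p_hi <- min(max(adj(1 - alpha / 2), 0), 1)
    lo <- sorted_quantile(xs, p_lo)
    hi <- sorted_quantile(xs, p_hi)
    null_value >= lo && null_value <= hi
  }
  if (!inside(floor_p)) return(list(p = floor_p, degenerate = FALSE))
  hi_alpha <- 1 - 1e-12
  if (inside(hi_alpha)) return(list(p = 1, degenerate = FALSE))
  lo_a <- floor_p
  hi_a <- hi_alpha
  while (hi_a - lo_a > tol) {
    mid <- (lo_a + hi_a) / 2
    if (inside(mid)) lo_a <- mid else hi_a <- mid
  }
  list(p = max(hi_a, floor_p), degenerate = FALSE)
}

# Statistics from per-group mean eGRs: log CI (the CI is carried on the log
# scale, null 0, matching its log-normal behaviour) and SS (natural scale,
# null 0).
contrast_stats <- function(means, model, t_eval) {
  s <- exp(-(means[["C"]] - means[c("A", "B", "AB")]) * t_eval)
  expected <- if (model == "bliss") s[["A"]] * s[["B"]] else min(s[["A"]], s[["B"]])
  c(log_ci = log(s[["AB"]] / expected), ss = 100 * (expected - s[["AB"]]))
}

#' Stratified BCa bootstrap inference for CI and SS
#'
#' Resamples mice with replacement within each treatment arm (`n_boot`
#' replicates, default 1000), re-running the eGR -> relative survival ->
#' CI/SS pipeline on every replicate, and attaches BCa confidence intervals
#' and interval-inversion P values to both the combination index and the
#' synergy score. The CI is bootstrapped on the log scale (its additivity
#' null at 0) and the interval is transformed back; the SS is bootstrapped
#' on its natural percentage scale (null 0). Acceleration comes from
#' leave-one-mouse-out jackknife re-estimates within strata.
#'
#' Because each per-mouse eGR is a fixed function of that mouse's curve,
#' resampling curves is equivalent to resampling the per-mouse eGR values
#' within groups; the implementation uses this identity for speed (group
#' index draws in the fixed order C, A, B, AB per replicate).
#'
#' @param ds a `study_dataset`.
#' @param model `"bliss"` or `"hsa"`.
#' @param t_eval evaluation time in days (default 21). Changing `t_eval`
#'   rescales CI and SS but leaves the CI's P value unchanged: the log CI is
#'   `t` times a t-free rate contrast, and the BCa construction is
#'   equivariant under monotone (here linear, positive) transforms.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed (sets the RNG; `NULL` uses the current
#'   RNG state).
#' @param max_day optional truncation passed to [group_egr()].
#' @return a `synergy_inference`: list with `observed` (a
#'   [synergy_estimate()]), `boot` (tibble of `log_ci`, `ci`, `ss`
#'   replicates), `intervals` (tibble per statistic with lower/upper and
#'   BCa diagnostics), `p` (named vector, `ci` and `ss`), and `config`.
#' @export
bootstrap_synergy <- function(ds, model = c("bliss", "hsa"), t_eval = 21,
                              n_boot = 1000, level = 0.95, seed = NULL,
                              max_day = NULL) {
  model <- match.arg(model)
  stopifnot(n_boot >= 2, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)

  egrs <- group_egr(ds, max_day = max_day)
  per <- egrs$mouse[!is.na(egrs$mouse$egr), , drop = FALSE]
  vals <- split(per$egr, factor(as.character(per$group), levels = GROUPS))
  n_g <- vapply(vals, length, integer(1))
  if (any(n_g == 0)) stop("group with no analyzable curve", call. = FALSE)

  observed <- synergy_estimate(egrs, model, t_eval)
  obs_stats <- contrast_stats(egrs$egr, model, t_eval)

  boot <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                 dimnames = list(NULL, c("log_ci", "ss")))
  means <- numeric(4)
  names(means) <- GROUPS
  for (b in seq_len(n_boot)) {
    for (g in GROUPS) {
      idx <- sample.int(n_g[[g]], n_g[[g]], replace = TRUE)
      means[[g]] <- mean(vals[[g]][idx])
    }
    boot[b, ] <- contrast_stats(means, model, t_eval)
  }

  # leave-one-mouse-out within stratum
  jack <- matrix(NA_real_, nrow = sum(n_g), ncol = 2,
                 dimnames = list(NULL, c("log_ci", "ss")))
  group_means <- vapply(vals, mean, numeric(1))
  r <- 0L
  for (g in GROUPS) {
    for (i in seq_len(n_g[[g]])) {
      m <- group_means
      m[[g]] <- mean(vals[[g]][-i])
      r <- r + 1L
      jack[r, ] <- contrast_stats(m, model, t_eval)
    }
  }

  int_log_ci <- bca_interval(boot[, "log_ci"], obs_stats[["log_ci"]],
                             jack[, "log_ci"], level)
  int_ss <- bca_interval(boot[, "ss"], obs_stats[["ss"]], jack[, "ss"], level)
  p_ci <- bootstrap_pvalue(boot[, "log_ci"], obs_stats[["log_ci"]],
                           jack[, "log_ci"], null_value = 0)
  p_ss <- bootstrap_pvalue(boot[, "ss"], obs_stats[["ss"]], jack[, "ss"],
                           null_value = 0)

  intervals <- tibble(
    statistic = c("ci", "ss"),
    estimate = c(observed$ci, observed$ss),
    lower = c(exp(int_log_ci$lower), int_ss$lower),
    upper = c(exp(int_log_ci$upper), int_ss$upper),
    z0 = c(int_log_ci$z0, int_ss$z0),
    accel = c(int_log_ci$a, int_ss$a),
    degenerate = c(int_log_ci$degenerate, int_ss$degenerate),
    clamped = c(int_log_ci$clamped, int_ss$clamped)
  )

  structure(
    list(
      observed = observed,
      boot = tibble(log_ci = boot[, "log_ci"], ci = exp(boot[, "log_ci"]),
                    ss = boot[, "ss"]),
      intervals = intervals,
      p = c(ci = p_ci$p, ss = p_ss$p),
      degenerate = c(ci = p_ci$degenerate, ss = p_ss$degenerate),
      config = list(model = model, t_eval = t_eval, n_boot = n_boot,
                    level = level, seed = seed, max_day = max_day,
                    n_jack = sum(n_g), group_sizes = n_g)
    ),
    class = "synergy_inference"
  )
}

#' @export
print.synergy_inference <- function(x, ...) {
  cat("<synergy_inference> model=", x$observed$model,
      ", t=", x$observed$t_eval, " days, n_boot=", x$config$n_boot, "\n", sep = "")
  ci <- x$intervals[x$intervals$statistic == "ci", ]
  ss <- x$intervals[x$intervals$statistic == "ss", ]
  lvl <- round(100 * x$config$level)
  cat(sprintf("  CI = %.3f [%d%%: %.3f, %.3f], P = %s\n",
              ci$estimate, lvl, ci$lower, ci$upper, format_p(x$p[["ci"]])))
  cat(sprintf("  SS = %.1f [%d%%: %.1f, %.1f], P = %s\n",
              ss$estimate, lvl, ss$lower, ss$upper, format_p(x$p[["ss"]])))
  cat("  verdict:", x$observed$verdict, "\n")
  if (any(x$degenerate)) cat("  note: degenerate bootstrap distribution\n")
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) "NA (degenerate)" else format(p, digits = 3)
}
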