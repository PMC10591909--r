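#' Twice-weekly measurement schedule
#'
#' The standard measurement pattern: twice a week with alternating 3- and
#' 4-day gaps, i.e. days 0, 4, 7, 10, 14, 18, 21, ... continued up to
#' `t_obs`.
#'
#' @param t_obs last observation day (days since treatment start).
#' @return numeric vector of measurement days starting at 0.
#' @export
default_schedule <- function(t_obs = 21) {
  stopifnot(t_obs >= 0)
  gaps <- c(4, 3, 3, 4)
  days <- 0
  i <- 0L
  while (days[length(days)] + gaps[i %% 4L + 1L] <= t_obs) {
    days <- c(days, days[length(days)] + gaps[i %% 4L + 1L])
    i <- i + 1L
  }
  days
}

#' Treatment-arm specification for the simulator
#'
#' @param arm one of `"C"`, `"A"`, `"B"`, `"AB"`.
#' @param tgi21 tumor growth inhibition at day 21, `1 - RTV_treated(21) /
#'   RTV_control(21)` under pure exponential growth; in `[0, 1)`, 0 for the
#'   control arm.
#' @param t_ki treatment kick-in delay in days (the arm grows at the control
#'   rate before `t_ki`); 0 for immediate effect.
#' @param p_rt fraction of tumor cells resistant to the treatment, in
#'   `[0, 1)`. With `t_ir = 0` the fraction is intrinsically resistant from
#'   day 0; with `t_ir > 0` it is the fraction of the population that
#'   resumes growth at the control rate at day `t_ir` (induced resistance).
#' @param t_ir induced-resistance onset day (0 = none).
#' @return an `arm_spec` list.
#' @export
arm_spec <- function(arm, tgi21 = 0, t_ki = 0, p_rt = 0, t_ir = 0) {
  arm <- match.arg(arm, GROUPS)
  if (tgi21 < 0 || tgi21 >= 1) {
    stop("tgi21 must be in [0, 1): complete kill is not representable by a finite rate",
         call. = FALSE)
  }
  stopifnot(t_ki >= 0, p_rt >= 0, p_rt < 1, t_ir >= 0)
  if (arm == "C" && (tgi21 != 0 || t_ki != 0 || p_rt != 0 || t_ir != 0)) {
    stop("control arm must have tgi21 = t_ki = p_rt = t_ir = 0", call. = FALSE)
  }
  structure(list(arm = arm, tgi21 = tgi21, t_ki = t_ki, p_rt = p_rt,
                 t_ir = t_ir), class = "arm_spec")
}

#' Simulation scenario for a four-group tumor-growth study
#'
#' Parameters of the exponential tumor-growth generator. Tumors grow as
#' `TV(t) = TV_0 * exp(k t)` modified per arm by treatment effect (`tgi21`),
#' kick-in delay, and resistance; animal-to-animal variation enters through
#' the initial volume (log-normal with coefficient of variation `cv0`) and
#' the growth rate (normal with CV `cvk`, truncated positive); measurement
#' error is multiplicative log-normal with log-scale SD `sigma`; a mouse is
#' euthanized at the first measurement reaching `tv_max` (that measurement
#' is retained, later days dropped).
#'
#' @param n_per_group mice per arm.
#' @param tgi named vector of day-21 tumor growth inhibition for arms `A`,
#'   `B`, `AB` (control is always 0).
#' @param t_ki,p_rt,t_ir optional named vectors (subset of `A`, `B`, `AB`)
#'   of kick-in delays, resistant fractions and induced-resistance onset
#'   days; unnamed arms default to 0. See [arm_spec()].
#' @param dt tumor doubling time in days; the mean growth rate is
#'   `k_mean = log(2) / dt`. Give either `dt` or `k_mean`.
#' @param k_mean mean control growth rate per day (overrides `dt`).
#' @param tv0_mean mean initial tumor volume, mm^3 (default 200; treatment
#'   typically starts at 100-300 mm^3).
#' @param cv0 coefficient of variation of initial TV across animals.
#' @param cvk coefficient of variation of the growth rate across animals.
#' @param sigma log-scale SD of the multiplicative measurement error.
#' @param tv_max euthanasia threshold, mm^3 (default 3000).
#' @param t_obs last observation day; the default schedule is twice weekly
#'   up to `t_obs`.
#' @param schedule measurement days (default [default_schedule()]).
#' @param seed optional integer seed stored with the scenario.
#' @param arms optional list of four [arm_spec()] objects overriding
#'   `tgi`/`t_ki`/`p_rt`/`t_ir`.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_per_group = 6,
                         tgi = c(A = 0.5, B = 0.4, AB = 0.7),
                         t_ki = NULL, p_rt = NULL, t_ir = NULL,
                         dt = 7, k_mean = NULL,
                         tv0_mean = 200, cv0 = 0.2, cvk = 0.2, sigma = 0.1,
                         tv_max = 3000, t_obs = 21, schedule = NULL,
                         seed = NULL, arms = NULL) {
  if (is.null(k_mean)) k_mean <- log(2) / dt
  if (is.null(schedule)) schedule <- default_schedule(t_obs)
  if (is.null(arms)) {
    get0v <- function(v, a) if (!is.null(v) && a %in% names(v)) v[[a]] else 0
    arms <- lapply(GROUPS, function(a) {
      if (a == "C") return(arm_spec("C"))
      arm_spec(a,
               tgi21 = if (a %in% names(tgi)) tgi[[a]] else 0,
               t_ki = get0v(t_ki, a), p_rt = get0v(p_rt, a),
               t_ir = get0v(t_ir, a))
    })
  }
  names(arms) <- vapply(arms, function(a) a$arm, character(1))
  if (!identical(sort(names(arms)), sort(GROUPS))) {
    stop("arms must cover C, A, B, AB exactly once", call. = FALSE)
  }
  if (length(schedule) < 2 || schedule[1] != 0 || any(diff(schedule) <= 0)) {
    stop("schedule must start at day 0 and be strictly increasing", call. = FALSE)
  }
  if (max(schedule) > t_obs) stop("schedule extends past t_obs", call. = FALSE)
  if (tv_max <= tv0_mean) stop("tv_max must exceed tv0_mean", call. = FALSE)
  stopifnot(n_per_group >= 1, k_mean > 0, cv0 >= 0, cvk >= 0, sigma >= 0)
  structure(
    list(n_per_group = as.integer(n_per_group), k_mean = k_mean,
         tv0_mean = tv0_mean, cv0 = cv0, cvk = cvk, sigma = sigma,
         tv_max = tv_max, t_obs = t_obs, schedule = schedule,
         arms = arms[GROUPS], seed = seed),
    class = "sim_scenario"
  )
}

#' Convert a day-21 TGI to a treated growth rate
#'
#' Under pure exponential growth, a treated arm with rate
#' `k_tr = k_control + log(1 - tgi21) / 21` has relative tumor volume ratio
#' `RTV_treated(21) / RTV_control(21) = 1 - tgi21` exactly.
#'
#' @param k_control control growth rate, per day.
#' @param tgi21 tumor growth inhibition at day 21, in `[0, 1)`.
#' @return treated growth rate, per day (may be negative: regression).
#' @export
tgi_to_rate <- function(k_control, tgi21) {
  if (any(tgi21 < 0) || any(tgi21 >= 1)) {
    stop("tgi21 must be in [0, 1)", call. = FALSE)
  }
  k_control + log(1 - tgi21) / 21
}

#' Noise-free expected tumor volume for an arm
#'
#' Closed-form trajectory of the two-population exponential model: a
#' sensitive population grows at the control rate until the kick-in day
#' `t_ki` and at the treated rate after; with intrinsic resistance
#' (`p_rt > 0`, `t_ir = 0`) a fraction `p_rt` grows at the control rate
#' throughout, `TV(t) = TV_0 * (p_rt e^{k_c t} + (1 - p_rt) g(t))`; with
#' induced resistance (`t_ir > 0`) a fraction `p_rt` of the population at
#' day `t_ir` switches back to the control rate thereafter.
#'
#' @param arm an [arm_spec()].
#' @param k_c control growth rate per day (this mouse's base rate).
#' @param tv0 initial tumor volume, mm^3.
#' @param t day(s) since treatment start (vectorized).
#' @return expected tumor volume(s), mm^3.
#' @export
expected_tv <- function(arm, k_c, tv0, t) {
  stopifnot(inherits(arm, "arm_spec"), all(t >= 0))
  k_tr <- tgi_to_rate(k_c, arm$tgi21)
  # sensitive-population growth factor with kick-in delay
  g <- function(t) exp(k_c * pmin(t, arm$t_ki) + k_tr * pmax(t - arm$t_ki, 0))
  p <- arm$p_rt
  if (p == 0) return(tv0 * g(t))
  if (arm$t_ir == 0) {
    # intrinsic: resistant fraction grows at control rate from day 0
    return(tv0 * (p * exp(k_c * t) + (1 - p) * g(t)))
  }
  # induced: split the population present at t_ir
  f_tir <- g(arm$t_ir)
  early <- t <= arm$t_ir
  out <- numeric(length(t))
  out[early] <- g(t[early])
  te <- t[!early]
  out[!early] <- f_tir * (p * exp(k_c * (te - arm$t_ir)) +
                            (1 - p) * g(te) / f_tir)
  tv0 * out
}

#' Simulate one mouse's growth curve
#'
#' Draws the animal's initial volume (log-normal with mean `tv0_mean` and CV
#' `cv0`) and base growth rate (normal, mean `k_mean`, SD `cvk * k_mean`,
#' redrawn if non-positive), evaluates the arm's expected trajectory on the
#' schedule, applies multiplicative log-normal measurement error
#' (`exp(eps)`, `eps ~ N(0, sigma^2)`), and truncates after the first
#' measurement at or above `tv_max` (that measurement is kept — it is the
#' animal's terminal datapoint).
#'
#' @param scenario a [sim_scenario()].
#' @param arm arm label (`"C"`, `"A"`, `"B"`, `"AB"`).
#' @param mouse_id identifier for the returned rows.
#' @return tibble with columns `mouse`, `group`, `day`, `tv`.
#' @export
simulate_mouse <- function(scenario, arm, mouse_id = paste0(arm, "1")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  spec <- scenario$arms[[arm]]
  sdlog <- sqrt(log(1 + scenario$cv0^2))
  tv0 <- stats::rlnorm(1, meanlog = log(scenario$tv0_mean) - sdlog^2 / 2,
                       sdlog = sdlog)
  k <- stats::rnorm(1, scenario$k_mean, scenario$cvk * scenario$k_mean)
  while (k <= 0) k <- stats::rnorm(1, scenario$k_mean, scenario$cvk * scenario$k_mean)
  days <- scenario$schedule
  mu <- expected_tv(spec, k, tv0, days)
  tv <- mu * exp(stats::rnorm(length(days), 0, scenario$sigma))
  hit <- which(tv >= scenario$tv_max)
  if (length(hit) > 0) {
    keep <- seq_len(hit[1])
    days <- days[keep]
    tv <- tv[keep]
  }
  tibble(mouse = mouse_id, group = arm, day = days, tv = tv)
}

#' Simulate a four-group study
#'
#' Draws `n_per_group` independent mice per arm (in the fixed order C, A, B,
#' AB) and returns them as a standard `study_dataset`, so simulated studies
#' flow through exactly the same analysis path and CSV schema as real ones.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional integer seed; defaults to the scenario's own
#'   `seed` if set.
#' @return a `study_dataset`.
#' @export
simulate_study <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  if (!is.null(seed)) set.seed(seed)
  pieces <- list()
  for (arm in GROUPS) {
    for (i in seq_len(scenario$n_per_group)) {
      pieces[[length(pieces) + 1L]] <-
        simulate_mouse(scenario, arm, mouse_id = paste0(arm, i))
    }
  }
  x <- dplyr::bind_rows(pieces)
  x$group <- factor(x$group, levels = GROUPS)
  new_study_dataset(dplyr::arrange(x, .data$group, .data$mouse, .data$day))
}

#' Read / write a simulation scenario as YAML
#'
#' @param path YAML file path.
#' @return for `read_scenario`, a [sim_scenario()]; for `write_scenario`,
#'   `path` invisibly.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  arms <- NULL
  if (!is.null(y$arms)) {
    arms <- lapply(y$arms, function(a) {
      arm_spec(a$arm, tgi21 = a$tgi21 %||% 0, t_ki = a$t_ki %||% 0,
               p_rt = a$p_rt %||% 0, t_ir = a$t_ir %||% 0)
    })
  }
  num <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  named <- function(v) if (is.null(v)) NULL else unlist(v)
  sim_scenario(
    n_per_group = y$n_per_group %||% 6,
    tgi = named(y$tgi) %||% c(A = 0.5, B = 0.4, AB = 0.7),
    t_ki = named(y$t_ki), p_rt = named(y$p_rt), t_ir = named(y$t_ir),
    dt = y$dt %||% 7, k_mean = y$k_mean,
    tv0_mean = y$tv0_mean %||% 200, cv0 = y$cv0 %||% 0.2,
    cvk = y$cvk %||% 0.2, sigma = y$sigma %||% 0.1,
    tv_max = y$tv_max %||% 3000, t_obs = y$t_obs %||% 21,
    schedule = num(y$schedule), seed = if (!is.null(y$seed)) as.integer(y$seed),
    arms = arms
  )
}

#' @rdname read_scenario
#' @param scenario a [sim_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  y <- unclass(scenario)
  y$arms <- lapply(y$arms, unclass)
  yaml::write_yaml(y, path, precision = 17L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
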