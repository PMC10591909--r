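#' Relative survival fractions at an evaluation time
#'
#' Treating tumor volume as a cell-count readout, each arm's relative
#' survival with respect to the vehicle control is the ratio of equivalent
#' exponentials at time `t`: `S_g = exp(-(eGR_C - eGR_g) * t)` for
#' g in A, B, AB. Values above 1 are allowed (a treatment that accelerates
#' growth).
#'
#' @param egrs an `egr_table` from [group_egr()], or a named numeric vector
#'   with elements `C`, `A`, `B`, `AB`.
#' @param t_eval evaluation time in days (> 0); 21 days (three weeks of
#'   treatment) is the conventional choice.
#' @return named vector `c(A=, B=, AB=)` of survival fractions.
#' @export
relative_survival <- function(egrs, t_eval = 21) {
  e <- egr_vector(egrs)
  if (!is.numeric(t_eval) || length(t_eval) != 1 || t_eval <= 0) {
    stop("t_eval must be a single positive number of days", call. = FALSE)
  }
  s <- exp(-(e[["C"]] - e[c("A", "B", "AB")]) * t_eval)
  stats::setNames(as.numeric(s), c("A", "B", "AB"))
}

egr_vector <- function(egrs) {
  e <- if (inherits(egrs, "egr_table")) egrs$egr else egrs
  if (!is.numeric(e) || !all(GROUPS %in% names(e))) {
    stop("need eGR values named C, A, B, AB", call. = FALSE)
  }
  if (anyNA(e[GROUPS])) stop("missing group eGR", call. = FALSE)
  e[GROUPS]
}

#' Combination index and synergy score under Bliss or HSA
#'
#' Under Bliss independence the expected combination survival is the product
#' of the single-agent survivals, `S_A * S_B`; under the highest-single-agent
#' (HSA) model it is the better single agent, `min(S_A, S_B)`. The
#' combination index is observed over expected survival,
#' `CI = S_AB / S_expected` (CI < 1 synergy, = 1 additivity, > 1
#' antagonism), and the synergy score is the survival difference in
#' percentage points, `SS = 100 * (S_expected - S_AB)` (SS > 0 synergy).
#' For Bliss the CI has the closed form
#' `exp(t * (eGR_C + eGR_AB - eGR_A - eGR_B))`.
#'
#' @inheritParams relative_survival
#' @param model `"bliss"` or `"hsa"`.
#' @return a `synergy_estimate`: list with `model`, `t_eval`, `egr`,
#'   `survival`, `ci`, `ss` and `verdict` (`"synergy"`, `"additivity"` or
#'   `"antagonism"`).
#' @export
synergy_estimate <- function(egrs, model = c("bliss", "hsa"), t_eval = 21) {
  model <- match.arg(model)
  e <- egr_vector(egrs)
  s <- relative_survival(e, t_eval)
  expected <- switch(model,
    bliss = s[["A"]] * s[["B"]],
    hsa   = min(s[["A"]], s[["B"]])
  )
  ci <- s[["AB"]] / expected
  ss <- 100 * (expected - s[["AB"]])
  verdict <- if (ci < 1) "synergy" else if (ci > 1) "antagonism" else "additivity"
  structure(
    list(model = model, t_eval = t_eval, egr = e, survival = s,
         expected_survival = expected, ci = ci, ss = ss, verdict = verdict),
    class = "synergy_estimate"
  )
}

#' @rdname synergy_estimate
#' @export
combination_index <- function(egrs, model = c("bliss", "hsa"), t_eval = 21) {
  synergy_estimate(egrs, model, t_eval)$ci
}

#' @rdname synergy_estimate
#' @export
synergy_score <- function(egrs, model = c("bliss", "hsa"), t_eval = 21) {
  synergy_estimate(egrs, model, t_eval)$ss
}

#' @export
print.synergy_estimate <- function(x, ...) {
  cat("<synergy_estimate> model=", x$model, ", t=", x$t_eval, " days\n", sep = "")
  cat(sprintf("  eGR: C=%.4f A=%.4f B=%.4f AB=%.4f (per day)\n",
              x$egr[["C"]], x$egr[["A"]], x$egr[["B"]], x$egr[["AB"]]))
  cat(sprintf("  relative survival: A=%.3f B=%.3f AB=%.3f (expected %.3f)\n",
              x$survival[["A"]], x$survival[["B"]], x$survival[["AB"]],
              x$expected_survival))
  cat(sprintf("  CI = %.3f, SS = %.1f -> %s\n", x$ci, x$ss, x$verdict))
  invisible(x)
}

#' Single-day log-ratio Bliss index (comparison baseline)
#'
#' The single-day baseline used by day-wise methods: for each group the mean
#' relative tumor volume `mu_g` at the given day (each mouse's TV divided by
#' its own first measurement, then averaged within group), and the local
#' Bliss index `log(mu_A) + log(mu_B) - log(mu_C) - log(mu_AB)` (natural
#' log). Orientation is opposite to the eGR-based CI: values > 0 indicate
#' synergy, < 0 antagonism. A mouse contributes to a day only if it was
#' measured at exactly that day — no interpolation — so the index is not
#' computable once any arm has no measurement at the day (the documented
#' weakness of day-wise methods, e.g. after control-arm euthanasia).
#'
#' @param ds a `study_dataset`.
#' @param day a single measurement day.
#' @return list with `day`, `mu` (named mean relative TV per group),
#'   `delta` (named treatment effects `(mu_C - mu_g)/mu_C` for A, B, AB) and
#'   `local_ci`; `local_ci` is `NA` (with `computable = FALSE`) if any arm
#'   lacks data at `day`.
#' @export
local_bliss_ci <- function(ds, day) {
  stopifnot(inherits(ds, "study_dataset"))
  x <- as_tibble(ds)
  rel <- dplyr::mutate(dplyr::group_by(x, .data$mouse),
                       rtv = .data$tv / .data$tv[which.min(.data$day)])
  rel <- dplyr::ungroup(rel)
  at <- rel[rel$day == day, , drop = FALSE]
  mu <- tapply(at$rtv, factor(as.character(at$group), levels = GROUPS), mean)
  mu <- stats::setNames(as.numeric(mu), GROUPS)
  if (anyNA(mu)) {
    return(list(day = day, mu = mu,
                delta = stats::setNames(rep(NA_real_, 3), c("A", "B", "AB")),
                local_ci = NA_real_, computable = FALSE))
  }
  delta <- (mu[["C"]] - mu[c("A", "B", "AB")]) / mu[["C"]]
  lci <- log(mu[["A"]]) + log(mu[["B"]]) - log(mu[["C"]]) - log(mu[["AB"]])
  list(day = day, mu = mu, delta = stats::setNames(delta, c("A", "B", "AB")),
       local_ci = lci, computable = TRUE)
}

#' Global single-day Bliss index (mean of local values)
#'
#' Averages [local_bliss_ci()] over every day at which all four arms have at
#' least one measured mouse. Days where any arm lacks data are skipped and
#' recorded, which is precisely how late treatment effects can be missed
#' when the control arm drops out early.
#'
#' @param ds a `study_dataset`.
#' @return a `local_ci_baseline`: list with `per_day` (tibble of day, mu per
#'   group, delta per arm, local_ci, computable), `days_used` and `gci`.
#' @export
global_ci <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  days <- sort(unique(as_tibble(ds)$day))
  rows <- lapply(days, function(d) {
    l <- local_bliss_ci(ds, d)
    tibble(day = d,
           mu_C = l$mu[["C"]], mu_A = l$mu[["A"]], mu_B = l$mu[["B"]],
           mu_AB = l$mu[["AB"]],
           delta_A = l$delta[["A"]], delta_B = l$delta[["B"]],
           delta_AB = l$delta[["AB"]],
           local_ci = l$local_ci, computable = l$computable)
  })
  per_day <- dplyr::bind_rows(rows)
  used <- per_day$day[per_day$computable]
  if (length(used) == 0) {
    stop("no day at which all four groups have data; gCI not computable",
         call. = FALSE)
  }
  structure(
    list(per_day = per_day, days_used = used,
         gci = mean(per_day$local_ci[per_day$computable])),
    class = "local_ci_baseline"
  )
}

#' @export
print.local_ci_baseline <- function(x, ...) {
  cat("<local_ci_baseline> gCI =", format(x$gci, digits = 4),
      "over", length(x$days_used), "day(s)\n")
  cat("  (orientation: > 0 synergy, < 0 antagonism)\n")
  invisible(x)
}
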