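#' Net log-scale area under a tumor growth curve
#'
#' The growth curve is taken on the natural-log tumor-volume scale and
#' integrated by the trapezoidal rule; the rectangle `d * log(TV_0)` spanned
#' by the baseline is subtracted, leaving the net-gain area. The net area is
#' positive, zero or negative according to whether the tumor shows net
#' growth, stasis or net shrinkage over the observation window.
#'
#' @param day numeric vector of measurement days, strictly increasing.
#' @param tv matching vector of positive tumor volumes (mm^3).
#' @return list with `net_auc` (day x log mm^3) and `duration` (days,
#'   last day minus first day).
#' @export
log_auc_net <- function(day, tv) {
  if (length(day) != length(tv)) stop("day and tv lengths differ", call. = FALSE)
  if (length(day) < 2) {
    stop("curve not analyzable: fewer than 2 measurements", call. = FALSE)
  }
  if (any(diff(day) <= 0)) {
    stop("days must be strictly increasing with no duplicates", call. = FALSE)
  }
  if (any(!is.finite(tv)) || any(tv <= 0)) {
    stop("tumor volumes must be positive", call. = FALSE)
  }
  lv <- log(tv)
  gaps <- diff(day)
  total <- sum(gaps * (lv[-length(lv)] + lv[-1]) / 2)
  d <- day[length(day)] - day[1]
  list(net_auc = total - d * lv[1], duration = d)
}

#' Exponential growth rate (eGR) of one growth curve
#'
#' eGR summarizes a growth curve by the rate constant of the equivalent
#' exponential curve with the same net log-scale AUC over the same duration:
#' `eGR = 2 * AUC_net / d^2`. For a curve that is exactly exponential,
#' `TV(t) = TV_0 * exp(k t)`, the net log-AUC is `k d^2 / 2`, so eGR equals
#' `k` regardless of the sampling schedule. No curve fitting or growth-law
#' assumption is involved, and the value is invariant to rescaling the
#' volumes (starting tumor size cancels).
#'
#' @inheritParams log_auc_net
#' @param max_day optional truncation: measurements after `max_day` are
#'   ignored (e.g. restrict to the first 21 days of a longer study).
#' @return rate per day.
#' @export
mouse_egr <- function(day, tv, max_day = NULL) {
  if (!is.null(max_day)) {
    keep <- day <= max_day
    day <- day[keep]
    tv <- tv[keep]
  }
  a <- log_auc_net(day, tv)
  if (a$duration <= 0) stop("zero-duration curve", call. = FALSE)
  2 * a$net_auc / a$duration^2
}

#' Per-mouse and per-group eGR table
#'
#' Computes eGR for every analyzable curve (>= 2 measurement days) and the
#' per-group mean eGR for the four arms. Group means average the individual
#' rates, so every mouse contributes over its own observation window and
#' uneven designs (dropout, euthanasia, extended follow-up) need no
#' interpolation. Curves with a single measurement are skipped with a
#' warning and reported in the `skipped` attribute.
#'
#' @param ds a `study_dataset`.
#' @param max_day optional truncation passed to [mouse_egr()].
#' @return an `egr_table`: list with `mouse` (tibble mouse, group, net_auc,
#'   duration, egr), `group` (tibble group, n, egr mean and sd) and `egr` (a
#'   named vector of the four group means), plus `skipped` mouse ids.
#' @export
group_egr <- function(ds, max_day = NULL) {
  stopifnot(inherits(ds, "study_dataset") || is.data.frame(ds))
  x <- as_tibble(ds)
  per <- lapply(split(x, x$mouse), function(mi) {
    day <- mi$day
    tv <- mi$tv
    if (!is.null(max_day)) {
      keep <- day <= max_day
      day <- day[keep]
      tv <- tv[keep]
    }
    if (length(day) < 2 || max(day) == min(day)) {
      return(tibble(mouse = mi$mouse[1], group = as.character(mi$group[1]),
                    net_auc = NA_real_, duration = NA_real_, egr = NA_real_))
    }
    a <- log_auc_net(day, tv)
    tibble(mouse = mi$mouse[1], group = as.character(mi$group[1]),
           net_auc = a$net_auc, duration = a$duration,
           egr = 2 * a$net_auc / a$duration^2)
  })
  per <- dplyr::bind_rows(per)
  per$group <- factor(per$group, levels = GROUPS)
  per <- dplyr::arrange(per, .data$group, .data$mouse)

  skipped <- per$mouse[is.na(per$egr)]
  if (length(skipped) > 0) {
    warning("excluded from eGR (fewer than 2 usable measurements): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  ok <- per[!is.na(per$egr), , drop = FALSE]

  grp <- dplyr::summarise(
    dplyr::group_by(ok, .data$group, .drop = FALSE),
    n = dplyr::n(),
    egr_sd = stats::sd(.data$egr),  # before the mean shadows the column
    egr = mean(.data$egr),
    .groups = "drop"
  )
  grp <- grp[, c("group", "n", "egr", "egr_sd")]
  empty <- as.character(grp$group[grp$n == 0])
  if (length(empty) > 0) {
    stop("group(s) with no analyzable curve: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      mouse = per,
      group = grp,
      egr = stats::setNames(grp$egr, as.character(grp$group))[GROUPS],
      skipped = skipped,
      max_day = max_day
    ),
    class = "egr_table"
  )
}

#' @export
print.egr_table <- function(x, ...) {
  cat("<egr_table> per-group mean exponential growth rates (per day)\n")
  print(x$group)
  if (length(x$skipped) > 0) {
    cat("skipped (non-analyzable):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write per-mouse and per-group eGR tables to CSV
#'
#' @param egrs an `egr_table` from [group_egr()].
#' @param mouse_path,group_path output CSV paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_egr <- function(egrs, mouse_path = NULL, group_path = NULL) {
  stopifnot(inherits(egrs, "egr_table"))
  if (!is.null(mouse_path)) readr::write_csv(egrs$mouse, mouse_path, progress = FALSE)
  if (!is.null(group_path)) readr::write_csv(egrs$group, group_path, progress = FALSE)
  invisible(c(mouse_path, group_path))
}
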