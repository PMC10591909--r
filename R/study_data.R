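#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

GROUPS <- c("C", "A", "B", "AB")

# Case-insensitive label dialects accepted for the four arms.
GROUP_ALIASES <- list(
  C  = c("c", "control", "vehicle", "ctrl", "veh", "vehicle control"),
  A  = c("a", "drug a", "drug_a", "druga", "treatment a"),
  B  = c("b", "drug b", "drug_b", "drugb", "treatment b"),
  AB = c("ab", "a+b", "a_b", "combo", "combination", "drug a+b", "a plus b")
)

canonical_group <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(lx))
  for (g in GROUPS) {
    out[lx %in% GROUP_ALIASES[[g]]] <- g
  }
  out
}

#' Construct a study dataset from a long-format table
#'
#' A study dataset is a tibble with one row per mouse per measurement day and
#' columns `mouse`, `group` (factor with levels `C`, `A`, `B`, `AB` for the
#' vehicle control, drug A, drug B and combination arms), `day` (days since
#' treatment start) and `tv` (tumor volume, mm^3). It is the unit of analysis
#' for synergy estimation and the unit of resampling for the stratified
#' bootstrap.
#'
#' @param df data frame with columns `mouse`, `group`, `day`, `tv` (or
#'   mappable via `column_map`). Group labels may use common dialects
#'   ("vehicle", "combo", "A+B", ...), matched case-insensitively.
#' @param column_map named character vector mapping canonical names
#'   (`mouse`, `group`, `day`, `tv`) to the column names used in `df`.
#' @param align_days if `TRUE` (default), shift each mouse's days so that its
#'   first measurement is day 0. The evaluation-time convention (t = 21 days)
#'   presumes days are indexed from treatment start.
#' @param drop_invalid_tv if `TRUE` (default), rows with missing or
#'   non-positive tumor volume are dropped (and counted in a message).
#' @return a `study_dataset` tibble, sorted by group, mouse and day.
#' @details A mouse assigned to two groups or duplicated (mouse, day) rows are
#'   hard errors: both make the growth curve ambiguous and should be resolved
#'   upstream rather than silently averaged. All four arms must be present
#'   with at least one analyzable (>= 2 measurements) curve each; group sizes
#'   may be unbalanced.
#' @seealso [read_study()], [validate_study()], [simulate_study()]
#' @export
as_study_dataset <- function(df, column_map = NULL, align_days = TRUE,
                             drop_invalid_tv = TRUE) {
  cmap <- c(mouse = "mouse", group = "group", day = "day", tv = "tv")
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    cmap[names(column_map)] <- column_map
  }
  missing_cols <- cmap[!cmap %in% names(df)]
  if (length(missing_cols) > 0) {
    stop("input table lacks required column(s): ",
         paste0(missing_cols, " (", names(missing_cols), ")", collapse = ", "),
         call. = FALSE)
  }
  x <- tibble(
    mouse = as.character(df[[cmap[["mouse"]]]]),
    group = canonical_group(df[[cmap[["group"]]]]),
    day   = as.numeric(df[[cmap[["day"]]]]),
    tv    = as.numeric(df[[cmap[["tv"]]]])
  )
  bad_group <- unique(as.character(df[[cmap[["group"]]]])[is.na(x$group)])
  if (length(bad_group) > 0) {
    stop("unrecognized group label(s): ", paste(bad_group, collapse = ", "),
         "; expected dialects of C/A/B/AB", call. = FALSE)
  }
  x$group <- factor(x$group, levels = GROUPS)

  n_bad_tv <- sum(is.na(x$tv) | x$tv <= 0)
  if (n_bad_tv > 0) {
    if (!drop_invalid_tv) {
      stop(n_bad_tv, " row(s) with missing or non-positive tumor volume",
           call. = FALSE)
    }
    message("dropping ", n_bad_tv, " row(s) with missing or non-positive tumor volume")
    x <- x[!is.na(x$tv) & x$tv > 0, , drop = FALSE]
  }
  if (anyNA(x$day)) stop("missing measurement day", call. = FALSE)

  multi <- tapply(as.character(x$group), x$mouse,
                  function(g) length(unique(g)))
  if (any(multi > 1)) {
    stop("mouse assigned to more than one group: ",
         paste(names(multi)[multi > 1], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(x[, c("mouse", "day")])
  if (any(dup)) {
    d1 <- x[dup, ][1, ]
    stop("duplicate measurement for mouse ", d1$mouse, " at day ", d1$day,
         "; resolve duplicates upstream", call. = FALSE)
  }

  x <- dplyr::arrange(x, .data$group, .data$mouse, .data$day)
  if (align_days) {
    x <- dplyr::mutate(dplyr::group_by(x, .data$mouse),
                       day = .data$day - min(.data$day))
    x <- dplyr::ungroup(x)
  }

  absent <- GROUPS[!GROUPS %in% as.character(x$group)]
  if (length(absent) > 0) {
    stop("treatment group(s) absent: ", paste(absent, collapse = ", "),
         "; a 4-group design (C, A, B, AB) is required", call. = FALSE)
  }

  new_study_dataset(x)
}

new_study_dataset <- function(x) {
  structure(x, class = c("study_dataset", class(tibble())))
}

#' Read a four-group tumor-volume study from CSV
#'
#' Reads a long-format CSV (header row required; default columns `mouse`,
#' `group`, `day`, `tv`) and assembles a [as_study_dataset()] study dataset.
#' The result is invariant to the row order of the input file.
#'
#' @param path path to a CSV file.
#' @inheritParams as_study_dataset
#' @return a `study_dataset` tibble.
#' @export
read_study <- function(path, column_map = NULL, align_days = TRUE,
                       drop_invalid_tv = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_study_dataset(df, column_map = column_map, align_days = align_days,
                   drop_invalid_tv = drop_invalid_tv)
}

#' Write a study dataset to CSV
#'
#' Writes the standard long-format schema (`mouse`, `group`, `day`, `tv`), so
#' that simulated studies round-trip through the same format as real ones.
#'
#' @param ds a `study_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  out <- as_tibble(ds)[, c("mouse", "group", "day", "tv")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-mouse summary of a study dataset
#'
#' @param ds a `study_dataset`.
#' @return tibble with one row per mouse: `mouse`, `group`, `n_obs`,
#'   `first_day`, `last_day`, `duration`, and `analyzable` (>= 2 measurement
#'   days; single-point curves are kept in the dataset but excluded from
#'   growth-rate estimation).
#' @export
study_mice <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  dplyr::summarise(
    dplyr::group_by(as_tibble(ds), .data$mouse, .data$group),
    n_obs = dplyr::n(),
    first_day = min(.data$day),
    last_day = max(.data$day),
    duration = max(.data$day) - min(.data$day),
    .groups = "drop"
  ) |>
    dplyr::mutate(analyzable = .data$n_obs >= 2 & .data$duration > 0) |>
    dplyr::arrange(.data$group, .data$mouse)
}

#' Validate a study dataset
#'
#' Reports structural issues without modifying the dataset: absent groups,
#' groups with no analyzable curve (fatal for synergy estimation), curves
#' with fewer than two measurement days or duplicated days, and curves whose
#' first recorded day is not 0.
#'
#' @param ds a `study_dataset` (or a plain data frame with the same columns,
#'   e.g. one assembled without the constructor's checks).
#' @return tibble with columns `severity` (`"fatal"`, `"warning"`, `"note"`),
#'   `scope` (`"group"` or `"mouse"`), `id` and `message`. Zero rows for a
#'   well-formed dataset.
#' @export
validate_study <- function(ds) {
  x <- as_tibble(ds)
  issues <- list()
  add <- function(severity, scope, id, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      severity = severity, scope = scope, id = id, message = message
    )
  }

  present <- unique(as.character(x$group))
  for (g in GROUPS[!GROUPS %in% present]) {
    add("fatal", "group", g, paste0("group ", g, " absent"))
  }

  mice <- split(x, x$mouse)
  for (m in names(mice)) {
    mi <- mice[[m]]
    dup_days <- unique(mi$day[duplicated(mi$day)])
    for (d in dup_days) {
      add("fatal", "mouse", m, paste0("duplicate day ", d, " for mouse ", m))
    }
    if (length(unique(mi$day)) < 2) {
      add("warning", "mouse", m,
          paste0("mouse ", m, " has fewer than 2 measurement days; excluded from eGR"))
    }
    if (min(mi$day) != 0) {
      add("note", "mouse", m,
          paste0("mouse ", m, " first measurement at day ", min(mi$day),
                 ", not 0; consider align_days"))
    }
    if (any(mi$tv <= 0, na.rm = TRUE) || anyNA(mi$tv)) {
      add("fatal", "mouse", m, paste0("non-positive or missing tumor volume for mouse ", m))
    }
  }

  smry <- dplyr::summarise(
    dplyr::group_by(x, .data$mouse, .data$group),
    ok = length(unique(.data$day)) >= 2, .groups = "drop"
  )
  for (g in intersect(GROUPS, present)) {
    if (!any(smry$ok[smry$group == g])) {
      add("fatal", "group", g, paste0("group ", g, " has no analyzable curve"))
    }
  }

  if (length(issues) == 0) {
    return(tibble(severity = character(), scope = character(),
                  id = character(), message = character()))
  }
  dplyr::bind_rows(issues)
}

#' @export
print.study_dataset <- function(x, ...) {
  mice <- study_mice(x)
  sizes <- table(mice$group)
  cat("<study_dataset> ", nrow(mice), " mice, ", nrow(x), " measurements\n", sep = "")
  cat("  group sizes: ",
      paste0(GROUPS, "=", as.integer(sizes[GROUPS]), collapse = ", "), "\n", sep = "")
  cat("  day span: ", min(x$day), "-", max(x$day), "\n", sep = "")
  NextMethod()
}

#' Group sizes of a study dataset
#'
#' @param ds a `study_dataset`.
#' @param analyzable_only count only curves with >= 2 measurement days.
#' @return named integer vector over `C`, `A`, `B`, `AB`.
#' @export
group_sizes <- function(ds, analyzable_only = FALSE) {
  mice <- study_mice(ds)
  if (analyzable_only) mice <- mice[mice$analyzable, , drop = FALSE]
  tab <- table(factor(mice$group, levels = GROUPS))
  stats::setNames(as.integer(tab), GROUPS)
}
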