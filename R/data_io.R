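# Reading, validating and structuring catch and covariate tables.
#
# The sampling unit throughout is the stop-month: one count of flies caught
# at a georeferenced transect stop in one month. Counts enter the analysis as
# log-scale abundances y = log10(count + 1); the +1 admits the many zero
# catches typical of fly-round data.

catch_cols <- c("site", "stop_id", "lon", "lat", "month", "count")
covariate_cols <- c("site", "stop_id", "month", "dlst", "nlst", "cattle")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "geomoran_schema_error")
  }
  invisible(df)
}

#' Read a monthly catch table
#'
#' Reads a CSV of monthly fly catches with columns `site`, `stop_id`, `lon`,
#' `lat`, `month`, `count` (one row per stop-month), validates it, and adds
#' the log-scale abundance `y = log10(count + 1)`.
#'
#' Counts must be non-negative whole numbers; `(site, stop_id, month)` must be
#' unique. If the table is at visit level (several rows per stop-month), pass
#' it through [aggregate_visits()] first.
#'
#' @param path Path to a CSV file.
#' @return A tibble of catch observations with a `y` column.
#' @seealso [read_covariates()], [build_transitions()], [site_totals()]
#' @export
read_catches <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("catch file does not exist: %s", path),
          class = "geomoran_schema_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    abort("catch file is empty: no header, zero records",
          class = "geomoran_schema_error")
  }
  check_columns(df, catch_cols, "catch table")
  validate_catches(df)
}

#' Validate an in-memory catch table and add the log abundance column
#'
#' @param df Data frame with the catch-table columns.
#' @return A validated tibble with `y = log10(count + 1)` appended.
#' @export
validate_catches <- function(df) {
  check_columns(df, catch_cols, "catch table")
  df <- tibble::as_tibble(df)
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad) > 0) {
    abort(sprintf("counts must be non-negative integers; first offending row: %d",
                  bad[1]),
          class = "geomoran_validation_error")
  }
  badm <- which(is.na(df$month) | df$month < 1 | df$month != round(df$month))
  if (length(badm) > 0) {
    abort(sprintf("months must be positive integers; first offending row: %d",
                  badm[1]),
          class = "geomoran_validation_error")
  }
  key <- paste(df$site, df$stop_id, df$month, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (site, stop_id, month) records; aggregate visits first (see aggregate_visits())",
          class = "geomoran_validation_error")
  }
  df$count <- as.integer(round(df$count))
  df$month <- as.integer(round(df$month))
  df$y <- log10(df$count + 1)
  df
}

#' Collapse visit-level rows to one count per stop-month
#'
#' Fly-rounds are typically repeated several times a month; when the input
#' table carries one row per visit, this sums counts within each
#' `(site, stop_id, month)` cell (coordinates are taken from the first visit).
#'
#' @param df Visit-level catch table.
#' @return One-row-per-stop-month tibble.
#' @export
aggregate_visits <- function(df) {
  check_columns(df, catch_cols, "catch table")
  df |>
    dplyr::group_by(.data$site, .data$stop_id, .data$month) |>
    dplyr::summarise(lon = dplyr::first(.data$lon),
                     lat = dplyr::first(.data$lat),
                     count = sum(.data$count),
                     .groups = "drop") |>
    dplyr::select(dplyr::all_of(catch_cols))
}

#' Read a covariate table
#'
#' Reads per-stop-per-month environmental covariates: day-time land surface
#' temperature `dlst` (deg C), night-time land surface temperature `nlst`
#' (deg C) and cattle density `cattle` (head per km2).
#'
#' @param path Path to a CSV with columns `site`, `stop_id`, `month`,
#'   `dlst`, `nlst`, `cattle`.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("covariate file does not exist: %s", path),
          class = "geomoran_schema_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, covariate_cols, "covariate table")
  tibble::as_tibble(df)
}

#' Write a catch or covariate table as CSV
#'
#' @param df Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Pooled catch totals per site
#'
#' Checksum helper mirroring the usual site summary table of a survey report.
#'
#' @param catches Catch table (validated).
#' @return Tibble with `site`, `n_stops`, `n_records`, `total_catch`.
#' @export
site_totals <- function(catches) {
  catches |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(n_stops = dplyr::n_distinct(.data$stop_id),
                     n_records = dplyr::n(),
                     total_catch = sum(.data$count),
                     .groups = "drop")
}

#' Build month-to-month transition pairs
#'
#' Pairs each stop-month observation with the same stop's observation one
#' month later, attaching the covariates at the starting month. Pairs that
#' would span a gap in the monthly series are dropped, as are pairs whose
#' starting month has no covariate record; drop counts are reported on
#' stderr.
#'
#' @param observations Validated catch table (with `y`).
#' @param covariates Covariate table, or `NULL` for a covariate-free pairing.
#' @return Tibble with one row per transition: `site`, `stop_id`, `lon`,
#'   `lat`, `t`, `y_t`, `y_t1`, and covariates `dlst`, `nlst`, `cattle`
#'   (when supplied), sorted by site, stop and month.
#' @export
build_transitions <- function(observations, covariates = NULL) {
  check_columns(observations, c(catch_cols, "y"), "catch table")
  obs <- observations |>
    dplyr::arrange(.data$site, .data$stop_id, .data$month)

  pairs <- obs |>
    dplyr::group_by(.data$site, .data$stop_id) |>
    dplyr::mutate(
      next_month = dplyr::lead(.data$month),
      y_next = dplyr::lead(.data$y)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_month))

  n_gap <- sum(pairs$next_month - pairs$month != 1L)
  pairs <- pairs |>
    dplyr::filter(.data$next_month - .data$month == 1L) |>
    dplyr::transmute(.data$site, .data$stop_id, .data$lon, .data$lat,
                     t = .data$month, y_t = .data$y, y_t1 = .data$y_next)
  if (n_gap > 0) {
    log_note("build_transitions: dropped %d pair(s) spanning a monthly gap", n_gap)
  }

  if (!is.null(covariates)) {
    check_columns(covariates, covariate_cols, "covariate table")
    n_before <- nrow(pairs)
    pairs <- pairs |>
      dplyr::inner_join(
        dplyr::select(covariates, dplyr::all_of(covariate_cols)),
        by = c("site", "stop_id", t = "month")
      )
    n_nocov <- n_before - nrow(pairs)
    if (n_nocov > 0) {
      log_note("build_transitions: dropped %d pair(s) with no covariate record at month t",
               n_nocov)
    }
    pairs <- dplyr::filter(
      pairs, !is.na(.data$dlst) & !is.na(.data$nlst) & !is.na(.data$cattle)
    )
  }

  if (nrow(pairs) == 0) {
    abort("no consecutive-month transition pairs could be built",
          class = "geomoran_validation_error")
  }
  dplyr::arrange(pairs, .data$site, .data$stop_id, .data$t)
}

#' Project study coordinates and build space-time distance matrices
#'
#' Projects longitude/latitude to local kilometre coordinates with an
#' equirectangular projection about the mean latitude (the study areas this
#' targets span a few tens of km, where curvature is negligible), and returns
#' the pairwise spatial (km) and temporal (months) distance matrices needed
#' by the spatio-temporal correlation function. Kilometre units matter: the
#' spatial-range prior is expressed in km.
#'
#' @param df Table with `lon` and `lat` columns and, optionally, a month
#'   column named `t` or `month` (temporal distances default to 0 without it).
#' @return An object of class `study_geometry`: a list with `points`
#'   (tibble of `x_km`, `y_km`, `t`), `d_space`, `d_time`, and the projection
#'   reference (`ref_lon`, `ref_lat`).
#' @export
project_geometry <- function(df) {
  stopifnot(all(c("lon", "lat") %in% names(df)))
  if (any(abs(df$lon) > 180, na.rm = TRUE) || any(abs(df$lat) > 90, na.rm = TRUE) ||
      anyNA(df$lon) || anyNA(df$lat)) {
    abort("coordinates outside plausible degree range",
          class = "geomoran_validation_error")
  }
  tcol <- if ("t" %in% names(df)) df$t else if ("month" %in% names(df)) df$month else rep(0, nrow(df))
  ref_lon <- mean(df$lon)
  ref_lat <- mean(df$lat)
  # km per degree: meridian arc and parallel arc at the reference latitude
  km_lat <- 110.574
  km_lon <- 111.320 * cos(ref_lat * pi / 180)
  pts <- tibble::tibble(
    x_km = (df$lon - ref_lon) * km_lon,
    y_km = (df$lat - ref_lat) * km_lat,
    t = as.numeric(tcol)
  )
  structure(
    list(
      points = pts,
      d_space = as.matrix(stats::dist(cbind(pts$x_km, pts$y_km))),
      d_time = abs(outer(pts$t, pts$t, "-")),
      ref_lon = ref_lon,
      ref_lat = ref_lat
    ),
    class = "study_geometry"
  )
}

#' @export
print.study_geometry <- function(x, ...) {
  cat(sprintf("<study_geometry> %d points, spatial extent %.2f km, %d time slices\n",
              nrow(x$points), max(x$d_space), length(unique(x$points$t))))
  invisible(x)
}
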