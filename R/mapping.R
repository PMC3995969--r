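# Prediction of net change on a regular grid: deterministic mean surface from
# the selected candidate plus simple kriging of the spatio-temporal residual.

#' Build a regular prediction lattice over the study area
#'
#' Cells are laid out in the fitted model's local km coordinate system,
#' covering the bounding box of the observation points plus a margin.
#'
#' @param geometry A [project_geometry()] object (e.g. `fit$geometry`).
#' @param cell_km Cell size in km (> 0).
#' @param margin_km Margin added around the bounding box.
#' @return Tibble with `cell_id`, `x_km`, `y_km`.
#' @export
make_prediction_grid <- function(geometry, cell_km = 1, margin_km = 1) {
  stopifnot(cell_km > 0)
  p <- geometry$points
  span <- function(lo, hi) {
    n <- ceiling((hi - lo) / cell_km)
    seq(lo, by = cell_km, length.out = n + 1)
  }
  xs <- span(min(p$x_km) - margin_km, max(p$x_km) + margin_km)
  ys <- span(min(p$y_km) - margin_km, max(p$y_km) + margin_km)
  g <- expand.grid(x_km = xs, y_km = ys, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(cell_id = seq_len(nrow(g)), x_km = g$x_km, y_km = g$y_km)
}

#' Mean net-change surface from the selected candidate
#'
#' Cell-month net change is `b - (beta1 + X_cell beta2) - dd_bar(month)`:
#' fertility minus the covariate-driven density-independent loss at the cell
#' minus the observed-data average density-dependent loss acting in that
#' month (cell-level abundance is unknown before prediction, so the monthly
#' average dd stands in for it). Cells with missing covariates are flagged
#' `NA` and excluded from maps.
#'
#' @param grid_covariates Tibble with `cell_id`, `x_km`, `y_km`, `month` and
#'   the covariate columns used in the fit (`dlst`, `nlst`, `cattle`).
#' @param fit A `moran_fit`.
#' @return The input tibble with `net_change` appended.
#' @export
predict_mean_surface <- function(grid_covariates, fit) {
  stopifnot(inherits(fit, "moran_fit"),
            all(c("cell_id", "month") %in% names(grid_covariates)))
  co <- fit$regression$coefficients
  terms <- co$term[co$term != "(Intercept)"]
  miss <- setdiff(terms, names(grid_covariates))
  if (length(miss) > 0) {
    abort(sprintf("prediction grid lacks covariate column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "geomoran_schema_error")
  }
  beta1 <- co$estimate[co$term == "(Intercept)"]
  beta2 <- setNames(co$estimate[co$term != "(Intercept)"], terms)
  X <- as.matrix(grid_covariates[terms])
  di_hat <- beta1 + drop(X %*% beta2)

  dd_bar <- fit$decomposition |>
    dplyr::group_by(month = .data$t) |>
    dplyr::summarise(dd_bar = mean(.data$dd), .groups = "drop")
  out <- grid_covariates |>
    dplyr::left_join(dd_bar, by = "month")
  out$net_change <- fit$b - di_hat - out$dd_bar
  out
}

#' Simple kriging of zero-mean residuals
#'
#' Best linear prediction of a known-mean (zero) field:
#' `prediction = c' C^-1 z` with `C = sigma2_z * Omega + sigma2_e * I` among
#' the data points and `c` the `sigma2_z`-scaled cross-covariances to each
#' target; the kriging variance `sigma2_z - c' C^-1 c` is returned alongside.
#' Exact at data points when `sigma2_e = 0`; far from all data the prediction
#' shrinks to 0 and the variance to `sigma2_z`.
#'
#' @param z Residuals at the data points.
#' @param data_points,targets Tibbles with `x_km`, `y_km`, `t`.
#' @param params Named list/vector with `phi`, `rho`, `delta`, `sigma2_z`,
#'   `sigma2_e`.
#' @return Tibble with `pred` and `krige_var`, one row per target.
#' @export
simple_krige <- function(z, data_points, targets, params) {
  stopifnot(length(z) == nrow(data_points))
  p <- as.list(params)
  ds <- as.matrix(stats::dist(cbind(data_points$x_km, data_points$y_km)))
  dt <- abs(outer(data_points$t, data_points$t, "-"))
  cross_s <- outer(data_points$x_km, targets$x_km,
                   function(a, b) (a - b)^2) +
    outer(data_points$y_km, targets$y_km, function(a, b) (a - b)^2)
  cross_s <- sqrt(cross_s)
  cross_t <- abs(outer(data_points$t, targets$t, "-"))
  res <- .simple_krige_cpp(z, ds, dt, cross_s, cross_t,
                           p$phi, p$rho, p$delta, p$sigma2_z, p$sigma2_e)
  tibble::tibble(pred = drop(res$pred), krige_var = drop(res$var))
}

#' Seasonal net-change maps
#'
#' Combines the mean surface with simple kriging of the fitted model's
#' spatio-temporal residuals (posterior-median covariance parameters), then
#' averages per cell over the months of each season and over the whole
#' period.
#'
#' @param fit A `moran_fit`.
#' @param grid_covariates Cell-month covariate table (see
#'   [predict_mean_surface()]).
#' @param krige If `FALSE`, only the mean surface is mapped.
#' @return Object of class `seasonal_map`: tibble with `cell_id`, `x_km`,
#'   `y_km`, `rainy`, `cold_dry`, `hot_dry`, `whole_period`.
#' @export
map_net_change <- function(fit, grid_covariates, krige = TRUE) {
  surf <- predict_mean_surface(grid_covariates, fit)
  if (krige) {
    post <- tidy(fit$chain)
    params <- setNames(post$median, post$term)
    dp <- fit$geometry$points
    tg <- tibble::tibble(x_km = surf$x_km, y_km = surf$y_km, t = surf$month)
    kr <- simple_krige(fit$residuals, dp, tg, params)
    surf$net_change <- surf$net_change + kr$pred
    surf$krige_var <- kr$krige_var
  }
  surf$season <- season_of(surf$month)
  wide <- surf |>
    dplyr::group_by(.data$cell_id, .data$x_km, .data$y_km, .data$season) |>
    dplyr::summarise(value = mean(.data$net_change), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "season", values_from = "value")
  for (s in c("rainy", "cold_dry", "hot_dry")) {
    if (!s %in% names(wide)) wide[[s]] <- NA_real_
  }
  whole <- surf |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(whole_period = mean(.data$net_change), .groups = "drop")
  out <- dplyr::left_join(wide, whole, by = "cell_id") |>
    dplyr::select("cell_id", "x_km", "y_km", "rainy", "cold_dry", "hot_dry",
                  "whole_period")
  class(out) <- c("seasonal_map", class(out))
  out
}

#' Classify persistent source cells
#'
#' A cell is a source (a reservoir the population never drains from) when its
#' net change is zero or positive in all three seasons; the boundary is
#' inclusive. Cells with any season missing are `NA` (unknown).
#'
#' @param seasonal_map A [map_net_change()] result, or any tibble with
#'   `rainy`, `cold_dry`, `hot_dry` columns.
#' @return The input with a logical `source` column appended.
#' @export
classify_sources <- function(seasonal_map) {
  stopifnot(all(c("rainy", "cold_dry", "hot_dry") %in% names(seasonal_map)))
  out <- tibble::as_tibble(seasonal_map)
  out$source <- out$rainy >= 0 & out$cold_dry >= 0 & out$hot_dry >= 0
  out
}

#' Write one map layer as an ESRI ASCII grid
#'
#' Plain-text raster export (no GIS dependency); cells must form a regular
#' lattice, as produced by [make_prediction_grid()].
#'
#' @param seasonal_map A seasonal map tibble.
#' @param layer Column to export (e.g. `"whole_period"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(seasonal_map, layer, path) {
  xs <- sort(unique(seasonal_map$x_km))
  ys <- sort(unique(seasonal_map$y_km))
  cell <- if (length(xs) > 1) min(diff(xs)) else 1
  m <- matrix(NA_real_, length(ys), length(xs))
  i <- match(seasonal_map$y_km, ys)
  j <- match(seasonal_map$x_km, xs)
  m[cbind(i, j)] <- seasonal_map[[layer]]
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", length(xs)),
    sprintf("nrows %d", length(ys)),
    sprintf("xllcorner %.6f", min(xs) - cell / 2),
    sprintf("yllcorner %.6f", min(ys) - cell / 2),
    sprintf("cellsize %.6f", cell),
    "NODATA_value -9999"
  ), con)
  # ESRI ASCII rows run north to south
  for (r in rev(seq_along(ys))) {
    writeLines(paste(format(m[r, ], trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}
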