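# Moran-curve demographic decomposition.
#
# The Moran curve is the logarithmic form of the Ricker stock-recruitment
# curve: log abundance next month, y_{t+1}, plotted against log abundance this
# month, y_t. Writing losses as k-values (differences of log10 population
# sizes, so they add), each monthly transition decomposes as
#
#   y_{t+1} = y_t + b - di - dd
#
# with b the monthly log10 fertility rate, di the density-independent loss,
# and dd the density-dependent loss that engages only above a threshold log
# abundance a, with intensity given by a slope angle alpha (in degrees; 45
# degrees would be exact compensation, 30 under-compensation).

#' Build the net-change candidate grid
#'
#' Candidates are demographic triples (b, a, alpha): log10 monthly fertility,
#' log10 abundance threshold at which density dependence starts, and the
#' slope angle (degrees) of the density-dependent loss. Each axis is evenly
#' spaced including both endpoints, and the Cartesian product is returned in
#' deterministic lexicographic order (b varying slowest, then a, then alpha);
#' downstream tie-breaking relies on this order.
#'
#' The defaults reproduce the standard 30 x 30 x 30 = 27,000-candidate search:
#' b in \[0.2, 0.4\] (spacing ~0.0069), a in \[0, 1.5\] (spacing ~0.0517) and
#' alpha in \[0, 89.9\] degrees (spacing exactly 3.1; 90 degrees itself is a
#' vertical slope and is excluded).
#'
#' @param n_b,n_a,n_alpha Number of grid points per axis (each >= 2).
#' @param b_range,a_range,alpha_range Length-2 numeric ranges per axis.
#' @return Tibble with columns `candidate` (1-based grid order), `b`, `a`,
#'   `alpha`.
#' @export
#' @examples
#' nrow(make_candidate_grid()) # 27000
make_candidate_grid <- function(n_b = 30, b_range = c(0.2, 0.4),
                                n_a = 30, a_range = c(0, 1.5),
                                n_alpha = 30, alpha_range = c(0, 89.9)) {
  for (n in c(n_b, n_a, n_alpha)) {
    if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
      abort("each grid axis needs at least 2 points (whole number)",
            class = "geomoran_parameter_error")
    }
  }
  check_range <- function(r, name, lo_ok, hi_ok) {
    if (length(r) != 2 || r[1] >= r[2] || r[1] < lo_ok || r[2] > hi_ok) {
      abort(sprintf("invalid %s range", name), class = "geomoran_parameter_error")
    }
  }
  check_range(b_range, "b", -Inf, Inf)
  check_range(a_range, "a", 0, Inf)
  check_range(alpha_range, "alpha", 0, 90 - 1e-9)

  g <- expand.grid(
    alpha = seq(alpha_range[1], alpha_range[2], length.out = n_alpha),
    a = seq(a_range[1], a_range[2], length.out = n_a),
    b = seq(b_range[1], b_range[2], length.out = n_b),
    KEEP.OUT.ATTRS = FALSE
  )[, c("b", "a", "alpha")]
  tibble::tibble(candidate = seq_len(nrow(g)), b = g$b, a = g$a, alpha = g$alpha)
}

#' Density-dependent loss (k-value) at a given log abundance
#'
#' The hinge form `dd = tan(alpha * pi / 180) * max(0, y - a)`: zero at and
#' below the threshold `a`, rising linearly above it with slope tan(alpha).
#' Continuous in `y`, non-decreasing in both `y` and `alpha`; `alpha = 0`
#' switches density dependence off entirely.
#'
#' @param y Log10 abundance (vector).
#' @param a Threshold log10 abundance.
#' @param alpha Slope angle in degrees, in \[0, 90).
#' @return Vector of non-negative k-values.
#' @export
#' @examples
#' density_dependent_loss(1.0, a = 0.459, alpha = 30) # tan(30 deg) * 0.541
density_dependent_loss <- function(y, a, alpha) {
  if (!is.numeric(alpha) || any(alpha < 0) || any(alpha >= 90)) {
    abort("alpha must lie in [0, 90) degrees (tan undefined at 90)",
          class = "geomoran_parameter_error")
  }
  if (any(a < 0)) {
    abort("threshold `a` must be non-negative", class = "geomoran_parameter_error")
  }
  tan(alpha * pi / 180) * pmax(0, y - a)
}

#' Raw density-independent loss implied by one transition
#'
#' Rearranges the Moran-curve identity: `di_raw = b - dd - (y_t1 - y_t)`.
#' Values can be negative: fertility in the field varies while `b` is held
#' constant, so fertility surpluses fold into the mortality term. They are
#' retained (not truncated) because they carry real signal.
#'
#' @param y_t,y_t1 Log10 abundances at months t and t+1 (vectors).
#' @param b Log10 monthly fertility rate.
#' @param dd Density-dependent losses for the same transitions.
#' @return Vector of raw density-independent k-values.
#' @export
density_independent_residual <- function(y_t, y_t1, b, dd) {
  stopifnot(length(y_t) == length(y_t1), length(dd) %in% c(1L, length(y_t)))
  b - dd - (y_t1 - y_t)
}

#' Regress raw density-independent losses on environmental covariates
#'
#' Ordinary least squares of `di_raw` on the covariate matrix with an
#' intercept. The fitted values `di_hat` are the environmental (mean) part of
#' the density-independent loss; the leftover stochasticity is deliberately
#' passed on to the spatio-temporal and error components of the model.
#'
#' @param di_raw Numeric vector of raw density-independent losses.
#' @param X Data frame or matrix of covariates (columns are covariates), or
#'   `NULL` for an intercept-only fit.
#' @return Object of class `di_regression`: list with `coefficients` table
#'   (tidy form: term, estimate, std.error, statistic, p.value), `di_hat`,
#'   `residuals` and the underlying `lm` fit.
#' @export
fit_di_regression <- function(di_raw, X = NULL) {
  if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0)) {
    dat <- data.frame(di_raw = di_raw)
    fit <- lm(di_raw ~ 1, data = dat)
  } else {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == length(di_raw))
    dat <- data.frame(di_raw = di_raw, X)
    fit <- lm(di_raw ~ ., data = dat)
    if (anyNA(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      abort(sprintf("covariate matrix is rank deficient; collinear column(s): %s",
                    paste(bad, collapse = ", ")),
            class = "geomoran_parameter_error")
    }
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(sm),
        estimate = sm[, 1], std.error = sm[, 2],
        statistic = sm[, 3], p.value = sm[, 4]
      ),
      di_hat = unname(fit$fitted.values),
      residuals = unname(fit$residuals),
      lm_fit = fit
    ),
    class = "di_regression"
  )
}

#' @export
tidy.di_regression <- function(x, ...) x$coefficients

#' @export
print.di_regression <- function(x, ...) {
  cat("Density-independent loss regression (OLS, k-value scale)\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Decompose transitions under one demographic candidate
#'
#' For every transition pair, computes the density-dependent loss `dd` from
#' `y_t`, the raw density-independent residual `di_raw`, its
#' regression-smoothed value `di_hat` (OLS on `dlst`, `nlst`, `cattle` when
#' present), and the net change `b - di_hat - dd`. The exact identity
#' `b - di_raw - dd = y_t1 - y_t` holds row by row.
#'
#' @param transitions Transition table from [build_transitions()].
#' @param b,a,alpha Demographic candidate.
#' @param covariate_names Covariate columns to use in the di regression.
#' @return Object of class `moran_decomposition`: the transition tibble with
#'   `dd`, `di_raw`, `di_hat`, `net_change` appended, and the
#'   [fit_di_regression()] object as attribute `regression`.
#' @export
decompose_transitions <- function(transitions, b, a, alpha,
                                  covariate_names = intersect(
                                    c("dlst", "nlst", "cattle"), names(transitions))) {
  dd <- density_dependent_loss(transitions$y_t, a, alpha)
  di_raw <- density_independent_residual(transitions$y_t, transitions$y_t1, b, dd)
  X <- if (length(covariate_names) > 0) transitions[covariate_names] else NULL
  reg <- fit_di_regression(di_raw, X)
  out <- transitions |>
    dplyr::mutate(dd = dd, di_raw = di_raw, di_hat = reg$di_hat,
                  net_change = net_change(b, reg$di_hat, dd))
  attr(out, "regression") <- reg
  attr(out, "params") <- c(b = b, a = a, alpha = alpha)
  class(out) <- c("moran_decomposition", class(out))
  out
}

#' Net change on the log10 scale
#'
#' Fertility minus total losses, `b - di_hat - dd`; zero at population
#' equilibrium, positive when the population grows.
#'
#' @param b Log10 monthly fertility.
#' @param di_hat Smoothed density-independent loss.
#' @param dd Density-dependent loss.
#' @return Net change (log10 rate).
#' @export
net_change <- function(b, di_hat, dd) {
  b - di_hat - dd
}

#' Seasonal and site means of per-transition net change
#'
#' Averages net change by site and Zambian season (rainy Jan-Apr, cold-dry
#' May-Aug, hot-dry Sep-Dec, from the transition's starting month), plus a
#' per-site year mean, a per-season all-site mean and the overall mean.
#' Site-season cells with no transitions are `NA`.
#'
#' @param decomposition A [decompose_transitions()] result, or any tibble with
#'   `site`, `t` and `net_change` columns.
#' @return Tibble with one row per site (plus an `all sites` row) and columns
#'   `rainy`, `cold_dry`, `hot_dry`, `year_mean`.
#' @export
aggregate_net_change <- function(decomposition) {
  stopifnot(all(c("site", "t", "net_change") %in% names(decomposition)))
  d <- tibble::as_tibble(decomposition)[c("site", "t", "net_change")]
  d$season <- season_of(d$t)

  one_block <- function(dd, label) {
    by_season <- dd |>
      dplyr::group_by(.data$season) |>
      dplyr::summarise(value = mean(.data$net_change), .groups = "drop")
    row <- setNames(rep(NA_real_, 3), c("rainy", "cold_dry", "hot_dry"))
    row[as.character(by_season$season)] <- by_season$value
    tibble::tibble(site = label, rainy = row[["rainy"]],
                   cold_dry = row[["cold_dry"]], hot_dry = row[["hot_dry"]],
                   year_mean = mean(dd$net_change))
  }

  per_site <- d |>
    dplyr::group_split(.data$site) |>
    purrr::map(~ one_block(.x, .x$site[1])) |>
    purrr::list_rbind()
  dplyr::bind_rows(per_site, one_block(d, "all sites"))
}
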