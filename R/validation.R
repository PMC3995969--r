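# Out-of-sample, leave-site-out validation.

#' Mean error and mean squared error of log-scale predictions
#'
#' `ME = mean(observed - predicted)` and `MSE = mean((observed - predicted)^2)`
#' on the log10(count + 1) scale.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Object of class `validation_report` with `me`, `mse`, `n`.
#' @export
me_mse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0)
  d <- observed - predicted
  structure(list(me = mean(d), mse = mean(d^2), n = length(d)),
            class = "validation_report")
}

#' Leave-site-out validation of the full pipeline
#'
#' Fits the whole pipeline (candidate grid search, DIC selection, mean
#' surface, kriging) on the training sites only, then predicts the test
#' site's log catches one month ahead: for each test transition,
#' `y_t1_hat = y_t + b - (beta1 + X beta2) - dd_bar(t) + kriged residual`,
#' with every ingredient estimated from the training sites. Reports ME and
#' MSE of the predictions.
#'
#' @param catches Validated catch table covering all sites.
#' @param covariates Covariate table covering all sites.
#' @param train_sites Character vector of training site names.
#' @param test_site Single test site name; must be disjoint from
#'   `train_sites`.
#' @param grid Candidate grid for the training fit.
#' @param priors,control,seed,strict Passed to [fit_candidates()].
#' @return A `validation_report` with the training fit attached.
#' @export
holdout_validate <- function(catches, covariates, train_sites, test_site,
                             grid = make_candidate_grid(5, c(0.2, 0.4),
                                                        5, c(0, 1.5),
                                                        5, c(0, 80)),
                             priors = prior_spec(), control = mcmc_control(),
                             seed = 1, strict = TRUE) {
  if (length(test_site) != 1 || test_site %in% train_sites) {
    abort("test site must be a single site disjoint from the training sites",
          class = "geomoran_validation_design_error")
  }
  present <- unique(catches$site)
  if (!all(c(train_sites, test_site) %in% present)) {
    abort("train/test sites not all present in the catch table",
          class = "geomoran_validation_design_error")
  }

  train_catch <- dplyr::filter(catches, .data$site %in% train_sites)
  test_catch <- dplyr::filter(catches, .data$site == test_site)
  train_tr <- build_transitions(train_catch, covariates)
  test_tr <- build_transitions(test_catch, covariates)

  fit <- fit_candidates(train_tr, grid = grid, priors = priors,
                        control = control, seed = seed, strict = strict)

  co <- fit$regression$coefficients
  terms <- co$term[co$term != "(Intercept)"]
  beta1 <- co$estimate[co$term == "(Intercept)"]
  beta2 <- setNames(co$estimate[co$term != "(Intercept)"], terms)
  di_hat_test <- beta1 + drop(as.matrix(test_tr[terms]) %*% beta2)

  dd_bar <- fit$decomposition |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(dd_bar = mean(.data$dd), .groups = "drop")
  dd_test <- dd_bar$dd_bar[match(test_tr$t, dd_bar$t)]
  dd_test[is.na(dd_test)] <- mean(fit$decomposition$dd)

  # kriged spatio-temporal residual at the test stop-months; the projection
  # must be shared with the training geometry
  all_geo <- project_geometry(dplyr::bind_rows(
    train_tr[c("lon", "lat", "t")], test_tr[c("lon", "lat", "t")]))
  n_train <- nrow(train_tr)
  dp <- all_geo$points[seq_len(n_train), ]
  tg <- all_geo$points[-seq_len(n_train), ]
  post <- tidy(fit$chain)
  params <- setNames(post$median, post$term)
  kr <- simple_krige(fit$residuals, dp, tg, params)

  pred_y1 <- test_tr$y_t + fit$b - di_hat_test - dd_test + kr$pred
  rep <- me_mse(test_tr$y_t1, pred_y1)
  rep$train_sites <- train_sites
  rep$test_site <- test_site
  rep$fit <- fit
  rep$predictions <- tibble::tibble(
    site = test_tr$site, stop_id = test_tr$stop_id, t = test_tr$t,
    observed = test_tr$y_t1, predicted = pred_y1,
    krige_var = kr$krige_var
  )
  rep
}

#' Annotate a validation report with natural-scale equivalents
#'
#' Attaches `10^ME` and `10^MSE` — the "equivalent flies" multiplicative
#' factors — so the log-scale errors can be read as fly counts.
#'
#' @param report A `validation_report`.
#' @return The report with `me_flies` and `mse_flies` fields added.
#' @export
natural_scale_report <- function(report) {
  stopifnot(inherits(report, "validation_report"),
            is.finite(report$me), is.finite(report$mse))
  report$me_flies <- to_natural_scale(report$me)
  report$mse_flies <- to_natural_scale(report$mse)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Out-of-sample validation\n")
  if (!is.null(x$test_site)) {
    cat(sprintf("  train: %s  test: %s\n",
                paste(x$train_sites, collapse = "+"), x$test_site))
  }
  cat(sprintf("  n = %d stop-months\n  ME  = %.4f", x$n, x$me))
  if (!is.null(x$me_flies)) cat(sprintf("  (%.3f equivalent flies)", x$me_flies))
  cat(sprintf("\n  MSE = %.4f", x$mse))
  if (!is.null(x$mse_flies)) cat(sprintf(" (%.3f equivalent flies)", x$mse_flies))
  cat("\n")
  invisible(x)
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(me = x$me, mse = x$mse, n = x$n,
                 me_flies = x$me_flies %||% to_natural_scale(x$me),
                 mse_flies = x$mse_flies %||% to_natural_scale(x$mse))
}
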