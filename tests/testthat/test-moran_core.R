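# Moran-curve decomposition: grid, losses, regression, aggregation.

test_that("candidate grid covers the box deterministically", {
  g <- make_candidate_grid(2, c(0.2, 0.4), 2, c(0, 1.5), 2, c(0, 80))
  expect_equal(nrow(g), 8)  # corners of the box
  expect_setequal(g$b, c(0.2, 0.4))
  expect_setequal(g$a, c(0, 1.5))
  expect_setequal(g$alpha, c(0, 80))
  # lexicographic order: b slowest, then a, then alpha
  expect_equal(g$b, rep(c(0.2, 0.4), each = 4))
  expect_equal(g$alpha, rep(c(0, 80), 4))

  # endpoint inclusion and spacing oracle (hi - lo) / (n - 1)
  g2 <- make_candidate_grid(30, c(0.2, 0.4), 30, c(0, 1.5), 30, c(0, 89.9))
  expect_equal(diff(sort(unique(g2$b)))[1], 0.2 / 29)
  expect_equal(max(g2$alpha), 89.9)

  # determinism
  expect_identical(make_candidate_grid(), make_candidate_grid())

  expect_error(make_candidate_grid(n_b = 1), class = "geomoran_parameter_error")
  expect_error(make_candidate_grid(alpha_range = c(0, 90)),
               class = "geomoran_parameter_error")
})

test_that("density-dependent loss is a hinge in log abundance", {
  expect_equal(density_dependent_loss(0.2, a = 0.459, alpha = 30), 0)
  expect_equal(density_dependent_loss(0.459, a = 0.459, alpha = 30), 0)
  expect_equal(density_dependent_loss(1.0, a = 0.459, alpha = 30),
               tan(30 * pi / 180) * (1.0 - 0.459), tolerance = 1e-12)
  # alpha = 0 switches density dependence off entirely
  expect_equal(density_dependent_loss(c(0.1, 1, 3), a = 0.2, alpha = 0),
               c(0, 0, 0))
  expect_error(density_dependent_loss(1, a = 0.4, alpha = 90),
               class = "geomoran_parameter_error")

  # monotone non-decreasing in y and in alpha
  set.seed(7)
  y <- sort(runif(50, 0, 2))
  dd <- density_dependent_loss(y, a = 0.5, alpha = 25)
  expect_true(all(diff(dd) >= 0))
  alphas <- sort(runif(20, 0, 89))
  dda <- vapply(alphas, function(al) density_dependent_loss(1.3, 0.5, al),
                numeric(1))
  expect_true(all(diff(dda) >= 0))
})

test_that("raw density-independent loss rearranges the Moran identity", {
  expect_equal(density_independent_residual(1, 1, b = 0.23, dd = 0), 0.23)
  expect_equal(density_independent_residual(0.5, 0.5 + 0.23, b = 0.23, dd = 0), 0)
  expect_equal(density_independent_residual(1.0, 0.8, b = 0.23,
                                            dd = tan(pi / 6) * 0.541),
               0.23 - tan(pi / 6) * 0.541 + 0.2, tolerance = 1e-12)
})

test_that("the Moran identity holds exactly for every decomposed pair", {
  sim <- simulate_population(synthetic_config(n_stops = c(8, 8)), seed = 11)
  tr <- build_transitions(sim$catches, sim$covariates)
  for (p in list(c(0.23, 0.459, 30), c(0.3, 0.1, 60), c(0.2, 1.2, 0))) {
    dec <- decompose_transitions(tr, p[1], p[2], p[3])
    lhs <- p[1] - dec$di_raw - dec$dd - (dec$y_t1 - dec$y_t)
    expect_lt(max(abs(lhs)), 1e-12)
  }
})

test_that("di regression recovers coefficients and matches normal equations", {
  set.seed(123)
  n <- 500
  X <- tibble::tibble(dlst = runif(n, 25, 45), nlst = runif(n, 10, 25),
                      cattle = runif(n, 0, 200))
  truth <- c(0.6, 0.01, -0.02, -0.004)
  di <- truth[1] + as.matrix(X) %*% truth[-1] + rnorm(n, 0, 0.05)
  fit <- fit_di_regression(drop(di), X)

  # independent oracle: explicit normal-equation solve
  Xmat <- cbind(1, as.matrix(X))
  beta_ne <- drop(solve(crossprod(Xmat), crossprod(Xmat, di)))
  expect_equal(unname(fit$coefficients$estimate), unname(beta_ne),
               tolerance = 1e-8)
  # estimates within 3 standard errors of the truth
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    3 * fit$coefficients$std.error))
  # residual mean zero with intercept; smoothing shrinks variance
  expect_lt(abs(mean(fit$residuals)), 1e-10)
  expect_lt(var(fit$di_hat), var(drop(di)))

  # noise-free linear signal recovered to machine precision
  di_exact <- drop(truth[1] + as.matrix(X) %*% truth[-1])
  fit0 <- suppressWarnings(fit_di_regression(di_exact, X))
  expect_equal(unname(fit0$coefficients$estimate), unname(truth),
               tolerance = 1e-10)

  # intercept-only fit returns the mean
  fitm <- fit_di_regression(drop(di), NULL)
  expect_equal(fitm$coefficients$estimate, mean(di))

  # collinear design named in the error
  Xbad <- dplyr::mutate(X, dlst2 = dlst * 2)
  expect_error(fit_di_regression(drop(di), Xbad), "dlst2",
               class = "geomoran_parameter_error")
})

test_that("net change is fertility minus losses", {
  expect_equal(net_change(0.23, 0.13, 0.10), 0)
  expect_equal(net_change(0.23, 0.10, 0.05), 0.08)
})

test_that("log rates convert to natural-scale multiplicative factors", {
  expect_equal(to_natural_scale(0), 1)
  expect_equal(to_natural_scale(0.23), 10^0.23)
  expect_lt(abs(to_natural_scale(0.23) - 1.698), 1e-3)
  expect_lt(abs(to_natural_scale(0.459) - 2.877), 1e-3)
})

test_that("seasonal aggregation averages by site and Zambian season", {
  expect_equal(as.character(season_of(c(2, 6, 9, 12))),
               c("rainy", "cold_dry", "hot_dry", "hot_dry"))
  expect_error(season_of(0), class = "geomoran_validation_error")

  # hand-averaged oracle
  d <- tibble::tibble(site = "s1", t = c(2, 3, 6),
                      net_change = c(0.1, 0.3, -0.2))
  out <- aggregate_net_change(d)
  s1 <- out[out$site == "s1", ]
  expect_equal(s1$rainy, 0.2)
  expect_equal(s1$cold_dry, -0.2)
  expect_true(is.na(s1$hot_dry))
  expect_equal(s1$year_mean, mean(c(0.1, 0.3, -0.2)))

  # constant input propagates to every populated cell
  d2 <- tibble::tibble(site = rep(c("x", "y"), each = 12), t = rep(1:12, 2),
                       net_change = 0.05)
  out2 <- aggregate_net_change(d2)
  expect_true(all(abs(as.matrix(out2[, c("rainy", "cold_dry", "hot_dry",
                                         "year_mean")]) - 0.05) < 1e-12))
  expect_equal(out2$site, c("x", "y", "all sites"))
})
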