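# Spatio-temporal correlation, marginal likelihood, MCMC, DIC, selection.

test_that("non-separable correlation matches scalar evaluation and limits", {
  # unit diagonal at zero separation
  g <- gp_residuals(n_stops = 4, n_months = 3)$geometry
  om <- st_correlation(g, 1.5, 1, 0.8)
  expect_equal(diag(om), rep(1, nrow(om)))
  expect_equal(om, t(om))
  expect_true(all(om > 0 & om <= 1))

  # scalar oracle at posterior-median-like parameters, ds = 1 km, dt = 1 month
  ds <- matrix(c(0, 1, 1, 0), 2)
  dt <- matrix(c(0, 1, 1, 0), 2)
  om2 <- st_correlation(ds, 1.568, 0.975, 0.864, d_time = dt)
  oracle <- exp(-1 / 1.568 - 1 / 0.975 - 0.864 * (1 / 1.568) * (1 / 0.975))
  expect_equal(om2[1, 2], oracle, tolerance = 1e-12)
  expect_lt(abs(om2[1, 2] - 0.1077), 5e-4)

  # delta = 0 factorises into spatial x temporal exponentials
  om0 <- st_correlation(g, 1.2, 0.7, 0)
  expect_equal(om0, unname(exp(-g$d_space / 1.2) * exp(-g$d_time / 0.7)),
               tolerance = 1e-12)

  expect_error(st_correlation(g, -1, 1, 0.5), class = "geomoran_parameter_error")
  expect_error(st_correlation(g, 1, 1, 1.5), class = "geomoran_parameter_error")
})

test_that("correlation matrices stay positive semi-definite across draws", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:25, 1)
    df <- tibble::tibble(lon = 31.8 + runif(n, 0, 0.1),
                         lat = -13.7 + runif(n, 0, 0.1),
                         t = sample(1:12, n, replace = TRUE))
    g <- project_geometry(df)
    om <- st_correlation(g, runif(1, 0.05, 3), runif(1, 0.05, 6), runif(1))
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("marginal likelihood equals the brute-force Gaussian density", {
  # standard normal at its mode
  expect_equal(marginal_loglik(0, 0, 0.4, 0.6, matrix(1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    df <- tibble::tibble(lon = 31.8 + runif(n, 0, 0.05),
                         lat = -13.7 + runif(n, 0, 0.05),
                         t = sample(1:4, n, replace = TRUE))
    g <- project_geometry(df)
    om <- st_correlation(g, runif(1, 0.2, 2), runif(1, 0.2, 3), runif(1))
    s2z <- runif(1, 0.05, 0.5); s2e <- runif(1, 0.01, 0.2)
    y <- rnorm(n); mu <- rnorm(n)
    S <- s2z * om + s2e * diag(n)
    oracle <- -0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
                        drop(t(y - mu) %*% solve(S) %*% (y - mu)))
    expect_equal(marginal_loglik(y, mu, s2z, s2e, om), oracle,
                 tolerance = 1e-10)
  }

  # sigma2_z -> 0 reduces to independent normals
  y <- c(0.3, -0.1, 0.5); mu <- rep(0, 3)
  ds3 <- matrix(0.5, 3, 3); diag(ds3) <- 0
  om3 <- st_correlation(ds3, 1, 1, 0, d_time = matrix(0, 3, 3))
  ll <- marginal_loglik(y, mu, 1e-14, 0.09, om3)
  expect_equal(ll, sum(dnorm(y, 0, 0.3, log = TRUE)), tolerance = 1e-6)
})

test_that("MCMC is bit-reproducible from its seed", {
  sim <- gp_residuals(n_stops = 6, n_months = 6, seed = 2)
  ctrl <- mcmc_control(n_adapt = 60, n_keep = 60, max_rounds = 1,
                       mc_error_target = Inf, gr_threshold = Inf)
  ch1 <- suppressWarnings(run_mcmc(sim$r, sim$geometry, control = ctrl, seed = 7))
  ch2 <- suppressWarnings(run_mcmc(sim$r, sim$geometry, control = ctrl, seed = 7))
  expect_identical(ch1$chains, ch2$chains)
  expect_identical(ch1$thinned, ch2$thinned)
})

test_that("with the likelihood switched off the sampler returns the prior", {
  sim <- gp_residuals(n_stops = 4, n_months = 4, seed = 3)
  ctrl <- mcmc_control(n_adapt = 400, n_keep = 2000, max_rounds = 1,
                       temperature = 0, mc_error_target = Inf,
                       gr_threshold = Inf)
  ch <- suppressWarnings(run_mcmc(sim$r, sim$geometry, control = ctrl, seed = 11))
  pooled <- do.call(rbind, ch$chains)
  # phi ~ U(0, 3): quantiles within Monte-Carlo error of the uniform's
  q <- quantile(pooled[, "phi"], c(0.25, 0.5, 0.75))
  expect_lt(max(abs(q - c(0.75, 1.5, 2.25))), 0.2)
  expect_lt(abs(mean(pooled[, "phi"]) - 1.5), 0.1)
  # delta ~ U(0, 1)
  expect_lt(abs(mean(pooled[, "delta"]) - 0.5), 0.05)
})

test_that("the full convergence contract is attainable at small n", {
  sim <- gp_residuals(n_stops = 10, n_months = 8, seed = 4)
  ctrl <- mcmc_control(n_adapt = 400, n_keep = 1200, max_rounds = 4,
                       mc_error_target = 0.05, gr_threshold = 1.1)
  ch <- run_mcmc(sim$r, sim$geometry, control = ctrl, seed = 21)
  expect_true(ch$converged)
  expect_true(all(ch$gelman_rubin < 1.1))
  # relative MC error of every parameter at most 5% of its posterior sd
  expect_true(all(ch$mc_error <= 0.05))
  expect_equal(nrow(ch$thinned), 200)
  # posterior summaries bracket the generating values at this modest n for
  # the well-identified parameters
  td <- tidy(ch)
  for (p in c("rho", "sigma2_z", "sigma2_e")) {
    row <- td[td$term == p, ]
    expect_gt(sim$truth[[p]], row$hpd_lower - 1e-9)
    expect_lt(sim$truth[[p]], row$hpd_upper + row$sd)
  }
})

test_that("DIC reduces to the plug-in deviance for a degenerate chain", {
  theta <- c(phi = 1.5, rho = 1, delta = 0.5, sigma2_z = 0.2, sigma2_e = 0.05)
  chain <- structure(list(
    thinned = matrix(rep(theta, each = 50), 50, 5,
                     dimnames = list(NULL, names(theta))),
    converged = TRUE
  ), class = "mcmc_chain")
  llf <- function(th) -0.5 * sum(th^2)  # arbitrary smooth function
  out <- compute_dic(chain, loglik_fn = llf)
  expect_equal(out$p_d, 0, tolerance = 1e-10)
  expect_equal(out$dic, out$d_hat, tolerance = 1e-10)
})

test_that("DIC matches the closed-form quadratic identity in a Gaussian case", {
  # known-variance Gaussian mean model: deviance is quadratic in mu, so
  # pD = n * Var_post(mu) exactly, approximately 1 under the flat prior
  set.seed(31)
  n <- 40
  y <- rnorm(n, 2, 1)
  mu_draws <- rnorm(400, mean(y), sqrt(1 / n))
  thinned <- cbind(phi = mu_draws, rho = 1, delta = 0, sigma2_z = 1,
                   sigma2_e = 0)
  chain <- structure(list(thinned = thinned, converged = TRUE),
                     class = "mcmc_chain")
  llf <- function(th) sum(dnorm(y, th[1], 1, log = TRUE))
  out <- compute_dic(chain, loglik_fn = llf)
  pop_var <- mean(mu_draws^2) - mean(mu_draws)^2
  expect_equal(out$p_d, n * pop_var, tolerance = 1e-8)
  expect_lt(abs(out$p_d - 1), 0.5)

  # refusal on a non-converged chain
  chain$converged <- FALSE
  expect_error(compute_dic(chain, loglik_fn = llf),
               class = "geomoran_convergence_error")
  expect_no_error(compute_dic(chain, loglik_fn = llf,
                              allow_nonconverged = TRUE))
})

test_that("candidate selection takes the lowest DIC with grid-order ties", {
  one <- tibble::tibble(candidate = 1, b = 0.2, a = 0, alpha = 0, dic = 700)
  expect_equal(select_candidate(one)$candidate, 1)

  three <- tibble::tibble(candidate = 1:3, dic = c(700, 560, 693))
  expect_equal(select_candidate(three)$dic, 560)

  tied <- tibble::tibble(candidate = c(4, 2, 9), dic = c(500, 500, 450))
  expect_equal(select_candidate(tied)$candidate, 9)
  tied2 <- tibble::tibble(candidate = c(4, 2), dic = c(500, 500))
  expect_equal(select_candidate(tied2)$candidate, 2)

  none <- tibble::tibble(candidate = 1:2, dic = c(500, 510),
                         eligible = c(FALSE, FALSE))
  expect_error(select_candidate(none), class = "geomoran_selection_error")
  expect_warning(sel <- select_candidate(none, allow_ineligible = TRUE))
  expect_equal(sel$candidate, 1)
})

test_that("the block-Toeplitz grid path matches the generic likelihood", {
  cfg <- synthetic_config(n_stops = c(7, 5))
  sim <- simulate_population(cfg, seed = 3)
  tr <- build_transitions(sim$catches, sim$covariates)
  geo <- project_geometry(tr)
  set.seed(9)
  r <- rnorm(nrow(tr))
  blocks <- geomoran:::make_blocks(r, geo, site = tr$site)
  for (b in blocks) {
    expect_false(is.null(b$grid))  # complete stops x months layout
    for (pars in list(c(1.3, 0.9, 0.7, 0.8), c(0.4, 2.5, 0.1, 0.3))) {
      p1 <- geomoran:::.collapsed_parts_cpp(b$r, b$ds, b$dt, b$dsdt,
                                            pars[1], pars[2], pars[3], pars[4])
      p2 <- geomoran:::.collapsed_parts_grid_cpp(b$grid$r_perm, b$grid$ds_stop,
                                                 b$grid$months,
                                                 pars[1], pars[2], pars[3],
                                                 pars[4])
      expect_equal(p1, p2, tolerance = 1e-10)
    }
  }
  # a gappy layout falls back to the generic path
  tr_gap <- tr[-3, ]
  geo_gap <- project_geometry(tr_gap)
  b_gap <- geomoran:::make_blocks(rnorm(nrow(tr_gap)), geo_gap,
                                  site = tr_gap$site)
  expect_true(is.null(b_gap[[1]]$grid))
})

test_that("likelihood is invariant to the fertility value b", {
  # the intercept of the di regression absorbs b, so candidates differing
  # only in b share residuals, likelihood and DIC exactly
  sim <- simulate_population(synthetic_config(n_stops = c(10, 10)), seed = 17)
  tr <- build_transitions(sim$catches, sim$covariates)
  grid <- make_candidate_grid(3, c(0.1, 0.4), 2, c(0.2, 0.6), 2, c(20, 40))
  rc <- geomoran:::residual_classes(tr, grid)
  expect_equal(nrow(rc$classes), 4)  # 2 x 2 distinct (a, alpha)
  # residuals computed from decompositions at different b agree exactly
  for (k in c(1, 4)) {
    a <- rc$classes$a[k]; al <- rc$classes$alpha[k]
    r_low <- local({
      d <- decompose_transitions(tr, 0.1, a, al); d$y_t1 - d$y_t - d$net_change
    })
    r_high <- local({
      d <- decompose_transitions(tr, 0.4, a, al); d$y_t1 - d$y_t - d$net_change
    })
    expect_equal(r_low, r_high, tolerance = 1e-12)
    expect_equal(r_low, rc$R[, k], tolerance = 1e-12)
  }
})
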