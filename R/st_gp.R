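# Bayesian layer: non-separable spatio-temporal Gaussian model for the
# transition residuals, fitted by adaptive random-walk Metropolis with the
# spatio-temporal field Z integrated out of the likelihood.

#' Prior specification for the covariance parameters
#'
#' Defaults: both variances are Inverse-Gamma, `sigma2_z ~ IG(5, 1)` (spatial
#' process) and `sigma2_e ~ IG(0.9, 0.25)` (observation error); ranges are
#' uniform, `phi ~ U(0, 3)` km, `rho ~ U(0, 6)` months, and the space-time
#' interaction `delta ~ U(0, 1)`.
#'
#' @param sigma2_z_shape,sigma2_z_scale Inverse-Gamma shape/scale for the
#'   spatial-process variance.
#' @param sigma2_e_shape,sigma2_e_scale Inverse-Gamma shape/scale for the
#'   observation-error variance.
#' @param phi_max,rho_max,delta_max Upper bounds of the uniform priors.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(sigma2_z_shape = 5, sigma2_z_scale = 1,
                       sigma2_e_shape = 0.9, sigma2_e_scale = 0.25,
                       phi_max = 3, rho_max = 6, delta_max = 1) {
  stopifnot(sigma2_z_shape > 0, sigma2_z_scale > 0,
            sigma2_e_shape > 0, sigma2_e_scale > 0,
            phi_max > 0, rho_max > 0, delta_max > 0, delta_max <= 1)
  structure(list(sigma2_z_shape = sigma2_z_shape, sigma2_z_scale = sigma2_z_scale,
                 sigma2_e_shape = sigma2_e_shape, sigma2_e_scale = sigma2_e_scale,
                 phi_max = phi_max, rho_max = rho_max, delta_max = delta_max),
            class = "prior_spec")
}

#' Non-separable spatio-temporal correlation matrix
#'
#' The double-exponential non-separable family:
#' `Omega(ds, dt) = exp(-ds/phi - dt/rho - delta * (ds/phi) * (dt/rho))`.
#' Symmetric with unit diagonal; when `delta = 0` it factorises into a purely
#' spatial times a purely temporal exponential, and `delta > 0` makes the
#' effective spatial range shrink with temporal separation (space and time
#' interact).
#'
#' @param geometry A [project_geometry()] object, or a spatial distance
#'   matrix in km (then `d_time` must be given).
#' @param phi Spatial range, km (> 0).
#' @param rho Temporal range, months (> 0).
#' @param delta Space-time interaction in \[0, 1\].
#' @param d_time Temporal distance matrix (months) when `geometry` is a
#'   matrix.
#' @return Correlation matrix with entries in (0, 1\].
#' @export
st_correlation <- function(geometry, phi, rho, delta, d_time = NULL) {
  if (phi <= 0 || rho <= 0) {
    abort("ranges phi and rho must be positive", class = "geomoran_parameter_error")
  }
  if (delta < 0 || delta > 1) {
    abort("delta must lie in [0, 1]", class = "geomoran_parameter_error")
  }
  if (inherits(geometry, "study_geometry")) {
    ds <- geometry$d_space
    dt <- geometry$d_time
  } else {
    ds <- geometry
    dt <- d_time
    stopifnot(is.matrix(ds), is.matrix(dt), all(dim(ds) == dim(dt)))
  }
  .st_corr_cpp(ds, dt, phi, rho, delta)
}

#' Marginal Gaussian log-likelihood of the transition residuals
#'
#' Log density of `y` under a multivariate normal with mean `mu` and
#' covariance `sigma2_z * omega + sigma2_e * I`, i.e. with the spatio-temporal
#' field integrated out. Evaluated through a Cholesky factorisation; no
#' explicit inverse is formed.
#'
#' @param y Observed vector (e.g. `y_t1`).
#' @param mu Mean vector (e.g. `y_t + net_change`).
#' @param sigma2_z,sigma2_e Process and error variances (> 0 and >= 0).
#' @param omega Correlation matrix from [st_correlation()].
#' @return Log-likelihood (scalar).
#' @export
marginal_loglik <- function(y, mu, sigma2_z, sigma2_e, omega) {
  stopifnot(length(y) == length(mu), nrow(omega) == length(y))
  r <- y - mu
  S <- sigma2_z * omega
  diag(S) <- diag(S) + sigma2_e
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L)) {
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    abort(sprintf("covariance factorisation failed (smallest eigenvalue %.3e)", ev),
          class = "geomoran_numerical_error")
  }
  u <- forwardsolve(L, r)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
}

# ---- internal: block structure and log posterior -------------------------

param_names <- c("phi", "rho", "delta", "sigma2_z", "sigma2_e")

# Split residuals into per-site blocks (or one global block). Each block
# carries its spatial/temporal distance matrices. Blocks make the likelihood
# block-diagonal: exact when cross-block correlation is truly zero, and an
# excellent approximation when sites are many ranges apart.
make_blocks <- function(residuals, geometry, site = NULL) {
  n <- length(residuals)
  stopifnot(nrow(geometry$points) == n)
  if (is.null(site)) {
    idx_list <- list(seq_len(n))
  } else {
    stopifnot(length(site) == n)
    idx_list <- split(seq_len(n), site)
  }
  lapply(idx_list, function(idx) {
    ds <- geometry$d_space[idx, idx, drop = FALSE]
    dt <- geometry$d_time[idx, idx, drop = FALSE]
    b <- list(r = as.numeric(residuals[idx]), ds = ds, dt = dt, dsdt = ds * dt)
    # complete stops x months grids admit a block-Toeplitz fast path: only
    # one spatial matrix per distinct temporal lag is exponentiated
    pts <- geometry$points[idx, , drop = FALSE]
    key <- paste(signif(pts$x_km, 12), signif(pts$y_km, 12))
    stop_keys <- unique(key)
    ts <- sort(unique(pts$t))
    if (length(stop_keys) * length(ts) == length(idx) &&
        anyDuplicated(paste(key, pts$t)) == 0) {
      ord <- order(match(pts$t, ts), match(key, stop_keys))
      first <- match(stop_keys, key)
      b$grid <- list(r_perm = b$r[ord],
                     ds_stop = ds[first, first, drop = FALSE],
                     months = as.numeric(ts))
    }
    b
  })
}

loglik_theta <- function(blocks, theta) {
  ll <- 0
  for (b in blocks) {
    v <- .mvn_loglik_cpp(b$r, b$ds, b$dt, theta[1], theta[2], theta[3],
                         theta[4], theta[5])
    if (is.na(v)) return(-Inf)
    ll <- ll + v
  }
  ll
}

#' MCMC control settings
#'
#' @param n_chains Number of chains (>= 2 for the Gelman-Rubin diagnostic).
#' @param n_adapt Warm-up iterations per chain during which the random-walk
#'   proposal scale and covariance adapt (discarded).
#' @param n_keep Post-warm-up iterations kept per chain per round.
#' @param max_rounds If diagnostics fail, chains are extended by `n_keep`
#'   further iterations up to this many rounds before being flagged
#'   non-converged.
#' @param thin_target Number of regularly thinned samples retained per
#'   parameter from the pooled kept draws.
#' @param gr_threshold Gelman-Rubin upper limit for convergence (1.1).
#' @param mc_error_target Maximum relative Monte-Carlo error (MC error as a
#'   fraction of the posterior sd), default 5%. Set to `Inf` for
#'   reduced-chain-length screening runs where only the Gelman-Rubin check is
#'   enforced.
#' @param temperature Likelihood temperature; 0 samples the prior (used for
#'   prior-predictive checks), 1 is the posterior.
#' @param site_blocks If `TRUE`, the likelihood is evaluated per site
#'   (block-diagonal covariance). Exact up to cross-site correlations, which
#'   are below `exp(-3)` whenever sites are at least three spatial ranges
#'   apart; roughly an order of magnitude faster at typical study sizes.
#' @param dic_method `"shared"` (one reference MCMC plus importance
#'   reweighting across the candidate grid, then a full refit of the selected
#'   candidate) or `"exact"` (one MCMC per candidate residual class).
#' @return Object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 2, n_adapt = 300, n_keep = 500,
                         max_rounds = 3, thin_target = 200,
                         gr_threshold = 1.1, mc_error_target = 0.05,
                         temperature = 1, site_blocks = FALSE,
                         dic_method = c("shared", "exact")) {
  stopifnot(n_chains >= 1, n_adapt >= 10, n_keep >= 10, max_rounds >= 1)
  structure(list(n_chains = n_chains, n_adapt = n_adapt, n_keep = n_keep,
                 max_rounds = max_rounds, thin_target = thin_target,
                 gr_threshold = gr_threshold, mc_error_target = mc_error_target,
                 temperature = temperature, site_blocks = site_blocks,
                 dic_method = match.arg(dic_method)),
            class = "mcmc_control")
}

# One adaptive chain of the collapsed sampler.
#
# Following the usual variance re-parameterisation for this model family, the
# covariance is written Sigma = s2 * V with V = kappa * Omega + (1 - kappa) * I
# (s2 = sigma2_z + sigma2_e the total variance, kappa the spatial proportion).
# Under the two inverse-gamma priors, s2 integrates out of the posterior in
# closed form, so the random walk only has to explore (phi, rho, delta,
# kappa); s2 is then drawn exactly (Gibbs) from its inverse-gamma conditional
# at every iteration. This removes the stiffest direction of the posterior
# from the Metropolis kernel. A likelihood temperature `T` turns the target
# into the power posterior (T = 0 samples the prior exactly).
run_one_chain <- function(blocks, priors, control, chain_seed, state = NULL) {
  az <- priors$sigma2_z_shape; gz <- priors$sigma2_z_scale
  ae <- priors$sigma2_e_shape; ge <- priors$sigma2_e_scale
  temp <- control$temperature
  n_tot <- sum(vapply(blocks, function(b) length(b$r), integer(1)))

  # collapsed log target over u = (logit phi/max, logit rho/max, logit delta,
  # logit kappa); returns the pieces needed for the s2 Gibbs draw and loglik
  lp <- function(u) {
    p <- plogis(u)
    phi <- priors$phi_max * p[1]
    rho <- priors$rho_max * p[2]
    delta <- priors$delta_max * p[3]
    kap <- p[4]
    logdet <- 0; q <- 0
    if (temp > 0) {
      for (b in blocks) {
        parts <- if (is.null(b$grid)) {
          .collapsed_parts_cpp(b$r, b$ds, b$dt, b$dsdt, phi, rho, delta, kap)
        } else {
          .collapsed_parts_grid_cpp(b$grid$r_perm, b$grid$ds_stop,
                                    b$grid$months, phi, rho, delta, kap)
        }
        if (is.na(parts[1])) return(list(lp = -Inf))
        logdet <- logdet + parts[1]
        q <- q + parts[2]
      }
    }
    shape <- temp * n_tot / 2 + az + ae
    rate <- temp * q / 2 + gz / kap + ge / (1 - kap)
    lp_val <- -0.5 * temp * logdet - shape * log(rate) -
      az * log(kap) - ae * log(1 - kap) +
      sum(log(p[1:3]) + log1p(-p[1:3]))
    list(lp = lp_val, phi = phi, rho = rho, delta = delta, kap = kap,
         logdet = logdet, q = q, shape = shape, rate = rate)
  }

  draw_state <- function(cur) {
    s2 <- 1 / stats::rgamma(1, shape = cur$shape, rate = cur$rate)
    theta <- c(phi = cur$phi, rho = cur$rho, delta = cur$delta,
               sigma2_z = s2 * cur$kap, sigma2_e = s2 * (1 - cur$kap))
    ll <- if (temp > 0) {
      -0.5 * (n_tot * log(2 * pi) + n_tot * log(s2) + cur$logdet + cur$q / s2)
    } else 0
    list(theta = theta, ll = ll)
  }

  if (is.null(state)) {
    set.seed(chain_seed)
    u <- c(qlogis(runif(1, 0.2, 0.8)), qlogis(runif(1, 0.1, 0.6)),
           qlogis(runif(1, 0.2, 0.8)), qlogis(runif(1, 0.4, 0.9)))
    lambda <- 0.4
    Sp <- diag(4)
    chol_Sp <- chol(Sp)
    cur <- lp(u)
    hist_u <- matrix(0, control$n_adapt, 4)
    for (i in seq_len(control$n_adapt)) {
      prop <- u + lambda * drop(rnorm(4) %*% chol_Sp)
      cand <- lp(prop)
      acc <- is.finite(cand$lp) && log(runif(1)) < cand$lp - cur$lp
      if (acc) { u <- prop; cur <- cand }
      lambda <- exp(log(lambda) + i^(-0.6) * ((if (acc) 1 else 0) - 0.234))
      hist_u[i, ] <- u
      if (i >= 50 && i %% 25 == 0) {
        Sp <- stats::cov(hist_u[seq_len(i), , drop = FALSE]) + 1e-6 * diag(4)
        chol_Sp <- chol(Sp)
      }
    }
    state <- list(u = u, cur = cur, lambda = lambda, chol_Sp = chol(Sp),
                  rng = NULL)
  } else {
    # continue an existing chain with the frozen kernel
    assign(".Random.seed", state$rng, envir = globalenv())
    state$cur <- lp(state$u)
  }

  n_iter <- control$n_keep
  draws <- matrix(NA_real_, n_iter, 5, dimnames = list(NULL, param_names))
  lls <- numeric(n_iter)
  n_acc <- 0
  u <- state$u; cur <- state$cur
  for (i in seq_len(n_iter)) {
    prop <- u + state$lambda * drop(rnorm(4) %*% state$chol_Sp)
    cand <- lp(prop)
    if (is.finite(cand$lp) && log(runif(1)) < cand$lp - cur$lp) {
      u <- prop; cur <- cand; n_acc <- n_acc + 1
    }
    st <- draw_state(cur)
    draws[i, ] <- st$theta
    lls[i] <- st$ll
  }
  state$u <- u; state$cur <- cur
  state$rng <- get(".Random.seed", envir = globalenv())
  list(draws = draws, loglik = lls, accept = n_acc / n_iter, state = state)
}

#' Sample the covariance-parameter posterior by adaptive MCMC
#'
#' Runs `n_chains` adaptive random-walk Metropolis chains on
#' (phi, rho, delta, sigma2_z, sigma2_e), jointly updated on an unconstrained
#' scale, against the Gaussian likelihood of the transition residuals with
#' the spatio-temporal field integrated out. Chains extend in rounds until
#' the Gelman-Rubin statistic is below `gr_threshold` for every parameter and
#' the relative Monte-Carlo error is at most `mc_error_target`, or until
#' `max_rounds` is exhausted (then the fit is flagged non-converged, not an
#' error). A regularly thinned set of `thin_target` samples is retained.
#'
#' @param residuals Numeric vector of transition residuals
#'   (`y_t1 - y_t - net_change`).
#' @param geometry [project_geometry()] object for the residual points
#'   (one point per transition, at the stop location and starting month).
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()].
#' @param seed Integer seed; chains are reproducible bit-for-bit from it.
#' @param site Optional site label per residual, used when
#'   `control$site_blocks` is `TRUE`.
#' @return Object of class `mcmc_chain`: kept draws per chain, pooled thinned
#'   draws (with the derived variance proportion `kappa`), log-likelihood
#'   values, Gelman-Rubin statistics, relative MC errors, acceptance rates
#'   and a `converged` flag.
#' @export
run_mcmc <- function(residuals, geometry, priors = prior_spec(),
                     control = mcmc_control(), seed = 1, site = NULL) {
  blocks <- make_blocks(residuals, geometry,
                        site = if (isTRUE(control$site_blocks)) site else NULL)
  chains <- vector("list", control$n_chains)
  for (j in seq_len(control$n_chains)) {
    chain_seed <- (as.numeric(seed) * 1000 + j) %% .Machine$integer.max
    chains[[j]] <- run_one_chain(blocks, priors, control,
                                 chain_seed = chain_seed)
  }

  diag_of <- function(chains) {
    ml <- coda::mcmc.list(lapply(chains, function(ch) coda::mcmc(ch$draws)))
    gr <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, 5))
    pooled <- do.call(rbind, lapply(chains, `[[`, "draws"))
    ess <- pmax(coda::effectiveSize(coda::mcmc(pooled)), 1)
    mc_err <- 1 / sqrt(ess)  # MC error of the mean relative to posterior sd
    list(gr = setNames(gr, param_names), mc_err = setNames(mc_err, param_names))
  }

  d <- diag_of(chains)
  round <- 1
  ok <- function(d) {
    (control$n_chains < 2 || all(is.finite(d$gr) & d$gr < control$gr_threshold)) &&
      all(d$mc_err <= control$mc_error_target)
  }
  while (!ok(d) && round < control$max_rounds) {
    round <- round + 1
    for (j in seq_len(control$n_chains)) {
      ext <- run_one_chain(blocks, priors, control, chain_seed = NA,
                           state = chains[[j]]$state)
      chains[[j]]$draws <- rbind(chains[[j]]$draws, ext$draws)
      chains[[j]]$loglik <- c(chains[[j]]$loglik, ext$loglik)
      chains[[j]]$accept <- mean(c(chains[[j]]$accept, ext$accept))
      chains[[j]]$state <- ext$state
    }
    d <- diag_of(chains)
  }

  pooled <- do.call(rbind, lapply(chains, `[[`, "draws"))
  pooled_ll <- unlist(lapply(chains, `[[`, "loglik"))
  idx <- unique(round(seq(1, nrow(pooled),
                          length.out = min(control$thin_target, nrow(pooled)))))
  thinned <- pooled[idx, , drop = FALSE]
  converged <- ok(d)
  if (!converged) {
    warn("MCMC flagged non-converged at the iteration cap; fit is ineligible for selection")
  }
  at_bound <- c(
    phi = mean(pooled[, "phi"] > 0.99 * priors$phi_max),
    rho = mean(pooled[, "rho"] > 0.99 * priors$rho_max),
    delta = mean(pooled[, "delta"] > 0.99 * priors$delta_max)
  )
  if (any(at_bound > 0.2)) {
    warn(sprintf("posterior mass piles at a uniform prior bound (%s); consider widening the prior",
                 paste(names(at_bound)[at_bound > 0.2], collapse = ", ")))
  }

  structure(
    list(
      chains = lapply(chains, `[[`, "draws"),
      loglik = lapply(chains, `[[`, "loglik"),
      thinned = thinned,
      thinned_loglik = pooled_ll[idx],
      gelman_rubin = d$gr,
      mc_error = d$mc_err,
      accept = vapply(chains, `[[`, numeric(1), "accept"),
      converged = converged,
      rounds = round,
      seed = seed,
      priors = priors,
      control = control,
      blocks = blocks
    ),
    class = "mcmc_chain"
  )
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain> %d chain(s), %d kept draws each, %d thinned; converged: %s\n",
              length(x$chains), nrow(x$chains[[1]]), nrow(x$thinned),
              x$converged))
  cat("Gelman-Rubin:", paste(sprintf("%s=%.3f", names(x$gelman_rubin),
                                     x$gelman_rubin), collapse = " "), "\n")
  invisible(x)
}

#' Posterior summary of an MCMC fit
#'
#' Median, mean, sd and 95% highest-posterior-density interval per parameter,
#' including the derived variance proportion
#' `kappa = sigma2_z / (sigma2_z + sigma2_e)`. Summaries use all pooled kept
#' draws (the 200 thinned samples are retained separately for export and
#' DIC).
#'
#' @param x An `mcmc_chain`.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @export
tidy.mcmc_chain <- function(x, ...) {
  pooled <- do.call(rbind, x$chains)
  s <- cbind(pooled,
             kappa = pooled[, "sigma2_z"] /
               (pooled[, "sigma2_z"] + pooled[, "sigma2_e"]))
  hpd <- coda::HPDinterval(coda::mcmc(s), prob = 0.95)
  tibble::tibble(
    term = colnames(s),
    median = apply(s, 2, median),
    mean = colMeans(s),
    sd = apply(s, 2, sd),
    hpd_lower = hpd[, 1],
    hpd_upper = hpd[, 2]
  )
}

#' Deviance Information Criterion of a converged fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, deviance
#' `D = -2 log L`, and `theta_bar` the posterior mean of the natural-scale
#' parameters, computed over the thinned samples.
#'
#' @param chain An `mcmc_chain`.
#' @param loglik_fn Optional log-likelihood function of a natural-scale
#'   parameter vector (phi, rho, delta, sigma2_z, sigma2_e); defaults to the
#'   likelihood the chain was run against.
#' @param allow_nonconverged Set `TRUE` to compute DIC for a flagged chain
#'   anyway (screening use).
#' @return A list with `dic`, `dbar`, `d_hat`, `p_d`.
#' @export
compute_dic <- function(chain, loglik_fn = NULL, allow_nonconverged = FALSE) {
  stopifnot(inherits(chain, "mcmc_chain"))
  if (!chain$converged && !allow_nonconverged) {
    abort("refusing to compute DIC from a non-converged chain",
          class = "geomoran_convergence_error")
  }
  theta_bar <- colMeans(chain$thinned)
  if (is.null(loglik_fn)) {
    lls <- chain$thinned_loglik
    ll_hat <- loglik_theta(chain$blocks, theta_bar)
  } else {
    lls <- apply(chain$thinned, 1, loglik_fn)
    ll_hat <- loglik_fn(theta_bar)
  }
  dbar <- mean(-2 * lls)
  d_hat <- -2 * ll_hat
  list(dic = 2 * dbar - d_hat, dbar = dbar, d_hat = d_hat, p_d = dbar - d_hat)
}
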