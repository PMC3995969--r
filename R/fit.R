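# Candidate-grid fitting and DIC selection.
#
# A demographic candidate (b, a, alpha) determines the mean of the Gaussian
# model; the covariance parameters are sampled by MCMC and each candidate is
# scored by DIC, the lowest winning. Two exact algebraic facts shape the
# implementation:
#
#  * the model residual is r = (I - H)(dy + dd), where H is the hat matrix of
#    the density-independent OLS (which contains an intercept) and
#    dy = y_t1 - y_t. Since dd depends only on (a, alpha), candidates sharing
#    (a, alpha) have identical residuals, likelihoods and DICs whatever their
#    b: the data cannot rank fertility values. Candidates are therefore
#    grouped into (a, alpha) "residual classes" and scored once per class.
#
#  * because the intercept absorbs b, the per-transition net change
#    b - di_hat - dd is also invariant to b. Net-change maps do not depend on
#    the fertility value chosen.

residual_classes <- function(transitions, grid,
                             covariate_names = intersect(
                               c("dlst", "nlst", "cattle"), names(transitions))) {
  classes <- dplyr::distinct(grid, .data$a, .data$alpha)
  classes$class_id <- seq_len(nrow(classes))
  dy <- transitions$y_t1 - transitions$y_t
  X <- if (length(covariate_names) > 0) {
    stats::model.matrix(~ ., data = as.data.frame(transitions[covariate_names]))
  } else {
    matrix(1, nrow(transitions), 1)
  }
  qrX <- qr(X)
  R <- matrix(NA_real_, nrow(transitions), nrow(classes))
  for (k in seq_len(nrow(classes))) {
    dd <- density_dependent_loss(transitions$y_t, classes$a[k], classes$alpha[k])
    v <- dy + dd
    R[, k] <- v - qr.fitted(qrX, v)   # (I - H) v
  }
  key <- paste(signif(grid$a, 12), signif(grid$alpha, 12))
  ckey <- paste(signif(classes$a, 12), signif(classes$alpha, 12))
  list(classes = classes, R = R, class_of = match(key, ckey))
}

# block list carrying a residual matrix instead of a single vector
make_blocks_multi <- function(R, geometry, site = NULL) {
  n <- nrow(R)
  idx_list <- if (is.null(site)) list(seq_len(n)) else split(seq_len(n), site)
  lapply(idx_list, function(idx) {
    list(R = R[idx, , drop = FALSE],
         ds = geometry$d_space[idx, idx, drop = FALSE],
         dt = geometry$d_time[idx, idx, drop = FALSE])
  })
}

loglik_multi_theta <- function(blocks, theta) {
  ll <- 0
  for (b in blocks) {
    v <- .mvn_loglik_multi_cpp(b$R, b$ds, b$dt, theta[1], theta[2], theta[3],
                               theta[4], theta[5])
    ll <- ll + v
  }
  ll
}

#' Fit the candidate grid and select the demographic parameterisation by DIC
#'
#' Runs the full Bayesian layer over a [make_candidate_grid()]: for each
#' candidate, the density-independent regression is refit, the covariance
#' parameters are sampled, the DIC is computed, and the candidate with the
#' lowest DIC is selected (ties broken by grid order). Candidates that share
#' `(a, alpha)` have provably identical likelihoods (see package vignette) and
#' are scored once.
#'
#' With `control$dic_method = "shared"` (default) one full MCMC is run at a
#' reference residual class chosen by profile likelihood, every class's DIC
#' is computed by importance-reweighting the thinned reference draws, and the
#' selected class is then refit with its own full MCMC. `"exact"` runs a full
#' MCMC per class, the exhaustive alternative, at desk-unfriendly
#' cost for large grids.
#'
#' @param transitions Transition table from [build_transitions()].
#' @param grid Candidate grid tibble.
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()].
#' @param seed Integer seed.
#' @param strict If `TRUE` (default), selection refuses to proceed when no
#'   candidate has a converged chain. `FALSE` selects anyway with a warning
#'   and records the convergence flags — screening use (e.g. simulation
#'   batches at reduced chain lengths).
#' @return Object of class `moran_fit`: the selected candidate and its
#'   decomposition, regression and posterior chain, plus the per-candidate
#'   DIC table (`$candidates`).
#' @export
fit_candidates <- function(transitions, grid = make_candidate_grid(5, c(0.2, 0.4),
                                                                   5, c(0, 1.5),
                                                                   5, c(0, 80)),
                           priors = prior_spec(), control = mcmc_control(),
                           seed = 1, strict = TRUE) {
  geometry <- project_geometry(transitions)
  site <- if (isTRUE(control$site_blocks)) transitions$site else NULL
  rc <- residual_classes(transitions, grid)
  K <- nrow(rc$classes)
  blocks <- make_blocks_multi(rc$R, geometry, site)

  class_dic <- rep(NA_real_, K)
  class_eligible <- rep(FALSE, K)

  if (control$dic_method == "exact") {
    chains <- vector("list", K)
    for (k in seq_len(K)) {
      ch <- run_mcmc(rc$R[, k], geometry, priors, control,
                     seed = seed + k, site = site)
      chains[[k]] <- ch
      class_eligible[k] <- ch$converged
      class_dic[k] <- compute_dic(ch, allow_nonconverged = TRUE)$dic
    }
  } else {
    # profile screen at a fixed plausible covariance value to pick the
    # reference class for the shared MCMC
    v <- stats::median(apply(rc$R, 2, var))
    theta0 <- c(priors$phi_max / 2, min(1, priors$rho_max / 2), 0.5,
                0.6 * v, 0.4 * v)
    ll0 <- loglik_multi_theta(blocks, theta0)
    ref <- which.max(ll0)

    chain <- run_mcmc(rc$R[, ref], geometry, priors, control,
                      seed = seed, site = site)
    # deviance of every class at every thinned draw
    M <- matrix(NA_real_, nrow(chain$thinned), K)
    for (m in seq_len(nrow(chain$thinned))) {
      M[m, ] <- loglik_multi_theta(blocks, chain$thinned[m, ])
    }
    for (k in seq_len(K)) {
      lw <- M[, k] - M[, ref]
      w <- exp(lw - max(lw)); w <- w / sum(w)
      theta_bar <- colSums(chain$thinned * w)
      ll_hat <- loglik_multi_theta(
        make_blocks_multi(rc$R[, k, drop = FALSE], geometry, site), theta_bar)
      dbar <- sum(w * (-2 * M[, k]))
      class_dic[k] <- 2 * dbar - (-2 * ll_hat)
      class_eligible[k] <- chain$converged
    }
    chains <- list(chain)
    names(chains) <- as.character(ref)
  }

  candidates <- grid |>
    dplyr::mutate(class_id = rc$class_of,
                  dic = class_dic[rc$class_of],
                  eligible = class_eligible[rc$class_of])
  best <- select_candidate(candidates, allow_ineligible = !strict)

  # posterior for the selected class from its own full MCMC
  sel_class <- best$class_id
  if (control$dic_method == "exact") {
    sel_chain <- chains[[sel_class]]
  } else if (as.character(sel_class) %in% names(chains)) {
    sel_chain <- chains[[as.character(sel_class)]]
  } else {
    sel_chain <- run_mcmc(rc$R[, sel_class], geometry, priors, control,
                          seed = seed, site = site)
  }

  decomposition <- decompose_transitions(transitions, best$b, best$a, best$alpha)

  structure(
    list(
      b = best$b, a = best$a, alpha = best$alpha,
      dic = best$dic,
      candidates = candidates,
      decomposition = decomposition,
      regression = attr(decomposition, "regression"),
      chain = sel_chain,
      residuals = rc$R[, sel_class],
      geometry = geometry,
      transitions = transitions,
      priors = priors, control = control, seed = seed
    ),
    class = "moran_fit"
  )
}

#' Select the lowest-DIC candidate
#'
#' Returns the eligible (converged) candidate with the smallest DIC; exact
#' ties are broken deterministically by grid order (lowest b, then a, then
#' alpha).
#'
#' @param candidates Tibble with at least `candidate` and `dic` columns and
#'   optionally `eligible`.
#' @param allow_ineligible Fall back to non-converged candidates (with a
#'   warning) when no eligible one exists.
#' @return The selected row (one-row tibble).
#' @export
select_candidate <- function(candidates, allow_ineligible = FALSE) {
  stopifnot(all(c("candidate", "dic") %in% names(candidates)))
  el <- if ("eligible" %in% names(candidates)) candidates$eligible else
    rep(TRUE, nrow(candidates))
  pool <- candidates[el & is.finite(candidates$dic), , drop = FALSE]
  if (nrow(pool) == 0 && allow_ineligible) {
    warn("no converged candidate; selecting among non-converged fits (screening mode)")
    pool <- candidates[is.finite(candidates$dic), , drop = FALSE]
  }
  if (nrow(pool) == 0) {
    abort("no eligible (converged, finite-DIC) candidate to select",
          class = "geomoran_selection_error")
  }
  pool <- pool[order(pool$dic, pool$candidate), , drop = FALSE]
  pool[1, ]
}

#' @export
print.moran_fit <- function(x, ...) {
  cat("Bayesian geostatistical Moran-curve fit\n")
  cat(sprintf("  selected candidate: b = %.4g (x%.3g/month), a = %.4g (%.3g flies), alpha = %.3g deg\n",
              x$b, 10^x$b, x$a, 10^x$a, x$alpha))
  cat(sprintf("  DIC = %.1f over %d candidate(s); chain converged: %s\n",
              x$dic, nrow(x$candidates), x$chain$converged))
  invisible(x)
}

#' Posterior and regression summaries of a fitted model
#'
#' Rows for the covariance parameters (posterior median, mean, sd, 95% HPD)
#' followed by the density-independent regression coefficients (estimate,
#' standard error, t-value), mirroring the usual report layout.
#'
#' @param x A `moran_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.moran_fit <- function(x, ...) {
  post <- tidy(x$chain) |>
    dplyr::mutate(component = "posterior", .before = 1)
  reg <- tidy(x$regression) |>
    dplyr::rename(mean = "estimate", sd = "std.error") |>
    dplyr::mutate(component = "regression", median = NA_real_,
                  hpd_lower = NA_real_, hpd_upper = NA_real_) |>
    dplyr::select("component", "term", "median", "mean", "sd",
                  "hpd_lower", "hpd_upper", "statistic", "p.value")
  dplyr::bind_rows(post, reg)
}

#' @export
glance.moran_fit <- function(x, ...) {
  tibble::tibble(
    b = x$b, a = x$a, alpha = x$alpha, dic = x$dic,
    n_pairs = nrow(x$transitions),
    n_candidates = nrow(x$candidates),
    converged = x$chain$converged
  )
}
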