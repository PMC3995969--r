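# Small in-code fixtures shared across test files.

# a tiny valid catch table: one site, two stops, several months
tiny_catches <- function(months = 1:6, counts = NULL) {
  g <- expand.grid(stop_id = c("a", "b"), month = months,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(g)
  tibble::tibble(
    site = "s1",
    stop_id = g$stop_id,
    lon = ifelse(g$stop_id == "a", 31.800, 31.801),
    lat = -13.70,
    month = g$month,
    count = if (is.null(counts)) rep_len(c(0L, 2L, 1L, 3L), n) else counts
  )
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  path
}

# residuals drawn exactly from the spatio-temporal Gaussian model on a small
# stop x month layout; returns residuals + geometry (+ truth used)
gp_residuals <- function(n_stops = 12, n_months = 10, phi = 1.5, rho = 1,
                         delta = 0.8, sigma2_z = 0.27, sigma2_e = 0.06,
                         seed = 1) {
  set.seed(seed)
  pts <- expand.grid(stop = seq_len(n_stops), t = seq_len(n_months))
  df <- tibble::tibble(
    lon = 31.8 + (pts$stop - 1) * 0.1 / 111.32 / cos(-13.7 * pi / 180),
    lat = -13.7,
    t = pts$t
  )
  geo <- project_geometry(df)
  omega <- st_correlation(geo, phi, rho, delta)
  S <- sigma2_z * omega + sigma2_e * diag(nrow(omega))
  r <- drop(t(chol(S)) %*% rnorm(nrow(omega)))
  list(r = r, geometry = geo,
       truth = c(phi = phi, rho = rho, delta = delta,
                 sigma2_z = sigma2_z, sigma2_e = sigma2_e))
}

fast_control <- function(...) {
  mcmc_control(n_adapt = 150, n_keep = 200, max_rounds = 2,
               mc_error_target = Inf, site_blocks = TRUE, ...)
}
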