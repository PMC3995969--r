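# YAML-driven pipeline configuration.

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys (all optional): `priors` (arguments of
#' [prior_spec()]), `mcmc` (arguments of [mcmc_control()]), `grid`
#' (`n_b`, `b_range`, `n_a`, `a_range`, `n_alpha`, `alpha_range`), and
#' `seed`. Unrecognised keys raise an error to catch typos early.
#'
#' @param path Path to a YAML file.
#' @return List with elements `priors`, `control`, `grid`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("priors", "mcmc", "grid", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown configuration key(s): %s", paste(extra, collapse = ", ")),
          class = "geomoran_schema_error")
  }
  grid_args <- raw$grid %||% list()
  for (nm in c("b_range", "a_range", "alpha_range")) {
    if (!is.null(grid_args[[nm]])) grid_args[[nm]] <- as.numeric(grid_args[[nm]])
  }
  list(
    priors = do.call(prior_spec, raw$priors %||% list()),
    control = do.call(mcmc_control, raw$mcmc %||% list()),
    grid = do.call(make_candidate_grid, grid_args),
    seed = raw$seed %||% 1L
  )
}
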