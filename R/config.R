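#' Run configuration for the analysis pipeline
#'
#' Collects the knobs shared across stages: the genome-size threshold that
#' defines "large" genomes, the MCMC schedule and variance prior of the
#' phylogenetic mixed model, the permutation count of the signal test, and
#' the random seed.
#'
#' @param gs_threshold_pg Genome-size threshold in pg; a 1C-value at or
#'   above it counts as "large". Default 5; conventional alternatives are
#'   2.5, 3 and 6.
#' @param iterations,burn_in,thinning MCMC schedule for the phylogenetic
#'   mixed model. Defaults are a desk-scale schedule (60000/10000/10) that
#'   the conjugate sampler mixes well under; production-scale schedules are
#'   just larger numbers here.
#' @param prior_v,prior_nu Scale and degree-of-belief of the
#'   scaled-inverse-chi-square prior applied to every variance component.
#' @param n_perm Permutations for the Blomberg K randomisation test.
#' @param seed Integer seed; fixes every stochastic stage.
#' @return A list with class `cwm_config`.
#' @export
run_config <- function(gs_threshold_pg = 5,
                       iterations = 60000, burn_in = 10000, thinning = 10,
                       prior_v = 1, prior_nu = 0.5,
                       n_perm = 999, seed = 1L) {
  if (gs_threshold_pg <= 0) abort("gs_threshold_pg must be positive")
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  if (thinning < 1) abort("thinning must be >= 1")
  if (prior_v <= 0) abort("prior_v must be positive")
  if (prior_nu < 0) abort("prior_nu must be non-negative")
  structure(
    list(gs_threshold_pg = gs_threshold_pg,
         iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thinning = as.integer(thinning),
         prior_v = prior_v, prior_nu = prior_nu,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "cwm_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_config`, a `cwm_config`; for `write_config`, `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is needed to read configuration files")
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `cwm_config`.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is needed to write configuration files")
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
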