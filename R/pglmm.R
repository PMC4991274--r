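#' Build the design of the phylogenetic mixed model
#'
#' Assembles, from the community tables and tree, the pieces of the
#' Gaussian "animal model" for log biomass: response `y = ln(biomass g)`
#' over occupied (biomass > 0) species-subplot pairs only; the 17-column
#' fixed design of [fixed_terms()] (genome size as ln 1C, N/P/ploidy as
#' 0-1 indicators, pH raw so its slope is interpretable per pH unit);
#' plot and species grouping factors; and the species-level phylogenetic
#' covariance scaled to unit maximum diagonal (making the phylogenetic
#' variance comparable across trees).
#'
#' @param biomass,species,design Community tables.
#' @param tree Rooted `phylo` covering the species.
#' @param terms Fixed-effect terms to keep, a subset of [fixed_terms()];
#'   the full 17-term structure by default. Reduced structures (e.g. main
#'   effects only) are the natural choice when the scientific question
#'   concerns a main effect, and for parameter-recovery studies whose
#'   generating model has no interactions.
#' @return A list of class `pglmm_design`: `y`, `X`, `plot` (factor),
#'   `species` (factor levelled like the covariance), `C`, `n_dropped`
#'   (zero-biomass rows excluded).
#' @export
pglmm_design <- function(biomass, species, design, tree,
                         terms = fixed_terms()) {
  bad <- setdiff(terms, fixed_terms())
  if (length(bad)) abort(paste0("unknown terms: ", paste(bad, collapse = ", ")))
  design <- classify_treatment(design)
  dat <- biomass |>
    inner_join(species, by = "species_id") |>
    inner_join(select(design, "subplot_id", "plot_id", "n_on", "p_on", "ph"),
               by = "subplot_id")
  n_dropped <- sum(dat$biomass_g <= 0)
  dat <- dat |> filter(.data$biomass_g > 0)
  if (!nrow(dat)) abort("no occupied species-subplot pairs")
  C <- phylo_covariance(tree)
  keep <- intersect(rownames(C), unique(dat$species_id))
  if (!length(keep)) abort("no overlap between tree tips and biomass species")
  C <- C[keep, keep, drop = FALSE]
  C <- C / max(diag(C))
  dat <- dat |> filter(.data$species_id %in% keep)
  X <- build_fixed_matrix(
    gs = log(dat$one_c_pg),
    n = as.numeric(dat$n_on), p = as.numeric(dat$p_on),
    ploidy = as.numeric(dat$ploidy_class == "polyploid"),
    ph = dat$ph
  )
  X <- X[, terms, drop = FALSE]
  structure(
    list(y = log(dat$biomass_g), X = X,
         plot = factor(dat$plot_id),
         species = factor(dat$species_id, levels = rownames(C)),
         C = C, n_dropped = n_dropped),
    class = "pglmm_design"
  )
}

#' Variance prior of the phylogenetic mixed model
#'
#' Each variance component gets a scaled-inverse-chi-square prior with
#' scale `v` and degree-of-belief `nu`, i.e. an inverse-gamma with shape
#' `nu/2` and rate `nu*v/2`. `v` and `nu` may be scalars (shared across
#' components) or length-4 vectors ordered plot, phylogeny, species,
#' residual — e.g. to pin the random-effect variances near zero while
#' leaving the residual free. `nu = 0` is the (improper) flat limit and
#' is accepted with a warning.
#'
#' @param v Prior scale(s) (> 0); length 1 or 4.
#' @param nu Prior degrees of freedom (>= 0); length 1 or 4.
#' @return A list of class `pglmm_prior` with length-4 `v` and `nu`.
#' @export
pglmm_prior <- function(v = 1, nu = 0.5) {
  if (any(v <= 0)) abort("prior scale v must be positive")
  if (any(nu < 0)) abort("prior nu must be non-negative")
  if (!length(v) %in% c(1, 4) || !length(nu) %in% c(1, 4)) {
    abort("v and nu must have length 1 or 4 (plot, phylo, species, residual)")
  }
  if (any(nu == 0)) warn("nu = 0 is an improper flat prior; the posterior may be improper for empty components")
  comp <- c("plot", "phylo", "species", "residual")
  structure(list(v = setNames(rep_len(v, 4), comp),
                 nu = setNames(rep_len(nu, 4), comp)),
            class = "pglmm_prior")
}

#' Conjugate Gibbs sampler for the phylogenetic mixed model
#'
#' Samples the posterior of the Gaussian mixed model
#' \deqn{y = X\beta + Z_{plot} u + Z_{sp} s + Z_{sp} a + e}
#' with \eqn{u \sim N(0, \sigma^2_{plot} I)},
#' \eqn{s \sim N(0, \sigma^2_{sp} I)},
#' \eqn{a \sim N(0, \sigma^2_{phy} C)} (phylogenetic effect) and
#' \eqn{e \sim N(0, \sigma^2_e I)}. All location effects are updated in
#' one multivariate-normal block from their joint full conditional (the
#' phylogenetic block contributes \eqn{C^{-1}/\sigma^2_{phy}} to the
#' precision); each variance then follows its scaled-inverse-chi-square
#' full conditional. Fixed effects carry a diffuse normal prior
#' (precision 1e-8). Chains are deterministic given `seed`.
#'
#' Run with a zero-row design the sampler draws each variance from its
#' prior, which is the exact posterior in that case (used by the
#' prior-recovery checks).
#'
#' @param dsg A [pglmm_design()] (or a list with the same fields).
#' @param prior A [pglmm_prior()].
#' @param iterations,burn_in,thinning MCMC schedule.
#' @param seed Integer seed.
#' @return A list of class `cwm_pglmm`: `chains` (matrix, one column per
#'   retained parameter: the 17 fixed effects then `var_plot`,
#'   `var_phylo`, `var_species`, `var_residual`), `terms` tibble with a
#'   `type` column (`fixed` / `variance`), the schedule, prior and seed.
#' @export
pglmm_gibbs <- function(dsg, prior = pglmm_prior(),
                        iterations = 60000, burn_in = 10000, thinning = 10,
                        seed = 1L) {
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  if (thinning < 1) abort("thinning must be >= 1")
  set.seed(seed)
  n_keep <- floor((iterations - burn_in) / thinning)

  if (is.null(dsg$y) || length(dsg$y) == 0) {
    # prior-only: the variance posterior is the prior itself
    draws <- vapply(seq_len(4), function(j) {
      1 / rgamma(n_keep, shape = prior$nu[j] / 2,
                 rate = prior$nu[j] * prior$v[j] / 2)
    }, numeric(n_keep))
    colnames(draws) <- c("var_plot", "var_phylo", "var_species", "var_residual")
    return(new_pglmm(draws, prior, iterations, burn_in, thinning, seed,
                     fixed_names = character(0)))
  }

  y <- dsg$y
  X <- dsg$X
  plot_f <- droplevels(dsg$plot)
  sp_f <- dsg$species
  C <- dsg$C
  n <- length(y)
  p <- ncol(X)
  np <- nlevels(plot_f)
  ns <- nlevels(sp_f)

  Zp <- stats::model.matrix(~ 0 + plot_f)
  Zs <- stats::model.matrix(~ 0 + sp_f)
  W <- cbind(X, Zp, Zs, Zs) # last block: phylogenetic effects, same incidence
  Cinv <- chol2inv(chol_jitter(C))

  fixed_names <- colnames(X)
  var_names <- c("var_plot", "var_phylo", "var_species", "var_residual")
  loop <- .gibbs_loop(W, y, Cinv, p, np, ns, unname(prior$v), unname(prior$nu),
                      iterations, burn_in, thinning, 1e-8)
  draws <- loop$draws
  colnames(draws) <- c(fixed_names, var_names)
  out <- new_pglmm(draws, prior, iterations, burn_in, thinning, seed,
                   fixed_names)
  out$n_obs <- n
  out
}

new_pglmm <- function(draws, prior, iterations, burn_in, thinning, seed,
                      fixed_names) {
  terms <- tibble(
    term = colnames(draws),
    type = ifelse(colnames(draws) %in% fixed_names, "fixed", "variance")
  )
  structure(list(chains = draws, terms = terms, prior = prior,
                 schedule = c(iterations = iterations, burn_in = burn_in,
                              thinning = thinning),
                 seed = seed),
            class = "cwm_pglmm")
}

#' Fit the phylogenetic mixed model to a community dataset
#'
#' Convenience wrapper: [pglmm_design()] then [pglmm_gibbs()] with the
#' schedule, prior and seed taken from a [run_config()].
#'
#' @param biomass,species,design Community tables.
#' @param tree Rooted `phylo`.
#' @param config A [run_config()].
#' @return A `cwm_pglmm` (see [pglmm_gibbs()]).
#' @export
pglmm_fit <- function(biomass, species, design, tree, config = run_config()) {
  dsg <- pglmm_design(biomass, species, design, tree)
  pglmm_gibbs(dsg, pglmm_prior(config$prior_v, config$prior_nu),
              iterations = config$iterations, burn_in = config$burn_in,
              thinning = config$thinning, seed = config$seed)
}

#' Effective sample size of an MCMC chain
#'
#' `M / (1 + 2 * sum of autocorrelations)`, with the autocorrelation sum
#' truncated by Geyer's initial positive sequence (consecutive lag-pair
#' sums are accumulated while positive). Approximately `M` for
#' independent draws and `M (1 - rho) / (1 + rho)` for an AR(1) chain.
#'
#' @param chain Numeric vector (length >= 10).
#' @return The effective sample size, or `NA` with a warning for a
#'   constant chain.
#' @export
effective_sample_size <- function(chain) {
  M <- length(chain)
  if (M < 10) abort("chain too short (need >= 10 samples)")
  if (sd(chain) == 0) {
    warn("constant chain: ESS undefined")
    return(NA_real_)
  }
  lag_max <- min(M - 1, max(50, floor(10 * sqrt(M))))
  rho <- drop(acf(chain, lag.max = lag_max, plot = FALSE)$acf)
  # Geyer initial positive sequence on pair sums (rho[1] is lag 0)
  tau <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 1
    i2 <- 2 * m + 2
    if (i1 > length(rho)) break
    g <- rho[i1] + if (i2 <= length(rho)) rho[i2] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
    m <- m + 1
  }
  tau <- tau - 1 # lag-0 term counted twice above
  min(M, M / max(tau, 1e-12))
}

#' Two-sided MCMC sign probability (pMCMC)
#'
#' `2 * min(#\{draws > 0\}, #\{draws < 0\}) / M`, floored at `1/M`. When
#' every draw falls on one side the value is reported as below the floor
#' (`label` `"< 1/M"`), mirroring how MCMC tables print `< 0.0001` for a
#' 10,000-sample chain.
#'
#' @param chain Numeric vector of posterior draws.
#' @return A list with `pmcmc` (numeric, floored) and `label` (character).
#' @export
pmcmc <- function(chain) {
  M <- length(chain)
  lo <- min(sum(chain > 0), sum(chain < 0))
  val <- 2 * lo / M
  if (lo == 0) {
    list(pmcmc = 1 / M, label = paste0("< ", format(1 / M, digits = 2)))
  } else {
    list(pmcmc = max(val, 1 / M), label = format(max(val, 1 / M), digits = 4))
  }
}

#' Posterior summary of a fitted phylogenetic mixed model
#'
#' Per parameter: posterior mean, central 95% credible interval
#' (2.5/97.5 percentiles), effective sample size, and pMCMC (fixed
#' effects only; sign probabilities are meaningless for variances).
#'
#' @param object A `cwm_pglmm`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `posterior_mean`,
#'   `ci_lower`, `ci_upper`, `ess`, `pmcmc`, `pmcmc_label`.
#' @export
summary.cwm_pglmm <- function(object, ...) {
  ch <- object$chains
  purrr::map2_dfr(colnames(ch), object$terms$type, function(nm, ty) {
    x <- ch[, nm]
    ci <- unname(quantile(x, c(0.025, 0.975)))
    pm <- if (ty == "fixed") pmcmc(x) else list(pmcmc = NA_real_, label = NA_character_)
    ess <- if (sd(x) == 0) {
      warn(paste0("constant chain for '", nm, "': ESS undefined"))
      NA_real_
    } else {
      effective_sample_size(x)
    }
    tibble(term = nm, type = ty, posterior_mean = mean(x),
           ci_lower = ci[1], ci_upper = ci[2], ess = ess,
           pmcmc = pm$pmcmc, pmcmc_label = pm$label)
  })
}

#' @export
print.cwm_pglmm <- function(x, ...) {
  cat("Phylogenetic mixed model (Gibbs sampler)\n")
  cat(sprintf("  %d retained samples (schedule %d / %d / thin %d), seed %d\n",
              nrow(x$chains), x$schedule[["iterations"]],
              x$schedule[["burn_in"]], x$schedule[["thinning"]], x$seed))
  print(summary(x), n = Inf)
  invisible(x)
}

#' Prior sensitivity scan of the phylogenetic mixed model
#'
#' Refits the model under each prior in `priors` (at whatever schedule is
#' passed, typically a reduced one) and reports, per prior, the fixed
#' effects' posterior means plus the maximum absolute change relative to
#' the first prior.
#'
#' @param dsg A [pglmm_design()].
#' @param priors List of [pglmm_prior()] objects (>= 2).
#' @param iterations,burn_in,thinning Schedule for the scan refits.
#' @param seed Integer seed (shared across refits).
#' @return A list: `means` (tibble term x prior), `max_change` (numeric
#'   vector per prior, first entry 0).
#' @export
sensitivity_scan <- function(dsg, priors, iterations = 6000, burn_in = 1000,
                             thinning = 5, seed = 1L) {
  if (length(priors) < 2) abort("need at least 2 priors")
  fits <- purrr::map(priors, function(pr) {
    pglmm_gibbs(dsg, pr, iterations = iterations, burn_in = burn_in,
                thinning = thinning, seed = seed)
  })
  fx <- purrr::map(fits, function(f) {
    s <- summary(f)
    setNames(s$posterior_mean[s$type == "fixed"], s$term[s$type == "fixed"])
  })
  ref <- fx[[1]]
  max_change <- vapply(fx, function(v) max(abs(v - ref)), numeric(1))
  means <- tibble(term = names(ref))
  for (i in seq_along(fx)) means[[paste0("prior_", i)]] <- unname(fx[[i]])
  list(means = means, max_change = max_change)
}
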