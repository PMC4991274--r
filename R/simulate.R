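#' Canonical fixed-effect terms of the biomass model
#'
#' The community biomass model has 17 fixed-effect terms: intercept, the
#' four focal covariates (log genome size `gs`, nitrogen `n`, phosphorus
#' `p`, `ploidy`), soil `ph`, and every 2-, 3- and 4-way interaction among
#' gs/n/p/ploidy. The order returned here is the canonical row order used
#' by the generator, the design builder and every reported table.
#'
#' @return Character vector of term names.
#' @export
fixed_terms <- function() {
  c("intercept", "gs", "n", "p", "ploidy", "ph",
    "gs:n", "gs:p", "n:p", "gs:ploidy", "n:ploidy", "p:ploidy",
    "gs:n:p", "gs:n:ploidy", "gs:p:ploidy", "n:p:ploidy",
    "gs:n:p:ploidy")
}

# rows: one per observation; gs = log 1C, n/p/ploidy in {0,1}, ph numeric
build_fixed_matrix <- function(gs, n, p, ploidy, ph) {
  X <- cbind(
    intercept = 1, gs = gs, n = n, p = p, ploidy = ploidy, ph = ph,
    "gs:n" = gs * n, "gs:p" = gs * p, "n:p" = n * p,
    "gs:ploidy" = gs * ploidy, "n:ploidy" = n * ploidy,
    "p:ploidy" = p * ploidy,
    "gs:n:p" = gs * n * p, "gs:n:ploidy" = gs * n * ploidy,
    "gs:p:ploidy" = gs * p * ploidy, "n:p:ploidy" = n * p * ploidy,
    "gs:n:p:ploidy" = gs * n * p * ploidy
  )
  stopifnot(identical(colnames(X), fixed_terms()))
  X
}

#' Parameters of the synthetic community generator
#'
#' Defaults describe a 60-species community on a 16-plot, 4-subplots-per-
#' plot factorial nutrient experiment. Fixed-effect defaults are effect
#' sizes of the magnitude estimated from long-term grassland fertilization
#' data (positive P and GS:N:P effects, a strong positive GS:P:ploidy
#' interaction, negative P:ploidy and GS:P two-way terms); variance
#' components default to a unit-scale baseline for log-biomass data.
#'
#' @param n_species Number of species (tree tips).
#' @param birth_rate Per-lineage speciation rate of the pure-birth tree.
#' @param sigma2_bm Brownian rate of log 1C evolution (per unit branch
#'   length).
#' @param lambda_true Pagel lambda of the simulated trait, in `[0, 1]`.
#' @param root_log1c Root state of log 1C (log pg).
#' @param p_polyploid Probability a species is polyploid.
#' @param polyploid_gs_multiplier Multiplier (>= 1) applied to polyploid
#'   1C-values, inducing the genome-size/ploidy association.
#' @param csr_concentration Length-3 Dirichlet concentration for the
#'   C:S:R strategy triple.
#' @param n_plots,subplots_per_plot Experimental layout.
#' @param beta Named vector of fixed effects over [fixed_terms()]; missing
#'   names default to 0.
#' @param sigma2_plot,sigma2_species,sigma2_phylo,sigma2_resid Variance
#'   components of the log-biomass model.
#' @param occupancy Probability a species occurs on a subplot.
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_species = 60, birth_rate = 1,
                       sigma2_bm = 0.5, lambda_true = 1, root_log1c = 1,
                       p_polyploid = 0.4, polyploid_gs_multiplier = 2,
                       csr_concentration = c(2, 2, 2),
                       n_plots = 16, subplots_per_plot = 4,
                       beta = c(intercept = -4.573, gs = 0.186, n = -0.034,
                                p = 0.907, ploidy = 0.452, ph = 0.256,
                                "gs:n" = 0.04, "gs:p" = -0.536, "n:p" = -0.605,
                                "gs:ploidy" = 0.053, "n:ploidy" = -0.722,
                                "p:ploidy" = -1.411, "gs:n:p" = 0.71,
                                "gs:n:ploidy" = 0.503, "gs:p:ploidy" = 1.225,
                                "n:p:ploidy" = -0.872, "gs:n:p:ploidy" = 0.043),
                       sigma2_plot = 0.25, sigma2_species = 0.5,
                       sigma2_phylo = 0.25, sigma2_resid = 1,
                       occupancy = 0.5, seed = 1L) {
  full_beta <- setNames(numeric(length(fixed_terms())), fixed_terms())
  if (length(beta)) {
    unknown <- setdiff(names(beta), fixed_terms())
    if (length(unknown)) abort(paste0("unknown beta terms: ", paste(unknown, collapse = ", ")))
    full_beta[names(beta)] <- beta
  }
  vars <- c(sigma2_plot, sigma2_species, sigma2_phylo, sigma2_resid)
  if (any(!is.finite(vars)) || any(vars < 0)) abort("variance components must be finite and >= 0")
  probs <- c(p_polyploid, occupancy)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (lambda_true < 0 || lambda_true > 1) abort("lambda_true must lie in [0, 1]")
  if (polyploid_gs_multiplier < 1) abort("polyploid_gs_multiplier must be >= 1")
  structure(
    list(n_species = n_species, birth_rate = birth_rate,
         sigma2_bm = sigma2_bm, lambda_true = lambda_true,
         root_log1c = root_log1c, p_polyploid = p_polyploid,
         polyploid_gs_multiplier = polyploid_gs_multiplier,
         csr_concentration = csr_concentration,
         n_plots = n_plots, subplots_per_plot = subplots_per_plot,
         beta = full_beta,
         sigma2_plot = sigma2_plot, sigma2_species = sigma2_species,
         sigma2_phylo = sigma2_phylo, sigma2_resid = sigma2_resid,
         occupancy = occupancy, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Wraps [ape::rphylo()] (birth-death process conditioned on the number of
#' tips, death rate 0), which yields an ultrametric tree. Tips are labelled
#' `sp001`, `sp002`, ...
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed; same seed, same tree.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (n_species < 2) abort("n_species must be at least 2")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate genome sizes along a tree
#'
#' Log 1C-values are drawn from a multivariate normal with mean
#' `root_log1c` and covariance `sigma2_bm * C(lambda)`, where `C` is the
#' shared-branch-length matrix of the tree and `C(lambda)` multiplies its
#' off-diagonal entries by `lambda_true`. `lambda_true = 1` is Brownian
#' motion; `lambda_true = 0` makes tip values independent.
#'
#' @param tree A `phylo` with branch lengths.
#' @param sigma2_bm Brownian rate (> 0).
#' @param lambda_true Signal parameter in `[0, 1]`.
#' @param root_log1c Root state on the log scale.
#' @param seed Integer seed.
#' @return Named numeric vector of 1C-values (pg) over the tips.
#' @export
simulate_gs <- function(tree, sigma2_bm, lambda_true = 1, root_log1c = 1,
                        seed = 1L) {
  if (lambda_true < 0 || lambda_true > 1) abort("lambda_true must lie in [0, 1]")
  if (sigma2_bm <= 0) abort("sigma2_bm must be positive")
  C <- phylo_covariance(tree)
  Cl <- lambda_transform(C, lambda_true)
  set.seed(seed)
  z <- rnorm(nrow(Cl))
  U <- chol(sigma2_bm * Cl + diag(1e-12, nrow(Cl)))
  log1c <- root_log1c + drop(crossprod(U, z))
  setNames(exp(log1c), rownames(C))
}

#' Assign ploidy classes and C-S-R strategies
#'
#' Each species is flagged polyploid with probability `p_polyploid`;
#' polyploid 1C-values are multiplied by `multiplier`, which creates the
#' genome-size/ploidy association seen in real communities. C:S:R triples
#' are drawn from a Dirichlet distribution so they are non-negative and sum
#' to one by construction.
#'
#' @param gs_map Named vector of 1C-values (pg), as from [simulate_gs()].
#' @param p_polyploid Polyploidy probability.
#' @param multiplier Genome-size multiplier (>= 1) for polyploids.
#' @param csr_concentration Length-3 Dirichlet concentration.
#' @param seed Integer seed.
#' @return A species tibble (see [read_species_table()]).
#' @export
assign_ploidy_csr <- function(gs_map, p_polyploid = 0.4, multiplier = 2,
                              csr_concentration = c(2, 2, 2), seed = 1L) {
  if (p_polyploid < 0 || p_polyploid > 1) abort("p_polyploid must lie in [0, 1]")
  if (multiplier < 1) abort("multiplier must be >= 1")
  n <- length(gs_map)
  set.seed(seed)
  poly <- rbinom(n, 1, p_polyploid) == 1
  g <- matrix(rgamma(3 * n, shape = rep(csr_concentration, each = n)), ncol = 3)
  tri <- g / rowSums(g)
  tibble(
    species_id = names(gs_map),
    one_c_pg = unname(gs_map) * ifelse(poly, multiplier, 1),
    ploidy_class = ifelse(poly, "polyploid", "diploid"),
    csr_c = tri[, 1], csr_s = tri[, 2], csr_r = tri[, 3]
  )
}

#' Simulate a factorial nutrient design
#'
#' Subplots are assigned to the four treatment cells (control, N, P, N+P)
#' in a balanced rotation: with four subplots per plot every plot carries
#' each cell once. Nitrogen cells receive either nitrate (48 or 96 kg N
#' ha^-1 yr^-1) or ammonium (48, 96 or 144); phosphorus cells get
#' `p_applied = TRUE`. Potassium/sodium/magnesium/silica applications are
#' independent Bernoulli draws, and soil pH is uniform on `[4.5, 7.0]`
#' (the inclusion range of limed grassland subplots).
#'
#' @param n_plots Number of plots (>= 4 for a full factorial).
#' @param subplots_per_plot Subplots per plot.
#' @param seed Integer seed.
#' @return A design tibble (see [read_design_table()]).
#' @export
simulate_design <- function(n_plots, subplots_per_plot = 1, seed = 1L) {
  if (n_plots < 4) abort("n_plots must be >= 4 for a full factorial")
  set.seed(seed)
  total <- n_plots * subplots_per_plot
  cells <- c("control", "N", "P", "N+P")[(seq_len(total) - 1) %% 4 + 1]
  plot_id <- rep(sprintf("plot%02d", seq_len(n_plots)), each = subplots_per_plot)
  sub_letter <- rep(letters[seq_len(subplots_per_plot)], times = n_plots)
  n_on <- cells %in% c("N", "N+P")
  use_ammonium <- rbinom(total, 1, 0.5) == 1
  dose_nitrate <- ifelse(n_on & !use_ammonium, sample(c(48, 96), total, replace = TRUE), 0)
  dose_ammonium <- ifelse(n_on & use_ammonium, sample(c(48, 96, 144), total, replace = TRUE), 0)
  tibble(
    plot_id = plot_id,
    subplot_id = paste0(plot_id, sub_letter),
    dose_nitrate = dose_nitrate,
    dose_ammonium = dose_ammonium,
    p_applied = cells %in% c("P", "N+P"),
    k_applied = rbinom(total, 1, 0.4) == 1,
    na_applied = rbinom(total, 1, 0.15) == 1,
    mg_applied = rbinom(total, 1, 0.15) == 1,
    si_applied = rbinom(total, 1, 0.05) == 1,
    ph = runif(total, 4.5, 7.0)
  )
}

#' Simulate species-by-subplot biomass
#'
#' For each occupied (species, subplot) pair, log biomass is the sum of
#' the 17-term fixed predictor (genome size entering as log 1C, N/P/ploidy
#' as 0-1 indicators, pH centred at 5.75), a plot random effect, a species
#' random effect, a phylogenetic species effect drawn once per species
#' from MVN(0, `sigma2_phylo * C`) with `C` scaled to unit maximum
#' diagonal, and a residual. Biomass is the exponential; unoccupied pairs
#' are recorded with 0 g.
#'
#' @param species Species tibble.
#' @param design Design tibble.
#' @param tree `phylo` covering the species.
#' @param params A [sim_params()] object (beta, variances, occupancy and
#'   seed are taken from it).
#' @return Long biomass tibble (`species_id`, `subplot_id`, `biomass_g`),
#'   with the per-pair true expected log-biomass attached as attribute
#'   `"linpred"` for recovery tests.
#' @export
simulate_biomass <- function(species, design, tree, params) {
  for (v in c("sigma2_plot", "sigma2_species", "sigma2_phylo", "sigma2_resid")) {
    if (is.null(params[[v]]) || !is.finite(params[[v]])) {
      abort(paste0("missing variance component: ", v))
    }
  }
  set.seed(params$seed + 4L)
  C <- phylo_covariance(tree)[species$species_id, species$species_id]
  C <- C / max(diag(C))
  ns <- nrow(species); nd <- nrow(design)

  u_plot <- setNames(rnorm(length(unique(design$plot_id)), 0, sqrt(params$sigma2_plot)),
                     unique(design$plot_id))
  u_sp <- setNames(rnorm(ns, 0, sqrt(params$sigma2_species)), species$species_id)
  u_phy <- if (params$sigma2_phylo > 0) {
    U <- chol(params$sigma2_phylo * C + diag(1e-12, ns))
    drop(crossprod(U, rnorm(ns)))
  } else {
    numeric(ns)
  }
  u_phy <- setNames(u_phy, species$species_id)

  grid <- tidyr::expand_grid(species_id = species$species_id,
                             subplot_id = design$subplot_id)
  grid <- grid |>
    left_join(species, by = "species_id") |>
    left_join(classify_treatment(design), by = "subplot_id")
  X <- build_fixed_matrix(
    gs = log(grid$one_c_pg),
    n = as.numeric(grid$n_on), p = as.numeric(grid$p_on),
    ploidy = as.numeric(grid$ploidy_class == "polyploid"),
    ph = grid$ph - 5.75
  )
  linpred <- drop(X %*% params$beta) +
    u_plot[grid$plot_id] + u_sp[grid$species_id] + u_phy[grid$species_id]
  occupied <- rbinom(nrow(grid), 1, params$occupancy) == 1
  logb <- linpred + rnorm(nrow(grid), 0, sqrt(params$sigma2_resid))
  out <- tibble(
    species_id = grid$species_id,
    subplot_id = grid$subplot_id,
    biomass_g = ifelse(occupied, exp(logb), 0)
  )
  attr(out, "linpred") <- unname(linpred)
  out
}

#' Generate a complete synthetic community dataset
#'
#' Runs the four generator stages (tree, genome sizes, ploidy/C-S-R,
#' design, biomass) under sub-seeds derived from `params$seed`, so the
#' whole dataset is a deterministic function of the parameter object.
#'
#' @param params A [sim_params()] object.
#' @return A list with `tree`, `species`, `design`, `biomass` and the
#'   `params` used.
#' @export
simulate_community <- function(params = sim_params()) {
  tree <- simulate_tree(params$n_species, params$birth_rate, seed = params$seed)
  gs <- simulate_gs(tree, params$sigma2_bm, params$lambda_true,
                    params$root_log1c, seed = params$seed + 1L)
  species <- assign_ploidy_csr(gs, params$p_polyploid,
                               params$polyploid_gs_multiplier,
                               params$csr_concentration,
                               seed = params$seed + 2L)
  design <- simulate_design(params$n_plots, params$subplots_per_plot,
                            seed = params$seed + 3L)
  biomass <- simulate_biomass(species, design, tree, params)
  list(tree = tree, species = species, design = design, biomass = biomass,
       params = params)
}

#' Write a synthetic dataset to disk in the standard input formats
#'
#' Emits the Newick tree and the three CSV tables, plus a YAML file of the
#' true generator parameters for parameter-recovery work.
#'
#' @param community As returned by [simulate_community()].
#' @param dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_community_set <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_community(community$species, community$design,
                           community$biomass, dir)
  tre <- file.path(dir, "tree.nwk")
  write_newick(community$tree, tre)
  prm <- file.path(dir, "params.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    pl <- unclass(community$params)
    pl$beta <- as.list(pl$beta)
    yaml::write_yaml(pl, prm)
  }
  invisible(c(paths, tree = tre, params = prm))
}
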