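#' Generalized least squares with a fixed covariance matrix
#'
#' Closed-form GLS: \eqn{\hat\beta = (X^T V^{-1} X)^{-1} X^T V^{-1} y},
#' \eqn{\hat\sigma^2 = r^T V^{-1} r / (n - p)} with standard errors from
#' \eqn{\hat\sigma^2 (X^T V^{-1} X)^{-1}}. With `V` a phylogenetic
#' covariance this is PGLS under Brownian motion; with `V = I` it reduces
#' exactly to ordinary least squares.
#'
#' @param X Design matrix (n x p), full rank.
#' @param y Response vector.
#' @param V Positive-definite covariance matrix (n x n), e.g. from
#'   [phylo_covariance()].
#' @return A list of class `cwm_gls`: `coefficients` tibble (term,
#'   estimate, se), `sigma2`, `loglik` (ML, Gaussian), `loglik_reml`,
#'   `fitted`, `residuals`, `df_residual`.
#' @export
gls_fit <- function(X, y, V) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n) abort("dimension mismatch")
  if (qr(X)$rank < p) abort("X is rank deficient")
  U <- chol_jitter(V)
  # whiten: solve(t(U)) %*% . ; GLS becomes OLS on the whitened problem
  Xw <- forwardsolve(t(U), X)
  yw <- forwardsolve(t(U), y)
  xtx <- crossprod(Xw)
  beta <- drop(solve(xtx, crossprod(Xw, yw)))
  r <- drop(y - X %*% beta)
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(solve(xtx)) * sigma2)
  logdet <- 2 * sum(log(diag(U)))
  sig2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sig2_ml) + logdet + n)
  loglik_reml <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet +
                           determinant(xtx, logarithm = TRUE)$modulus + (n - p))
  structure(
    list(coefficients = tibble(term = colnames(X), estimate = beta, se = se),
         sigma2 = sigma2, loglik = loglik,
         loglik_reml = as.numeric(loglik_reml),
         fitted = drop(X %*% beta), residuals = r, df_residual = n - p),
    class = "cwm_gls"
  )
}

#' Phylogenetically corrected group means of a tip trait
#'
#' GLS of the trait on group indicator columns with the Brownian
#' phylogenetic covariance as `V`: the returned means discount the
#' pseudo-replication of closely related species sharing a group. On a
#' star phylogeny they reduce to the arithmetic group means; with a
#' single group the mean equals the phylogenetic mean used by
#' [blomberg_k()].
#'
#' @param trait Named numeric vector over the tips.
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @param group Factor or character vector (one entry per tip, aligned
#'   with `trait`) partitioning the tips; may be `NULL` for a single
#'   overall mean.
#' @return A list of class `cwm_pgls_means`: `means` tibble (group,
#'   estimate, se) and the underlying `cwm_gls` fit.
#' @export
pgls_species_mean <- function(trait, C, group = NULL) {
  trait <- align_trait_keep_names(trait, C)
  n <- length(trait)
  if (is.null(group)) group <- rep("all", n)
  if (!is.factor(group)) group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) == 0) abort("empty group")
  X <- vapply(levels(group), function(l) as.numeric(group == l),
              numeric(n))
  colnames(X) <- levels(group)
  fit <- gls_fit(X, trait, C)
  structure(list(means = fit$coefficients |> rename(group = "term"),
                 fit = fit),
            class = "cwm_pgls_means")
}

align_trait_keep_names <- function(trait, C) {
  x <- align_trait(trait, C)
  names(x) <- rownames(C)
  x
}

#' PGLS biomass-weighted mean genome size per treatment
#'
#' A phylogenetically corrected analogue of the community-weighted mean:
#' for each treatment cell, species log 1C-values are regressed (GLS,
#' Brownian covariance) on an intercept with weights proportional to the
#' species' summed biomass on that treatment's subplots, i.e. a
#' phylogenetic weighted mean \eqn{(1^T C^{-1} W 1)^{-1} 1^T C^{-1} W y}
#' computed per treatment. This construction — biomass enters as species
#' weights, phylogeny as the residual covariance — is one documented
#' interpretation of "phylogenetic biomass-weighted means"; the primary
#' community metric remains [cwm_table()].
#'
#' @param biomass,species,design The community tables.
#' @param tree Rooted `phylo` covering the species.
#' @return A tibble with one row per treatment: `treatment`,
#'   `pgls_mean_1c_pg` (back-transformed from the log scale), `se_log`.
#' @export
pgls_cwm <- function(biomass, species, design, tree) {
  C <- phylo_covariance(tree)
  design <- classify_treatment(design)
  sp <- species[match(rownames(C), species$species_id), ]
  if (anyNA(sp$species_id)) {
    keep <- intersect(rownames(C), species$species_id)
    C <- C[keep, keep]
    sp <- species[match(keep, species$species_id), ]
  }
  y <- log(sp$one_c_pg)
  per_treat <- biomass |>
    left_join(select(design, "subplot_id", "treatment"), by = "subplot_id") |>
    group_by(.data$treatment, .data$species_id) |>
    summarise(w = sum(.data$biomass_g), .groups = "drop")
  purrr::map_dfr(levels(design$treatment), function(tr) {
    w <- per_treat |> filter(.data$treatment == tr)
    wv <- setNames(numeric(nrow(sp)), sp$species_id)
    wv[w$species_id[w$species_id %in% names(wv)]] <-
      w$w[w$species_id %in% names(wv)]
    pres <- wv > 0
    if (sum(pres) < 2) {
      return(tibble(treatment = tr, pgls_mean_1c_pg = NA_real_,
                    se_log = NA_real_))
    }
    # weighted phylogenetic mean: V = C scaled by inverse weights
    Vw <- C[pres, pres] * tcrossprod(1 / sqrt(wv[pres] / mean(wv[pres])))
    fit <- gls_fit(matrix(1, sum(pres), 1, dimnames = list(NULL, "mean")),
                   y[pres], Vw)
    tibble(treatment = tr,
           pgls_mean_1c_pg = exp(fit$coefficients$estimate),
           se_log = fit$coefficients$se)
  })
}
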