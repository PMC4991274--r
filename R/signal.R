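#' Phylogenetic covariance matrix of a rooted tree
#'
#' `C[i, j]` is the summed branch length from the root to the most recent
#' common ancestor of tips i and j; `C[i, i]` is the root-to-tip distance.
#' Under Brownian motion the tip values are multivariate normal with
#' covariance proportional to this matrix.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric positive-semidefinite matrix with tip-name dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  ape::vcv.phylo(tree)
}

# Pagel transform: multiply off-diagonal entries by lambda
lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Cholesky with one jitter retry; returns the upper factor.
chol_jitter <- function(M, jitter = 1e-8) {
  U <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(U)) {
    U <- tryCatch(chol(M + diag(jitter * mean(diag(M)), nrow(M))),
                  error = function(e) NULL)
    if (is.null(U)) abort("covariance matrix is singular even after jitter")
    warn("covariance matrix singular; diagonal jitter applied")
  }
  U
}

# phylogenetic GLS mean and the two mean squared errors behind K
k_components <- function(trait, C) {
  n <- length(trait)
  U <- chol_jitter(C)
  Cinv_y <- backsolve(U, forwardsolve(t(U), trait))
  Cinv_1 <- backsolve(U, forwardsolve(t(U), rep(1, n)))
  a_hat <- sum(Cinv_y) / sum(Cinv_1)
  r <- trait - a_hat
  mse0 <- sum(r^2) / (n - 1)
  Cinv_r <- backsolve(U, forwardsolve(t(U), r))
  mse <- sum(r * Cinv_r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv_1)) / (n - 1)
  list(a_hat = a_hat, mse0 = mse0, mse = mse, expected = expected)
}

#' Blomberg's K phylogenetic signal statistic
#'
#' The ratio of the observed mean squared trait error (from the
#' phylogenetically corrected mean) to the phylogenetically expected mean
#' squared error, scaled by its Brownian-motion expectation:
#' \deqn{K = \frac{MSE_0 / MSE}{\big(\mathrm{tr}(C) - n / (1^T C^{-1} 1)\big)/(n-1)}}
#' with the phylogenetic mean \eqn{\hat a = 1^T C^{-1} y / 1^T C^{-1} 1},
#' \eqn{MSE_0 = (y-\hat a)^T (y-\hat a)/(n-1)} and
#' \eqn{MSE = (y-\hat a)^T C^{-1} (y-\hat a)/(n-1)}. K = 1 under Brownian
#' motion (and exactly 1 on a star phylogeny); larger values mean
#' stronger-than-Brownian clustering of trait values on the tree.
#'
#' @param trait Named numeric vector over the tips (n >= 4).
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @return The K statistic (scalar), or `NA` with a warning for a
#'   constant trait.
#' @export
blomberg_k <- function(trait, C) {
  trait <- align_trait(trait, C)
  if (length(trait) < 4) abort("need at least 4 tips")
  if (sd(trait) == 0) {
    warn("constant trait: K undefined")
    return(NA_real_)
  }
  kc <- k_components(trait, C)
  (kc$mse0 / kc$mse) / kc$expected
}

align_trait <- function(trait, C) {
  if (!is.null(names(trait))) {
    miss <- setdiff(rownames(C), names(trait))
    if (length(miss)) abort(paste0("trait missing for tips: ",
                                   paste(head(miss, 5), collapse = ", ")))
    trait <- trait[rownames(C)]
  } else if (length(trait) != nrow(C)) {
    abort("trait length does not match the covariance dimension")
  }
  as.numeric(trait)
}

#' Permutation test for Blomberg's K
#'
#' Trait values are shuffled across tips; signal shows up as a small
#' observed phylogenetic mean squared error relative to the permutation
#' distribution. The p-value uses the add-one correction:
#' `(1 + #\{MSE_perm <= MSE_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return One-row tibble `k_stat`, `k_pvalue`, `n_perm`.
#' @export
blomberg_k_test <- function(trait, C, n_perm = 999, seed = 1L) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  trait <- align_trait(trait, C)
  if (sd(trait) == 0) {
    warn("constant trait: K undefined")
    return(tibble(k_stat = NA_real_, k_pvalue = NA_real_, n_perm = n_perm))
  }
  kc <- k_components(trait, C)
  k_obs <- (kc$mse0 / kc$mse) / kc$expected
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    mse_p <- k_components(sample(trait), C)$mse
    if (mse_p <= kc$mse) hits <- hits + 1L
  }
  tibble(k_stat = k_obs, k_pvalue = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Pagel's lambda by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood of the trait under
#' covariance `sigma2 * C(lambda)`, where `C(lambda)` scales the
#' off-diagonal entries of the phylogenetic covariance by `lambda`.
#' `sigma2` and the phylogenetic mean are profiled out analytically, so
#' the optimization is one-dimensional over
#' `lambda in [0, lambda_max]`, with `lambda_max` the largest value
#' keeping `C(lambda)` positive definite (bounded by pairwise
#' `min(C_ii, C_jj) / C_ij` ratios and capped at 1.2, so estimates
#' slightly above 1 are attainable). A likelihood-ratio test against
#' `lambda = 0` (no signal) is included.
#'
#' @inheritParams blomberg_k
#' @return One-row tibble `lambda_hat`, `lambda_loglik`,
#'   `lambda_lr_pvalue`, `loglik_lambda0`.
#' @export
pagel_lambda_ml <- function(trait, C) {
  trait <- align_trait(trait, C)
  if (length(trait) < 4) abort("need at least 4 tips")
  if (sd(trait) == 0) {
    warn("constant trait: lambda undefined")
    return(tibble(lambda_hat = NA_real_, lambda_loglik = NA_real_,
                  lambda_lr_pvalue = NA_real_, loglik_lambda0 = NA_real_))
  }
  n <- length(trait)
  off <- C[upper.tri(C)]
  dd <- outer(diag(C), diag(C), pmin)[upper.tri(C)]
  pos <- off > 0
  lambda_max <- if (any(pos)) min(1.2, min(dd[pos] / off[pos])) else 1.2

  loglik <- function(lambda) {
    U <- chol_jitter(lambda_transform(C, lambda))
    logdet <- 2 * sum(log(diag(U)))
    Cinv_y <- backsolve(U, forwardsolve(t(U), trait))
    Cinv_1 <- backsolve(U, forwardsolve(t(U), rep(1, n)))
    a_hat <- sum(Cinv_y) / sum(Cinv_1)
    r <- trait - a_hat
    q <- sum(r * backsolve(U, forwardsolve(t(U), r)))
    sigma2 <- q / n
    -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  }
  opt <- optimize(loglik, c(0, lambda_max), maximum = TRUE, tol = 1e-8)
  # the optimum can sit on a boundary; compare against both ends
  cand <- c(opt$maximum, 0, lambda_max)
  # the PSD cap is a pairwise bound; at the cap itself chol may need the
  # jitter fallback, which is routine here rather than noteworthy
  ll <- c(opt$objective, loglik(0), suppressWarnings(loglik(lambda_max)))
  best <- which.max(ll)
  ll0 <- ll[2]
  lr <- max(0, 2 * (ll[best] - ll0))
  tibble(lambda_hat = cand[best], lambda_loglik = ll[best],
         lambda_lr_pvalue = pchisq(lr, 1, lower.tail = FALSE),
         loglik_lambda0 = ll0)
}

#' Phylogenetic signal of a tip trait
#'
#' Combines Blomberg's K (with its permutation test) and Pagel's lambda
#' (maximum likelihood, with a likelihood-ratio test against no signal)
#' for one trait on one tree. Genome sizes are log-transformed by default
#' (`scale = "log"`), the scale on which 1C-values are modelled.
#'
#' @param tree A rooted `phylo`.
#' @param trait Named numeric vector over the tips (e.g. 1C-values in pg).
#' @param scale `"log"` (default) or `"raw"` transformation applied to the
#'   trait before testing.
#' @param n_perm Permutations for the K test.
#' @param seed Integer seed for the permutation test.
#' @return One-row tibble: `k_stat`, `k_pvalue`, `lambda_hat`,
#'   `lambda_loglik`, `lambda_lr_pvalue`, `scale`.
#' @export
phylo_signal <- function(tree, trait, scale = c("log", "raw"),
                         n_perm = 999, seed = 1L) {
  scale <- match.arg(scale)
  C <- phylo_covariance(tree)
  x <- align_trait(trait, C)
  if (scale == "log") {
    if (any(x <= 0)) abort("log scale requires strictly positive trait values")
    x <- log(x)
  }
  names(x) <- rownames(C)
  kt <- blomberg_k_test(x, C, n_perm = n_perm, seed = seed)
  lt <- pagel_lambda_ml(x, C)
  bind_cols(kt[, c("k_stat", "k_pvalue")], lt[, c("lambda_hat", "lambda_loglik",
                                                  "lambda_lr_pvalue")]) |>
    mutate(scale = scale, n_perm = n_perm)
}
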