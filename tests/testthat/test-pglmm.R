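# one small fitted model shared across blocks in this file
fixture_fit <- local({
  com <- small_community(seed = 61L, beta = c(p = 0.9, intercept = 0.5))
  dsg <- pglmm_design(com$biomass, com$species, com$design, com$tree)
  list(com = com, dsg = dsg,
       fit = pglmm_gibbs(dsg, pglmm_prior(1, 0.5),
                         iterations = 8000, burn_in = 2000, thinning = 3,
                         seed = 62L))
})

test_that("the model design matches its declared shape", {
  sp1 <- toy_species()[1, ]
  de1 <- toy_design()[1, ]
  tr <- ape::read.tree(text = "(sp1:1,spX:1):0;")
  bm1 <- tibble::tibble(species_id = "sp1", subplot_id = "p1a", biomass_g = 1)
  dsg <- pglmm_design(bm1, sp1, de1, tr)
  expect_equal(dim(dsg$X), c(1, 17))
  expect_equal(dsg$y, 0) # ln(1 g)
  expect_identical(colnames(dsg$X), fixed_terms())

  # zero-biomass rows are excluded, with the count reported
  com <- fixture_fit$com
  dsg2 <- fixture_fit$dsg
  expect_equal(dsg2$n_dropped, sum(com$biomass$biomass_g == 0))
  expect_equal(length(dsg2$y), sum(com$biomass$biomass_g > 0))
  expect_equal(max(diag(dsg2$C)), 1)
})

test_that("chains are deterministic under the seed", {
  dsg <- fixture_fit$dsg
  f1 <- pglmm_gibbs(dsg, pglmm_prior(1, 0.5), 2000, 500, 2, seed = 9L)
  f2 <- pglmm_gibbs(dsg, pglmm_prior(1, 0.5), 2000, 500, 2, seed = 9L)
  expect_identical(f1$chains, f2$chains)
  f3 <- pglmm_gibbs(dsg, pglmm_prior(1, 0.5), 2000, 500, 2, seed = 10L)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("with no data the variance posterior is the prior", {
  f <- pglmm_gibbs(list(y = numeric(0)), pglmm_prior(1, 0.5),
                   iterations = 3000, burn_in = 1000, thinning = 1, seed = 3L)
  draws <- f$chains[, "var_residual"]
  # 1/sigma2 ~ Gamma(nu/2, rate = nu*V/2)
  ks <- stats::ks.test(1 / draws, stats::pgamma, shape = 0.25, rate = 0.25)
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate variance priors drive fixed effects to the OLS solution", {
  dsg <- fixture_fit$dsg
  # pin the three random-effect variances near zero, leave the residual free
  pinned <- pglmm_prior(v = c(1e-10, 1e-10, 1e-10, 1),
                        nu = c(1e10, 1e10, 1e10, 0.002))
  f <- pglmm_gibbs(dsg, pinned, 20000, 4000, 4, seed = 5L)
  s <- summary(f)
  post <- s$posterior_mean[match(fixed_terms(), s$term)]
  ols <- qr.coef(qr(dsg$X), dsg$y)
  expect_equal(unname(post), unname(ols), tolerance = 0.02)
})

test_that("posterior summaries recover generator effects on the fixture", {
  s <- summary(fixture_fit$fit)
  p_row <- s[s$term == "p", ]
  expect_gt(p_row$posterior_mean, 0.4)
  expect_lt(p_row$posterior_mean, 1.4)
  expect_true(p_row$ci_lower <= p_row$posterior_mean &
                p_row$posterior_mean <= p_row$ci_upper)
  expect_true(all(s$ess <= nrow(fixture_fit$fit$chains) + 1e-9, na.rm = TRUE))
  expect_true(all(s$posterior_mean[s$type == "variance"] > 0))
})

test_that("split-chain means agree on the fixture (stationarity)", {
  ch <- fixture_fit$fit$chains
  for (term in c("p", "gs", "var_residual")) {
    x <- ch[, term]
    h <- length(x) %/% 2
    expect_lt(abs(mean(x[1:h]) - mean(x[(h + 1):(2 * h)])), 0.1 * sd(x))
  }
})

test_that("credible intervals cover generator effects at near-nominal rate", {
  terms <- c("gs", "n", "p", "ploidy", "ph")
  hits <- 0L; total <- 0L
  for (i in 1:25) {
    com <- small_community(seed = 700L + i)
    dsg <- pglmm_design(com$biomass, com$species, com$design, com$tree)
    f <- pglmm_gibbs(dsg, pglmm_prior(1, 0.5), 3000, 1000, 2, seed = 800L + i)
    s <- summary(f)
    truth <- com$params$beta[terms]
    rows <- s[match(terms, s$term), ]
    hits <- hits + sum(rows$ci_lower <= truth & truth <= rows$ci_upper)
    total <- total + length(terms)
  }
  expect_gte(hits / total, 0.85)
})

test_that("effective sample size behaves like its closed forms", {
  set.seed(15)
  iid <- rnorm(5000)
  expect_gt(effective_sample_size(iid), 4200)
  expect_lte(effective_sample_size(iid), 5000)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.5), 10000))
  expect_equal(effective_sample_size(ar), 10000 / 3, tolerance = 0.25)
  expect_warning(e <- effective_sample_size(rep(1, 100)), "constant")
  expect_true(is.na(e))
  expect_error(effective_sample_size(1:5), "short")
})

test_that("ESS roughly agrees with an independent implementation", {
  skip_if_not_installed("coda")
  set.seed(16)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.7), 8000))
  expect_equal(effective_sample_size(ar),
               unname(coda::effectiveSize(ar)), tolerance = 0.25)
})

test_that("pMCMC uses the two-sided sign probability with a floor", {
  set.seed(17)
  z <- rnorm(10000)
  pm <- pmcmc(z)
  expect_equal(pm$pmcmc, 1, tolerance = 0.05)
  allpos <- abs(z) + 0.001
  pm2 <- pmcmc(allpos)
  expect_equal(pm2$pmcmc, 1e-4)
  expect_match(pm2$label, "^< ")
  # central 95% interval of a standard normal chain
  s_ci <- unname(stats::quantile(z, c(0.025, 0.975)))
  expect_equal(s_ci, c(-1.96, 1.96), tolerance = 0.1)
})

test_that("constant chains collapse their summaries with a flag", {
  f <- fixture_fit$fit
  f$chains[, "gs"] <- 2.5
  expect_warning(s <- summary(f), "constant|ESS")
  row <- s[s$term == "gs", ]
  expect_equal(row$ci_lower, 2.5)
  expect_equal(row$ci_upper, 2.5)
  expect_true(is.na(row$ess))
})

test_that("the prior sensitivity scan is null for identical priors and small
           for reasonable ones", {
  dsg <- fixture_fit$dsg
  same <- sensitivity_scan(dsg, list(pglmm_prior(1, 0.5), pglmm_prior(1, 0.5)),
                           iterations = 1500, burn_in = 500, thinning = 2,
                           seed = 21L)
  expect_equal(same$max_change[2], 0)
  varied <- sensitivity_scan(dsg, list(pglmm_prior(1, 0.002), pglmm_prior(1, 0.5),
                                       pglmm_prior(1, 2)),
                             iterations = 4000, burn_in = 1000, thinning = 2,
                             seed = 22L)
  expect_lt(max(varied$max_change), 0.05)
  expect_error(sensitivity_scan(dsg, list(pglmm_prior(1, 0.5))), "2 priors")
})

test_that("improper flat priors are accepted with a warning", {
  expect_warning(pr <- pglmm_prior(1, 0), "improper")
  expect_true(all(pr$nu == 0))
})
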