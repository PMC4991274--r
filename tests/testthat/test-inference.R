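test_that("two-way ANOVA matches the balanced closed-form decomposition", {
  d <- classify_treatment(factorial_design(4))
  cell_mean <- ifelse(d$n_on & d$p_on, 1, 0)
  noise <- rep(c(-0.15, -0.05, 0.05, 0.15), 4)
  d$cwm_1c_pg <- cell_mean + noise

  # balanced 2x2 hand formulas: SS_A = sum_i n_i (mean_i - grand)^2 etc.
  y <- d$cwm_1c_pg
  grand <- mean(y)
  ss_n <- sum(tapply(y, d$n_on, function(v) length(v) * (mean(v) - grand)^2))
  ss_p <- sum(tapply(y, d$p_on, function(v) length(v) * (mean(v) - grand)^2))
  cellm <- tapply(y, interaction(d$n_on, d$p_on), mean)
  rowm <- tapply(y, d$n_on, mean); colm <- tapply(y, d$p_on, mean)
  ss_int <- 4 * sum((cellm - rep(rowm, 2) - rep(colm, each = 2) + grand)^2)
  ss_res <- sum(noise^2)

  out <- two_way_anova(d)
  expect_equal(out$anova$ss, c(ss_n, ss_p, ss_int), tolerance = 1e-10)
  expect_equal(out$anova$df_den, rep(12, 3))
  expect_equal(out$anova$F, c(ss_n, ss_p, ss_int) / (ss_res / 12),
               tolerance = 1e-10)
  # contrasts are against the control cell
  expect_true(all(c("N", "P", "N+P") %in% out$contrasts$cell))
})

test_that("constant responses give zero F, and empty cells error", {
  d <- classify_treatment(factorial_design(2))
  d$cwm_1c_pg <- 3
  out <- two_way_anova(d)
  expect_equal(out$anova$F, rep(0, 3))
  d2 <- d[d$treatment != "N+P", ]
  expect_error(two_way_anova(d2), "empty factorial cell")
})

test_that("sequential SS sum to the model SS and F is affine-invariant", {
  set.seed(8)
  for (rep in 1:10) {
    d <- classify_treatment(factorial_design(sample(3:6, 1)))
    d$cwm_1c_pg <- rnorm(nrow(d), mean = 2 * d$n_on * d$p_on)
    out <- two_way_anova(d)
    fit0 <- lm(cwm_1c_pg ~ 1, data = d)
    model_ss <- sum((fitted(out$fit) - fitted(fit0))^2)
    expect_equal(sum(out$anova$ss), model_ss, tolerance = 1e-9)

    d2 <- d; d2$cwm_1c_pg <- -3 + 7 * d$cwm_1c_pg
    expect_equal(two_way_anova(d2)$anova$F, out$anova$F, tolerance = 1e-8)
  }
})

test_that("mixed model collapses to OLS when between-group variance is zero", {
  # identical group means leave nothing for the random intercept
  d <- data.frame(g = rep(letters[1:4], each = 5),
                  x = rep(seq(-2, 2), 4))
  d$y <- 1 + 0.5 * d$x + rep(c(-0.2, -0.1, 0, 0.1, 0.2), 4)
  fit <- lmm_fit(d, y ~ x, "g", "REML")
  ols <- coef(lm(y ~ x, data = d))
  expect_equal(unname(fit$fixed_effects$estimate), unname(ols),
               tolerance = 1e-6)
  expect_lt(fit$variance_components[["g"]], 1e-6)
})

test_that("balanced one-way REML equals the ANOVA method-of-moments estimates", {
  set.seed(21)
  g <- 12; m <- 6
  grp <- rep(seq_len(g), each = m)
  y <- rnorm(g, sd = 1.5)[grp] + rnorm(g * m)
  d <- data.frame(y = y, g = factor(grp))
  msw <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / (g * (m - 1))
  msb <- m * sum((tapply(y, grp, mean) - mean(y))^2) / (g - 1)
  fit <- lmm_fit(d, y ~ 1, "g", "REML")
  expect_equal(fit$variance_components[["residual"]], msw, tolerance = 1e-4)
  expect_equal(fit$variance_components[["g"]], (msb - msw) / m,
               tolerance = 1e-4)
})

test_that("variance components are recovered from simulated mixed data", {
  set.seed(33)
  est <- t(replicate(20, {
    grp <- rep(1:50, each = 10)
    y <- rnorm(50)[grp] + rnorm(500)
    f <- lmm_fit(data.frame(y = y, g = factor(grp)), y ~ 1, "g", "REML")
    f$variance_components
  }))
  expect_equal(mean(est[, 1]), 1, tolerance = 0.2)
  expect_equal(mean(est[, 2]), 1, tolerance = 0.2)
})

test_that("likelihood-ratio machinery enforces its preconditions", {
  d <- data.frame(y = rnorm(40), x = rnorm(40), g = factor(rep(1:8, each = 5)))
  full <- lmm_fit(d, y ~ x, "g", "ML")
  same <- lmm_fit(d, y ~ x, "g", "ML")
  out <- lrt_reduce(full, same)
  expect_equal(out$chi2, 0, tolerance = 1e-8)
  expect_equal(out$p, 1)
  reml <- lmm_fit(d, y ~ x, "g", "REML")
  expect_error(lrt_reduce(reml, same), "ML")
  expect_error(lmm_fit(cbind(d, x2 = d$x), y ~ x + x2, "g", "ML"), "aliased")
})

test_that("backward elimination keeps a true P effect and drops dead columns", {
  de <- simulate_design(16, 4, seed = 40L)
  keep_p <- logical(10); extras <- integer(10)
  for (i in 1:10) {
    set.seed(400 + i)
    cw <- classify_treatment(de)
    cw$cwm_1c_pg <- 1 + 0.9 * cw$p_applied +
      rnorm(16, sd = 0.1)[as.integer(factor(cw$plot_id))] + rnorm(64, sd = 0.2)
    res <- per_nutrient_lme(cw, de)
    keep_p[i] <- "p_applied" %in% res$retained
    extras[i] <- length(setdiff(res$retained, "p_applied"))
  }
  expect_true(all(keep_p))
  expect_lte(mean(extras), 1)

  # all-zero nutrient columns: nothing to test, intercept-only retained
  de0 <- de
  de0$dose_nitrate <- 0; de0$dose_ammonium <- 0
  de0$p_applied <- FALSE; de0$k_applied <- FALSE
  de0$na_applied <- FALSE; de0$si_applied <- FALSE
  cw0 <- classify_treatment(de0)
  cw0$cwm_1c_pg <- rnorm(64)
  res0 <- per_nutrient_lme(cw0, de0)
  expect_equal(res0$retained, character(0))
  expect_setequal(res0$dropped_constant,
                  c("dose_nitrate", "dose_ammonium", "p_applied", "k_applied",
                    "na_applied", "si_applied"))
})

test_that("the group ANOVA uses subplot error strata with the expected df", {
  com <- simulate_community(sim_params(n_species = 60, n_plots = 16,
                                       subplots_per_plot = 4, seed = 50L))
  gs <- group_summaries(com$biomass, com$species, com$design,
                        threshold_pg = median(com$species$one_c_pg))
  out <- four_way_anova(gs, "sqrt_biomass")
  within <- out$anova[out$anova$stratum == "Within", ]
  # 64 subplots x 4 groups: 192 within-subplot df, minus 12 within terms
  expect_equal(unique(within$df_den), 180)
  expect_true("N:P:GS:Ploidy" %in% within$term)
  between <- out$anova[out$anova$stratum != "Within", ]
  expect_true(all(c("N", "P", "N:P") %in% between$term))

  gs0 <- gs; gs0$sqrt_biomass <- 1
  out0 <- four_way_anova(gs0, "sqrt_biomass")
  expect_true(all(out0$anova$F == 0))
})

test_that("tidiers return well-formed tables", {
  d <- classify_treatment(factorial_design(3))
  d$cwm_1c_pg <- rnorm(nrow(d), mean = d$p_on)
  a <- two_way_anova(d)
  expect_s3_class(tidy(a), "tbl_df")
  expect_named(glance(a), c("r_squared", "df_residual", "sigma", "response"))
  f <- lmm_fit(data.frame(y = rnorm(20), g = factor(rep(1:4, 5))), y ~ 1, "g", "ML")
  expect_equal(nrow(tidy(f)), 1)
  expect_equal(glance(f)$method, "ML")
})
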