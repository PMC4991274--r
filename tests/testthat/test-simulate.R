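test_that("pure-birth trees are ultrametric, labelled and deterministic", {
  tr <- simulate_tree(2, 1, seed = 3L)
  expect_equal(ape::Ntip(tr), 2)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))

  tr60 <- simulate_tree(60, 1, seed = 3L)
  depths <- diag(ape::vcv.phylo(tr60))
  expect_lt(diff(range(depths)), 1e-9 * max(depths))
  expect_equal(tr60$tip.label, sprintf("sp%03d", 1:60))

  again <- simulate_tree(60, 1, seed = 3L)
  expect_identical(ape::write.tree(tr60), ape::write.tree(again))
  expect_error(simulate_tree(1, 1, seed = 1L), "at least 2")
})

test_that("lambda = 0 trait simulation gives independent tips", {
  # sister tips share most of their Brownian history; with lambda = 0 the
  # shared part is switched off, so their correlation across replicates
  # vanishes
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.1):1.9,C:2):0;", f)
  tr <- read_newick(f)
  reps <- t(vapply(1:400, function(i) {
    log(simulate_gs(tr, 1, lambda_true = 0, root_log1c = 0, seed = i))
  }, numeric(3)))
  r <- cor(reps[, "A"], reps[, "B"])
  expect_lt(abs(r), 0.15)
  # and with lambda = 1 the same pair is strongly correlated
  reps1 <- t(vapply(1:400, function(i) {
    log(simulate_gs(tr, 1, lambda_true = 1, root_log1c = 0, seed = i))
  }, numeric(3)))
  expect_gt(cor(reps1[, "A"], reps1[, "B"]), 0.8)
  expect_error(simulate_gs(tr, 1, lambda_true = 1.5, seed = 1L), "lambda")
})

test_that("trait variance across replicates matches the Brownian closed form", {
  tr <- simulate_tree(5, 1, seed = 9L)
  height <- max(diag(ape::vcv.phylo(tr)))
  s2 <- 0.7
  tips <- t(vapply(1:500, function(i) {
    log(simulate_gs(tr, s2, 1, root_log1c = 2, seed = 1000L + i))
  }, numeric(5)))
  v <- var(tips[, 1])
  expect_equal(v, s2 * height, tolerance = 0.25)
  expect_equal(mean(tips[, 1]), 2, tolerance = 0.2)
})

test_that("Brownian traits carry Blomberg K near 1 on average", {
  tr <- simulate_tree(50, 1, seed = 21L)
  C <- phylo_covariance(tr)
  ks <- vapply(1:200, function(i) {
    blomberg_k(log(simulate_gs(tr, 0.5, 1, 0, seed = 5000L + i)), C)
  }, numeric(1))
  expect_equal(mean(ks), 1, tolerance = 0.15)
})

test_that("ploidy and strategy assignment respects its parameters", {
  gs <- setNames(rep(2, 50), sprintf("sp%03d", 1:50))
  alld <- assign_ploidy_csr(gs, p_polyploid = 0, multiplier = 3, seed = 1L)
  expect_true(all(alld$ploidy_class == "diploid"))
  expect_equal(alld$one_c_pg, rep(2, 50))

  sp <- assign_ploidy_csr(gs, p_polyploid = 0.5, multiplier = 3, seed = 2L)
  expect_true(all(abs(sp$csr_c + sp$csr_s + sp$csr_r - 1) < 1e-9))
  expect_true(all(sp$one_c_pg[sp$ploidy_class == "polyploid"] == 6))
  # multiplier 1 leaves the two classes identically distributed
  sp1 <- assign_ploidy_csr(gs, p_polyploid = 0.5, multiplier = 1, seed = 2L)
  expect_true(all(sp1$one_c_pg == 2))
})

test_that("factorial designs are balanced with pH in the inclusion range", {
  d4 <- simulate_design(4, 1, seed = 1L)
  expect_equal(sort(as.character(classify_treatment(d4)$treatment)),
               sort(c("control", "N", "P", "N+P")))
  d64 <- simulate_design(16, 4, seed = 1L)
  expect_equal(nrow(d64), 64)
  expect_true(all(table(classify_treatment(d64)$treatment) == 16))
  expect_true(all(d64$ph >= 4.5 & d64$ph <= 7.0))
  expect_error(simulate_design(3, 1, seed = 1L), "full factorial")
})

test_that("biomass generator honours its fixed-effect structure", {
  tr <- simulate_tree(10, 1, seed = 2L)
  gs <- simulate_gs(tr, 0.3, 1, 0.5, seed = 3L)
  sp <- assign_ploidy_csr(gs, 0.4, 2, seed = 4L)
  de <- simulate_design(8, 4, seed = 5L)

  # null model: every occupied biomass is exp(0) = 1
  p0 <- sim_params(n_species = 10, beta = numeric(0), sigma2_plot = 0,
                   sigma2_species = 0, sigma2_phylo = 0, sigma2_resid = 0,
                   occupancy = 1, seed = 6L)
  b0 <- simulate_biomass(sp, de, tr, p0)
  expect_true(all(b0$biomass_g == 1))

  # a pure P effect moves the log-biomass contrast by beta_P
  pP <- sim_params(n_species = 10, beta = c(p = 0.9), sigma2_plot = 0,
                   sigma2_species = 0, sigma2_phylo = 0, sigma2_resid = 1e-4,
                   occupancy = 1, seed = 7L)
  bP <- simulate_biomass(sp, de, tr, pP)
  dd <- classify_treatment(de)
  joined <- dplyr::left_join(bP, dd[, c("subplot_id", "p_on")], by = "subplot_id")
  contrast <- mean(log(joined$biomass_g[joined$p_on])) -
    mean(log(joined$biomass_g[!joined$p_on]))
  expect_equal(contrast, 0.9, tolerance = 0.02)

  expect_identical(simulate_biomass(sp, de, tr, pP),
                   simulate_biomass(sp, de, tr, pP))
  pbad <- pP; pbad$sigma2_phylo <- NULL
  expect_error(simulate_biomass(sp, de, tr, pbad), "sigma2_phylo")
})

test_that("positive GS x N x P effects raise CWM genome size on N+P subplots", {
  diffs <- vapply(1:100, function(i) {
    com <- simulate_community(sim_params(
      n_species = 15, n_plots = 4, subplots_per_plot = 4,
      lambda_true = 1, polyploid_gs_multiplier = 2, occupancy = 0.8,
      seed = 100L + i
    ))
    cw <- cwm_table(com$biomass, com$species, com$design)
    mean(cw$cwm_1c_pg[cw$treatment == "N+P"], na.rm = TRUE) -
      mean(cw$cwm_1c_pg[cw$treatment == "control"], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("the full generator is deterministic and writes loadable files", {
  com1 <- small_community(seed = 11L)
  com2 <- small_community(seed = 11L)
  expect_equal(com1$species, com2$species)
  expect_equal(com1$biomass$biomass_g, com2$biomass$biomass_g)
  dir <- withr::local_tempdir()
  write_community_set(com1, dir)
  sp <- read_species_table(file.path(dir, "species.csv"))
  expect_equal(nrow(sp), 20)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_equal(ape::Ntip(tr), 20)
})
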