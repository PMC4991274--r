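# Small in-code fixtures shared across test files.

toy_species <- function() {
  tibble::tibble(
    species_id = c("sp1", "sp2", "sp3", "sp4"),
    one_c_pg = c(1.2, 6.0, 2.0, 10.0),
    ploidy_class = c("diploid", "diploid", "polyploid", "polyploid"),
    csr_c = c(0.5, 1, 0, 1 / 3),
    csr_s = c(0.25, 0, 0.5, 1 / 3),
    csr_r = c(0.25, 0, 0.5, 1 / 3)
  )
}

toy_design <- function() {
  tibble::tibble(
    plot_id = c("p1", "p1", "p2", "p2"),
    subplot_id = c("p1a", "p1b", "p2a", "p2b"),
    dose_nitrate = c(0, 48, 0, 0),
    dose_ammonium = c(0, 0, 0, 96),
    p_applied = c(FALSE, FALSE, TRUE, TRUE),
    k_applied = c(FALSE, TRUE, FALSE, TRUE),
    na_applied = FALSE,
    mg_applied = FALSE,
    si_applied = FALSE,
    ph = c(5.2, 5.6, 6.0, 6.4)
  )
}

toy_biomass <- function() {
  tidyr::expand_grid(species_id = toy_species()$species_id,
                     subplot_id = toy_design()$subplot_id) |>
    dplyr::mutate(biomass_g = c(
      4, 2, 1, 0,    # sp1
      1, 3, 0, 5,    # sp2
      2, 2, 2, 2,    # sp3
      0, 1, 3, 6     # sp4
    ))
}

# a small but full synthetic community, fast to regenerate
small_community <- function(seed = 1L, ...) {
  simulate_community(sim_params(
    n_species = 20, n_plots = 8, subplots_per_plot = 4,
    occupancy = 0.6, seed = seed, ...
  ))
}

# balanced 2x2 design table: n_rep subplots per factorial cell
factorial_design <- function(n_rep = 4) {
  cells <- tidyr::expand_grid(n_on = c(FALSE, TRUE), p_on = c(FALSE, TRUE),
                              rep = seq_len(n_rep))
  tibble::tibble(
    plot_id = paste0("pl", rep(seq_len(nrow(cells) / 2), each = 2)),
    subplot_id = paste0("s", seq_len(nrow(cells))),
    dose_nitrate = ifelse(cells$n_on, 48, 0),
    dose_ammonium = 0,
    p_applied = cells$p_on,
    k_applied = FALSE, na_applied = FALSE, mg_applied = FALSE,
    si_applied = FALSE,
    ph = 5.75
  )
}
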