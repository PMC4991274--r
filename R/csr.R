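#' Partition one biomass value by a C:S:R strategy triple
#'
#' Componentwise product: a species holding 10 g with strategy
#' 0.5:0.25:0.25 contributes 5 g to C and 2.5 g to each of S and R. The
#' partition conserves mass exactly.
#'
#' @param biomass_g Non-negative dry weight (g); vectorised.
#' @param csr_c,csr_s,csr_r Strategy proportions, summing to 1 per species.
#' @return A tibble with columns `c_g`, `s_g`, `r_g`.
#' @export
#' @examples
#' partition_biomass_csr(10, 0.5, 0.25, 0.25) # 5, 2.5, 2.5
partition_biomass_csr <- function(biomass_g, csr_c, csr_s, csr_r) {
  if (any(biomass_g < 0)) abort("biomass must be non-negative")
  s <- csr_c + csr_s + csr_r
  if (any(abs(s - 1) > 1e-9)) {
    abort("C:S:R triple(s) do not sum to 1")
  }
  tibble(c_g = unname(biomass_g * csr_c),
         s_g = unname(biomass_g * csr_s),
         r_g = unname(biomass_g * csr_r))
}

#' Strategy-partitioned biomass by subplot and genomic group
#'
#' Each species' biomass is split into its C, S and R components, then
#' summed per subplot x genomic group. Ratios are of the subplot's total
#' biomass, so per subplot the C+S+R ratios over all four groups sum to 1.
#' Square-root transformed component columns are attached for the
#' strategy ANOVAs.
#'
#' @inheritParams group_summaries
#' @return A tibble with one row per subplot x genomic group and columns
#'   `c_g`, `s_g`, `r_g`, matching ratio columns (`c_ratio`, ...), and
#'   treatment metadata.
#' @export
csr_group_table <- function(biomass, species, design, threshold_pg = 5) {
  species <- partition_genomic_groups(validate_species(species), threshold_pg)
  design <- classify_treatment(design)
  parts <- biomass |>
    inner_join(select(species, "species_id", "genomic_group",
                      "csr_c", "csr_s", "csr_r"),
               by = "species_id")
  parts <- bind_cols(parts, partition_biomass_csr(parts$biomass_g, parts$csr_c,
                                                  parts$csr_s, parts$csr_r))
  out <- parts |>
    group_by(.data$subplot_id, .data$genomic_group) |>
    summarise(across(c("c_g", "s_g", "r_g"), sum),
              biomass_g = sum(.data$biomass_g), .groups = "drop") |>
    tidyr::complete(subplot_id = unique(design$subplot_id),
                    genomic_group = levels(species$genomic_group),
                    fill = list(c_g = 0, s_g = 0, r_g = 0, biomass_g = 0)) |>
    mutate(genomic_group = factor(.data$genomic_group,
                                  levels = levels(species$genomic_group))) |>
    group_by(.data$subplot_id) |>
    mutate(subplot_total_g = sum(.data$biomass_g),
           c_ratio = ratio_or_na(.data$c_g, .data$subplot_total_g),
           s_ratio = ratio_or_na(.data$s_g, .data$subplot_total_g),
           r_ratio = ratio_or_na(.data$r_g, .data$subplot_total_g)) |>
    ungroup() |>
    left_join(select(design, "subplot_id", "plot_id", "treatment",
                     "n_on", "p_on"),
              by = "subplot_id") |>
    mutate(threshold_pg = threshold_pg,
           sqrt_c = sqrt(.data$c_g), sqrt_s = sqrt(.data$s_g),
           sqrt_r = sqrt(.data$r_g))
  tidyr::separate_wider_delim(out, "genomic_group", "-",
                              names = c("ploidy_class", "gs_class"),
                              cols_remove = FALSE)
}

ratio_or_na <- function(x, total) ifelse(total > 0, x / total, NA_real_)

#' Treatment-level strategy ratios per genomic group
#'
#' @param csr As returned by [csr_group_table()].
#' @return One row per treatment x genomic group with mean (SD) C, S and
#'   R ratios of subplot total biomass.
#' @export
csr_treatment_summary <- function(csr) {
  csr |>
    group_by(.data$treatment, .data$genomic_group) |>
    summarise(across(c("c_ratio", "s_ratio", "r_ratio"),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              .groups = "drop")
}
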