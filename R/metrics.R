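#' Classify subplots into the factorial nutrient cells
#'
#' A subplot is N+ iff it receives any nitrogen (nitrate or ammonium dose
#' above zero) and P+ iff phosphorus is applied; the 2x2 cell gives the
#' treatment class `control`, `N`, `P` or `N+P`. Potassium, sodium,
#' magnesium and silica applications do not enter this four-cell factor
#' (their individual effects are examined with [per_nutrient_lme()]).
#'
#' @param design Design tibble (see [read_design_table()]).
#' @return The design with added logical columns `n_on`, `p_on` and a
#'   `treatment` factor levelled `control, N, P, N+P`.
#' @export
classify_treatment <- function(design) {
  design <- validate_design(design)
  design |>
    mutate(
      n_on = (.data$dose_nitrate + .data$dose_ammonium) > 0,
      p_on = .data$p_applied,
      treatment = factor(
        case_when(
          .data$n_on & .data$p_on ~ "N+P",
          .data$n_on ~ "N",
          .data$p_on ~ "P",
          TRUE ~ "control"
        ),
        levels = c("control", "N", "P", "N+P")
      )
    )
}

#' Biomass-weighted mean genome size of one community
#'
#' The community-weighted mean (CWM) 1C-value: each species' 1C-value
#' times its biomass fraction, summed over the species present,
#' \deqn{\mathrm{CWM} = \sum_i 1C_i \, b_i / \sum_j b_j.}
#'
#' @param biomass_g Numeric vector of dry weights (g), one per species.
#' @param one_c_pg Matching vector of 1C-values (pg); may contain NA for
#'   species with zero biomass.
#' @param na_action What to do when a species with positive biomass lacks
#'   a 1C-value: `"error"` (default) or `"drop"` (drop it and renormalize
#'   over the remaining biomass).
#' @return The CWM in pg, or `NA_real_` (with a warning) when total
#'   biomass is zero.
#' @export
#' @examples
#' biomass_weighted_mean_gs(c(1, 1), c(2, 6)) # 4
biomass_weighted_mean_gs <- function(biomass_g, one_c_pg,
                                     na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (length(biomass_g) != length(one_c_pg)) abort("length mismatch")
  if (any(biomass_g < 0)) abort("negative biomass")
  present <- biomass_g > 0
  if (!any(present)) {
    warn("total biomass is zero; CWM undefined")
    return(NA_real_)
  }
  if (anyNA(one_c_pg[present])) {
    if (na_action == "error") {
      abort("species with positive biomass lack a 1C-value (set na_action = 'drop' to renormalize without them)")
    }
    present <- present & !is.na(one_c_pg)
    if (!any(present)) {
      warn("no species with both biomass and a 1C-value")
      return(NA_real_)
    }
  }
  b <- biomass_g[present]
  sum(one_c_pg[present] * b / sum(b))
}

#' Per-subplot community-weighted mean genome size
#'
#' Applies [biomass_weighted_mean_gs()] to every subplot and attaches the
#' subplot's total biomass, species richness (species with biomass > 0)
#' and treatment class.
#'
#' @param biomass Long biomass tibble.
#' @param species Species tibble.
#' @param design Design tibble.
#' @param na_action Passed to [biomass_weighted_mean_gs()].
#' @return A tibble with one row per subplot: `subplot_id`, `plot_id`,
#'   `treatment`, `n_on`, `p_on`, `ph`, `cwm_1c_pg`, `total_biomass_g`,
#'   `n_species`.
#' @export
cwm_table <- function(biomass, species, design, na_action = "error") {
  design <- classify_treatment(design)
  biomass |>
    left_join(select(species, "species_id", "one_c_pg"), by = "species_id") |>
    group_by(.data$subplot_id) |>
    summarise(
      cwm_1c_pg = biomass_weighted_mean_gs(.data$biomass_g, .data$one_c_pg,
                                           na_action = na_action),
      total_biomass_g = sum(.data$biomass_g),
      n_species = sum(.data$biomass_g > 0),
      .groups = "drop"
    ) |>
    right_join(select(design, "subplot_id", "plot_id", "treatment",
                      "n_on", "p_on", "ph"),
               by = "subplot_id") |>
    relocate("subplot_id", "plot_id", "treatment")
}

#' Treatment-level summary of CWM genome size
#'
#' Means and standard deviations of subplot total biomass, species
#' richness and CWM 1C-value per treatment cell.
#'
#' @param cwm As returned by [cwm_table()].
#' @return One row per treatment.
#' @export
cwm_treatment_summary <- function(cwm) {
  cwm |>
    group_by(.data$treatment) |>
    summarise(
      n = n(),
      total_biomass_mean = mean(.data$total_biomass_g),
      total_biomass_sd = sd(.data$total_biomass_g),
      n_species_mean = mean(.data$n_species),
      n_species_sd = sd(.data$n_species),
      cwm_mean = mean(.data$cwm_1c_pg, na.rm = TRUE),
      cwm_sd = sd(.data$cwm_1c_pg, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Partition species into genomic groups
#'
#' Crosses the ploidy class with a genome-size threshold: "large" means
#' `one_c_pg >= threshold_pg` (boundary inclusive), giving the four groups
#' diploid-small, diploid-large, polyploid-small, polyploid-large.
#'
#' @param species Species tibble.
#' @param threshold_pg Threshold in pg (default 5).
#' @return The species tibble with added columns `gs_class`
#'   (`small`/`large`) and `genomic_group` (factor with the four groups).
#' @export
partition_genomic_groups <- function(species, threshold_pg = 5) {
  if (threshold_pg <= 0) abort("threshold_pg must be positive")
  species |>
    mutate(
      gs_class = ifelse(.data$one_c_pg >= threshold_pg, "large", "small"),
      genomic_group = factor(
        paste(.data$ploidy_class, .data$gs_class, sep = "-"),
        levels = c("diploid-small", "diploid-large",
                   "polyploid-small", "polyploid-large")
      )
    )
}

#' Biomass and richness by genomic group
#'
#' Per subplot and genomic group: summed biomass, the group's share of
#' subplot biomass, and the number of species with positive biomass.
#' Groups absent from a subplot appear with 0 g so that every subplot
#' carries all four groups (the shape the factorial group ANOVA expects).
#' Square-root transformed response columns (`sqrt_biomass`, `sqrt_n_species`)
#' are included, the transform used to meet ANOVA normality assumptions.
#'
#' @inheritParams cwm_table
#' @param threshold_pg Genome-size threshold (pg).
#' @return A tibble with one row per subplot x genomic group, plus
#'   treatment columns.
#' @export
group_summaries <- function(biomass, species, design, threshold_pg = 5) {
  species <- partition_genomic_groups(species, threshold_pg)
  design <- classify_treatment(design)
  base <- biomass |>
    inner_join(select(species, "species_id", "genomic_group"), by = "species_id") |>
    group_by(.data$subplot_id, .data$genomic_group) |>
    summarise(biomass_g = sum(.data$biomass_g),
              n_species = sum(.data$biomass_g > 0),
              .groups = "drop") |>
    tidyr::complete(subplot_id = unique(design$subplot_id),
                    genomic_group = levels(species$genomic_group),
                    fill = list(biomass_g = 0, n_species = 0L)) |>
    mutate(genomic_group = factor(.data$genomic_group,
                                  levels = levels(species$genomic_group)))
  base |>
    group_by(.data$subplot_id) |>
    mutate(biomass_ratio = if (sum(.data$biomass_g) > 0)
      .data$biomass_g / sum(.data$biomass_g) else NA_real_) |>
    ungroup() |>
    left_join(select(design, "subplot_id", "plot_id", "treatment",
                     "n_on", "p_on"),
              by = "subplot_id") |>
    mutate(threshold_pg = threshold_pg,
           sqrt_biomass = sqrt(.data$biomass_g),
           sqrt_n_species = sqrt(.data$n_species)) |>
    tidyr::separate_wider_delim("genomic_group", "-",
                                names = c("ploidy_class", "gs_class"),
                                cols_remove = FALSE)
}

#' Treatment-level means of group biomass ratios
#'
#' @param groups As returned by [group_summaries()].
#' @return One row per treatment x genomic group with mean/SD biomass,
#'   mean ratio and mean species count.
#' @export
group_treatment_summary <- function(groups) {
  groups |>
    group_by(.data$treatment, .data$genomic_group) |>
    summarise(
      biomass_mean = mean(.data$biomass_g),
      biomass_sd = sd(.data$biomass_g),
      ratio_mean = mean(.data$biomass_ratio, na.rm = TRUE),
      ratio_sd = sd(.data$biomass_ratio, na.rm = TRUE),
      n_species_mean = mean(.data$n_species),
      .groups = "drop"
    )
}
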