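#' Broom-style tidiers for cwmphylo fits
#'
#' `tidy()` returns the per-term table of a fit; `glance()` a one-row
#' model summary.
#'
#' @param x A fitted object (`cwm_anova`, `cwm_anova4`, `cwm_lmm`,
#'   `cwm_gls`, `cwm_pglmm`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.cwm_anova <- function(x, ...) x$anova

#' @rdname tidiers
#' @export
glance.cwm_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, df_residual = x$fit$df.residual,
         sigma = s$sigma, response = x$response)
}

#' @rdname tidiers
#' @export
tidy.cwm_anova4 <- function(x, ...) x$anova

#' @rdname tidiers
#' @export
tidy.cwm_lmm <- function(x, ...) x$fixed_effects

#' @rdname tidiers
#' @export
glance.cwm_lmm <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood, df = x$df, method = x$method,
         n = x$n,
         sigma2_group = unname(x$variance_components[1]),
         sigma2_residual = unname(x$variance_components["residual"]))
}

#' @rdname tidiers
#' @export
tidy.cwm_gls <- function(x, ...) x$coefficients

#' @rdname tidiers
#' @export
glance.cwm_gls <- function(x, ...) {
  tibble(sigma2 = x$sigma2, loglik = x$loglik, loglik_reml = x$loglik_reml,
         df_residual = x$df_residual)
}

#' @rdname tidiers
#' @export
tidy.cwm_pglmm <- function(x, ...) summary(x)

#' @rdname tidiers
#' @export
glance.cwm_pglmm <- function(x, ...) {
  tibble(n_samples = nrow(x$chains),
         iterations = x$schedule[["iterations"]],
         burn_in = x$schedule[["burn_in"]],
         thinning = x$schedule[["thinning"]],
         prior_v = x$prior$v, prior_nu = x$prior$nu, seed = x$seed)
}

#' Boxplot of CWM genome size by nutrient treatment
#'
#' @param cwm A [cwm_table()] result.
#' @return A ggplot.
#' @export
plot_cwm_treatment <- function(cwm) {
  ggplot2::ggplot(cwm, ggplot2::aes(x = .data$treatment, y = .data$cwm_1c_pg)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Nutrient treatment",
                  y = "Biomass-weighted mean 1C-value (pg)") +
    ggplot2::theme_minimal()
}

#' Biomass ratios of the four genomic groups by treatment
#'
#' @param groups A [group_summaries()] result.
#' @return A ggplot.
#' @export
plot_genomic_groups <- function(groups) {
  ggplot2::ggplot(groups,
                  ggplot2::aes(x = .data$treatment, y = .data$biomass_ratio,
                               fill = .data$genomic_group)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = "Nutrient treatment", y = "Share of subplot biomass",
                  fill = "Genomic group") +
    ggplot2::theme_minimal()
}

#' Trace plot of selected MCMC chains
#'
#' @param fit A `cwm_pglmm`.
#' @param terms Parameter names to show (default: first four).
#' @return A ggplot.
#' @export
plot_pglmm_trace <- function(fit, terms = head(colnames(fit$chains), 4)) {
  df <- as_tibble(fit$chains[, terms, drop = FALSE]) |>
    mutate(sample = dplyr::row_number()) |>
    tidyr::pivot_longer(-"sample", names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::theme_minimal()
}
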