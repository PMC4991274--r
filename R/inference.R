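#' Two-way factorial ANOVA of a subplot response on N and P
#'
#' Fits `response ~ N + P + N:P` with N and P as 0/1 factors and
#' sequential (Type I) sums of squares in that order — the appropriate
#' decomposition for this unbalanced design when terms are entered in
#' declared order. Alongside the ANOVA table, treatment contrasts against
#' the control cell (coefficients of the N, P and N+P cells relative to
#' control) are reported.
#'
#' @param cwm Subplot-level table with logical columns `n_on`, `p_on`, a
#'   `treatment` factor and the response column (see [cwm_table()]).
#' @param response Name of the response column (default `"cwm_1c_pg"`).
#' @return A list of class `cwm_anova`: `anova` (tibble: term, df_num,
#'   df_den, ss, F, p), `contrasts` (tibble: cell, estimate, se), and the
#'   underlying `lm` fits.
#' @export
two_way_anova <- function(cwm, response = "cwm_1c_pg") {
  dat <- as.data.frame(cwm)
  dat$.y <- dat[[response]]
  dat <- dat[is.finite(dat$.y), ]
  dat$N <- factor(ifelse(dat$n_on, "N+", "N-"), levels = c("N-", "N+"))
  dat$P <- factor(ifelse(dat$p_on, "P+", "P-"), levels = c("P-", "P+"))
  cells <- table(dat$N, dat$P)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    abort(paste0("empty factorial cell(s): ",
                 paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                       collapse = "; ")))
  }
  fit <- lm(.y ~ N + P + N:P, data = dat)
  tab <- tidy_sequential_anova(fit)
  cfit <- lm(.y ~ treatment, data = dat)
  cs <- summary(cfit)$coefficients
  contrasts <- tibble(
    cell = sub("^treatment", "", rownames(cs)),
    estimate = cs[, 1], se = cs[, 2], t = cs[, 3], p = cs[, 4]
  )
  structure(list(anova = tab, contrasts = contrasts,
                 fit = fit, contrast_fit = cfit, response = response),
            class = "cwm_anova")
}

# sequential SS table from an lm fit, with the 0/0 conventions:
# a term with (numerically) zero SS gets F = 0; a positive term SS over a
# zero residual SS is undefined and reported NA with a warning.
tidy_sequential_anova <- function(fit) {
  a <- anova(fit)
  terms <- rownames(a)
  resid_row <- terms == "Residuals"
  rss <- a[resid_row, "Sum Sq"]
  rdf <- a[resid_row, "Df"]
  tot <- sum(a[, "Sum Sq"])
  ss <- a[!resid_row, "Sum Sq"]
  df <- a[!resid_row, "Df"]
  ms_res <- rss / rdf
  Fv <- ss / df / ms_res
  zero_ss <- ss <= 1e-12 * (tot + 1)
  Fv[zero_ss] <- 0
  if (rss <= 1e-12 * (tot + 1) && any(!zero_ss)) {
    warn("residual sum of squares is zero; F undefined for non-null terms")
    Fv[!zero_ss] <- NA_real_
  }
  p <- ifelse(is.na(Fv), NA_real_, pf(Fv, df, rdf, lower.tail = FALSE))
  p[zero_ss] <- 1
  tibble(term = terms[!resid_row], df_num = df, df_den = rdf,
         ss = ss, F = Fv, p = p)
}

#' Random-intercept linear mixed model
#'
#' Gaussian mixed model with a single random intercept, estimated by
#' maximum likelihood or REML (via [nlme::lme()]). The design is checked
#' for full rank first; aliased columns are reported by name rather than
#' silently dropped.
#'
#' @param data A data frame.
#' @param fixed Fixed-effects formula, e.g. `y ~ n_on * p_on`.
#' @param group Name of the grouping column for the random intercept.
#' @param method `"ML"` or `"REML"`.
#' @return An object of class `cwm_lmm`: tibble `fixed_effects`
#'   (term, estimate, se), named vector `variance_components`
#'   (`<group>`, `residual`), `log_likelihood`, `method`, `n`, and the
#'   underlying `lme` fit.
#' @export
lmm_fit <- function(data, fixed, group, method = c("ML", "REML")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  if (length(unique(data[[group]])) < 2) {
    abort("grouping factor must have at least 2 levels")
  }
  mm <- stats::model.matrix(fixed, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(paste0("fixed design is not full rank; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  random <- as.formula(paste0("~ 1 | ", group))
  fit <- nlme::lme(fixed = fixed, random = random, data = data,
                   method = method,
                   control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
  ct <- summary(fit)$tTable
  vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
  variance <- setNames(vc[seq_len(2)], c(group, "residual"))
  structure(
    list(fixed_effects = tibble(term = rownames(ct), estimate = ct[, 1],
                                se = ct[, 2]),
         variance_components = variance,
         log_likelihood = as.numeric(logLik(fit)),
         df = attr(logLik(fit), "df"),
         method = method, n = nrow(data), fit = fit,
         fixed = fixed, group = group),
    class = "cwm_lmm"
  )
}

#' Likelihood-ratio test between nested ML mixed-model fits
#'
#' Twice the log-likelihood difference, referred to a chi-square with
#' degrees of freedom equal to the parameter-count difference. Both fits
#' must be ML on the same data: REML likelihoods are not comparable
#' across fixed-effect structures and are rejected.
#'
#' @param full,reduced `cwm_lmm` fits with the reduced model nested in
#'   the full one.
#' @return A tibble with `chi2`, `df`, `p`.
#' @export
lrt_reduce <- function(full, reduced) {
  if (full$method != "ML" || reduced$method != "ML") {
    abort("both fits must use ML (REML likelihoods are not comparable across fixed structures)")
  }
  if (full$n != reduced$n) abort("fits are not on the same data")
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  df <- full$df - reduced$df
  if (df < 0) abort("`reduced` has more parameters than `full`")
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  tibble(chi2 = chi2, df = df, p = p)
}

#' Per-nutrient mixed models with backward elimination
#'
#' Regresses the subplot response on the individual nutrient columns
#' (nitrate dose, ammonium dose, P, K, Na, Si applications) with a
#' plot-level random intercept, then removes the least significant term
#' by ML likelihood-ratio test until every remaining term is significant
#' at `alpha`. The final model is refit with REML. Columns constant
#' across subplots carry no information and are set aside up front.
#'
#' @param cwm Subplot response table (needs `plot_id` and the response).
#' @param design Design table providing the nutrient columns.
#' @param response Response column name.
#' @param alpha Elimination threshold (default 0.05).
#' @param nutrients Candidate columns.
#' @return A list of class `cwm_nutrient_lme`: `final` (REML `cwm_lmm`),
#'   `retained`, `dropped_constant`, and `steps` (tibble of LRT p-values
#'   per elimination round).
#' @export
per_nutrient_lme <- function(cwm, design, response = "cwm_1c_pg", alpha = 0.05,
                             nutrients = c("dose_nitrate", "dose_ammonium",
                                           "p_applied", "k_applied",
                                           "na_applied", "si_applied")) {
  dat <- as.data.frame(
    left_join(cwm, select(design, "subplot_id", dplyr::any_of(nutrients)),
              by = "subplot_id", suffix = c("", ".design"))
  )
  dat$.y <- dat[[response]]
  dat <- dat[is.finite(dat$.y), ]
  constant <- nutrients[vapply(nutrients, function(v) {
    length(unique(dat[[v]])) < 2
  }, logical(1))]
  terms <- setdiff(nutrients, constant)
  steps <- list()
  round <- 0
  repeat {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    full <- lmm_fit(dat, as.formula(paste(".y ~", rhs)), "plot_id", "ML")
    if (!length(terms)) break
    pvals <- vapply(terms, function(tm) {
      rest <- setdiff(terms, tm)
      rhs_r <- if (length(rest)) paste(rest, collapse = " + ") else "1"
      red <- lmm_fit(dat, as.formula(paste(".y ~", rhs_r)), "plot_id", "ML")
      lrt_reduce(full, red)$p
    }, numeric(1))
    round <- round + 1
    steps[[round]] <- tibble(round = round, term = terms, p = unname(pvals))
    worst <- which.max(pvals)
    if (pvals[worst] > alpha) {
      terms <- terms[-worst]
    } else break
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  final <- lmm_fit(dat, as.formula(paste(".y ~", rhs)), "plot_id", "REML")
  structure(list(final = final, retained = terms,
                 dropped_constant = constant,
                 steps = bind_rows(steps)),
            class = "cwm_nutrient_lme")
}

#' Factorial ANOVA of group biomass on N, P, genome-size class and ploidy
#'
#' Fits `response ~ N * P * GS * Ploidy` (all binary) with sequential sums
#' of squares and subplot identity as an error stratum, so that terms
#' varying within subplots (GS class, ploidy and their interactions) are
#' tested against the within-subplot residual. On a 64-subplot, 4-group
#' layout that residual has 180 degrees of freedom. The response should be
#' a square-root-transformed biomass or species count column from
#' [group_summaries()] or [csr_group_table()].
#'
#' @param groups Long table with one row per subplot x genomic group
#'   (columns `n_on`, `p_on`, `gs_class`, `ploidy_class`, `subplot_id`).
#' @param response Response column name (default `"sqrt_biomass"`).
#' @return A list of class `cwm_anova4`: `anova` tibble (term, stratum,
#'   df_num, df_den, ss, F, p) and the underlying `aov` fit.
#' @export
four_way_anova <- function(groups, response = "sqrt_biomass") {
  dat <- as.data.frame(groups)
  dat$.y <- dat[[response]]
  dat$N <- factor(ifelse(dat$n_on, "N+", "N-"), levels = c("N-", "N+"))
  dat$P <- factor(ifelse(dat$p_on, "P+", "P-"), levels = c("P-", "P+"))
  dat$GS <- factor(dat$gs_class, levels = c("small", "large"))
  dat$Ploidy <- factor(dat$ploidy_class, levels = c("diploid", "polyploid"))
  dat$subplot_id <- factor(dat$subplot_id)
  if (any(table(dat$N, dat$P) == 0)) abort("empty N x P cell")
  fit <- aov(.y ~ N * P * GS * Ploidy + Error(subplot_id), data = dat)
  strata <- summary(fit)
  tabs <- purrr::imap(strata, function(s, nm) {
    a <- as.data.frame(s[[1]])
    term <- trimws(rownames(a))
    resid <- term == "Residuals"
    rdf <- a$Df[resid]
    rss <- a$`Sum Sq`[resid]
    if (!length(rdf)) { rdf <- NA_real_; rss <- NA_real_ }
    ss <- a$`Sum Sq`[!resid]
    df <- a$Df[!resid]
    Fv <- ss / df / (rss / rdf)
    zero <- ss <= 1e-12 * (sum(a$`Sum Sq`) + 1)
    Fv[zero] <- 0
    p <- ifelse(is.na(Fv), NA_real_, pf(Fv, df, rdf, lower.tail = FALSE))
    p[zero] <- 1
    tibble(term = term[!resid],
           stratum = sub("^Error: ", "", nm),
           df_num = df, df_den = rdf, ss = ss, F = Fv, p = p)
  })
  structure(list(anova = bind_rows(tabs), fit = fit, response = response),
            class = "cwm_anova4")
}
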