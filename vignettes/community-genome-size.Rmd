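---
title: "Genome size, ploidy and nutrient limitation in plant communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome size, ploidy and nutrient limitation in plant communities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwmphylo)
```

## The scientific question

Nucleic acids are among the most nitrogen- and phosphorus-demanding
molecules a plant builds, so a species' genome size (its 1C-value, the DNA
amount of the unreplicated gametic nucleus, in picograms) sets a floor on
its N and P demand. In a nutrient-limited grassland this predicts that
species with large genomes — and polyploids, whose genomes are multiplied
wholesale — should be at a disadvantage unless *both* N and P are
supplied. `cwmphylo` provides the full analysis chain for testing that
prediction on long-term factorial fertilization experiments: community
trait summaries, biomass partitions, classical factorial inference, and
phylogenetically explicit models.

The package expects four inputs:

* a **species table**: 1C-value (pg), ploidy class (diploid/polyploid),
  and a Grime C-S-R strategy triple per species;
* a **design table**: per-subplot nutrient doses (nitrate and ammonium in
  kg N ha^-1^ yr^-1^), P/K/Na/Mg/Si application flags, and soil pH;
* a **biomass table**: species-by-subplot dry weight (g), with 0 meaning
  absent;
* an ultrametric **phylogeny** (Newick) over the species.

## Community-weighted mean genome size

The first-line statistic is the biomass-weighted community mean (CWM)
1C-value of each subplot,

$$\mathrm{CWM}_j \;=\; \sum_i 1C_i \,\frac{b_{ij}}{\sum_k b_{kj}},$$

where $b_{ij}$ is the dry weight of species $i$ on subplot $j$. It is
bounded by the smallest and largest 1C present and invariant to rescaling
a subplot's biomasses — both properties are enforced by tests. Subplots
are classified into the 2×2 factorial cells (control, N, P, N+P): a
subplot is N+ iff its nitrate plus ammonium dose is positive, and P+ iff
phosphorus is applied. Other nutrients do not enter this four-cell
factor; their individual contributions are screened separately (below).

The N and P effects on CWM are tested with a two-way ANOVA using
*sequential* (Type I) sums of squares in the order N, P, N:P. Sequential
decomposition is the deliberate choice for these historically unbalanced
designs (the classical layout has 12/11/16/25 subplots per cell): each
term is adjusted for those before it, the decomposition is exact, and the
terms sum to the model SS. Treatment contrasts against the control cell
are reported alongside. Two conventions for degenerate cases: a term with
numerically zero SS reports F = 0 (a constant response is "no effect",
not 0/0), while a positive SS over a zero residual SS is reported as
undefined with a warning rather than infinity.

Per-nutrient screening (`per_nutrient_lme()`) regresses CWM on the
individual nutrient columns with a plot-level random intercept, then
removes the least significant term by maximum-likelihood likelihood-ratio
test until all survivors are significant at α = 0.05; the final model is
refit with REML. The random intercept is placed at the *plot* (main-plot)
level: a subplot-level intercept under a subplot-level response is
confounded with the residual, so the plot level is the finest grouping
that remains identifiable. Mixed models are estimated by `nlme::lme`;
REML fits are refused by the LRT machinery because REML likelihoods are
not comparable across fixed structures.

## Genomic groups and C-S-R partitions

Species are crossed into four *genomic groups* by ploidy class and a
genome-size threshold: "large" means 1C ≥ threshold, boundary inclusive,
with 5 pg the default and 2.5, 3 and 6 pg the conventional alternatives
(2.5 pg is near the angiosperm-wide median). Per subplot and group the
package reports summed biomass, the group's share of subplot biomass
(shares sum to 1 exactly), and species counts; a species contributes to
richness only when its recorded biomass is positive. Groups absent from a
subplot are kept as explicit zeros so the group-level factorial ANOVA
sees a complete subplot × group layout.

Each species' biomass is also split into Grime's C, S and R components by
its strategy triple (componentwise product: 10 g at 0.5:0.25:0.25 gives
5, 2.5 and 2.5 g). The partition conserves mass exactly and commutes with
the genomic grouping. A lookup (`csr_code_to_triple()`) translates letter
codes ("C", "CSR", "C/CSR", ...) into numeric triples: a pure letter
takes the unit mass, a multi-letter code splits it equally, a slash code
averages its two sides.

Group-level responses (square-root transformed biomass or counts — the
transform used to bring the heavy-tailed biomass data near normality)
are analysed with `response ~ N * P * GS * Ploidy` and subplot identity
as an error stratum: terms varying within subplots (GS class, ploidy and
their interactions) are tested against the within-subplot residual,
which on a 64-subplot, four-group layout carries 180 degrees of freedom.

## Phylogenetic signal

Genome size is phylogenetically conserved, so species are not independent
data points. Two standard statistics quantify this for log 1C (the log
scale is the package default, matching how 1C enters every model; a
`scale = "raw"` switch is provided):

**Blomberg's K** compares the observed ratio of mean squared error from
the phylogenetic mean to its Brownian-motion expectation,

$$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
           {\big(\mathrm{tr}(C) - n/(\mathbf{1}^\top C^{-1}\mathbf{1})\big)/(n-1)},$$

with $C$ the shared-branch-length matrix, phylogenetic mean
$\hat a = \mathbf{1}^\top C^{-1} y / \mathbf{1}^\top C^{-1}\mathbf{1}$,
$\mathrm{MSE}_0$ the ordinary mean square about $\hat a$ and
$\mathrm{MSE}$ its $C^{-1}$-weighted counterpart. K equals 1 under
Brownian motion, exactly 1 on a star phylogeny, and grows with
stronger-than-Brownian clustering. Significance comes from permuting
trait values across tips and asking how often the permuted phylogenetic
MSE is at most the observed one, with the add-one correction
$p = (1 + \#\{\mathrm{MSE}^* \le \mathrm{MSE}\})/(n_\mathrm{perm}+1)$
(default 999 permutations, seeded).

**Pagel's λ** rescales the off-diagonal of $C$ and is estimated by
maximum likelihood with the mean and rate profiled out, leaving a
one-dimensional optimization over $[0, \lambda_\mathrm{max}]$.
$\lambda_\mathrm{max}$ is the largest value keeping $C(\lambda)$
positive definite, bounded by the pairwise ratios
$\min(C_{ii},C_{jj})/C_{ij}$ and capped at 1.2 — deliberately above 1,
since empirical estimates slightly exceeding 1 occur for strongly
conserved traits. A likelihood-ratio test against λ = 0 uses the
χ²~1~ reference. Both statistics return flagged missing values, with a
warning, for constant traits.

Numerical choices: covariance factorizations go through a Cholesky with
one jitter-and-retry (10^-8^ of the mean diagonal) for matrices made
singular by, e.g., zero-length terminal branches; the reader flags such
branches on input.

## Phylogenetic GLS

`gls_fit()` is the closed-form generalized least squares
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ with
$\hat\sigma^2 = r^\top V^{-1} r/(n-p)$; with $V = C$ it is PGLS under
Brownian motion, and with $V = I$ it reduces to OLS exactly (a test
identity). Phylogenetically corrected group means
(`pgls_species_mean()`) regress a tip trait on group indicators with
$V = C$; on a star tree they collapse to arithmetic group means, and
with a single group they equal the phylogenetic mean inside Blomberg's K
— a deliberate cross-module identity.

`pgls_cwm()` supplies a phylogenetically corrected analogue of the CWM:
per treatment, a phylogenetic *weighted* mean of species log 1C with
weights proportional to each species' summed biomass under that
treatment (implemented by scaling the Brownian covariance by inverse
weights). The construction of a "phylogenetic biomass-weighted mean" is
genuinely under-determined — biomass could enter as weights at species
level or the response could be modelled at subplot level — and we
document ours as one defensible interpretation; the primary community
statistic remains the ordinary CWM.

## The Bayesian phylogenetic mixed model

The central inferential model is a Gaussian "animal model" for log
biomass of the occupied species-subplot pairs:

$$\log b_{ij} = x_{ij}^\top\beta + u_{\mathrm{plot}(j)} + s_i + a_i + e_{ij},$$

with $u \sim N(0, \sigma^2_\mathrm{plot} I)$,
$s \sim N(0, \sigma^2_\mathrm{sp} I)$,
$a \sim N(0, \sigma^2_\mathrm{phy} C)$ and
$e \sim N(0, \sigma^2_e I)$. The fixed design has 17 terms — intercept,
log 1C (`gs`), N, P, ploidy (all binary except `gs` and pH), pH, and
every interaction among gs/N/P/ploidy — in a fixed canonical order
(`fixed_terms()`). pH enters uncentred so its slope reads per pH unit; a
`terms` argument selects reduced structures (e.g. main effects only),
the natural fit when the question concerns a main effect and the
appropriate design for parameter-recovery studies whose generating model
has no interactions. Zero-biomass pairs are excluded (absence is a
different process than yield and is not modelled here); $C$ is scaled to
unit maximum diagonal so $\sigma^2_\mathrm{phy}$ is comparable across
trees.

The sampler is a conjugate Gibbs scheme, with the inner loop in
compiled code: all location effects $(\beta, u, s, a)$ are drawn in one
block from their joint multivariate-normal full conditional — the
phylogenetic block contributes $C^{-1}/\sigma^2_\mathrm{phy}$ to the
precision, fixed effects carry a diffuse normal prior (precision
10^-8^) — and each variance then follows its scaled-inverse-χ²
full conditional. Priors are scaled-inverse-χ²(ν, V) per component,
default ν = 0.5, V = 1; ν and V may differ across the four components
(plot, phylogeny, species, residual), e.g. to pin random-effect
variances near zero, in which limit the posterior fixed-effect means
collapse onto the OLS solution (a test invariant). ν = 0 (flat) is
accepted with an impropriety warning. Run against an empty design the
sampler returns draws from the prior itself, which is exactly the
posterior in that case — the basis of the prior-recovery test.

The default schedule is 60,000 iterations, 10,000 burn-in, thinning 10.
The block-conjugate updates mix quickly (fixed-effect effective sample
sizes on the default synthetic fixture are a large fraction of the 5,000
retained draws), so this desk-scale schedule gives stable summaries in
tens of seconds; multi-million-iteration schedules are only a config
change. Summaries per parameter: posterior mean, central 95% credible
interval, effective sample size by the initial-positive-sequence
truncation of the autocorrelation sum ($\mathrm{ESS} = M/(1 +
2\sum\rho_k)$, about $M$ for independent draws and $M(1-\rho)/(1+\rho)$
for AR(1)), and the two-sided sign probability pMCMC
$= 2\min(\#\{\theta>0\},\#\{\theta<0\})/M$, floored at $1/M$ and
labelled `< 1/M` when all draws share a sign. pMCMC is reported for
fixed effects only — sign probabilities are meaningless for variances.
`sensitivity_scan()` refits under a list of priors at a reduced schedule
and reports the largest shift in fixed-effect posterior means.

## The synthetic-community generator

Every stage is testable without field data via `simulate_community()`,
which draws:

1. an ultrametric pure-birth tree (`ape::rphylo`, death rate 0);
2. log 1C from $N(\mu_0, \sigma^2_\mathrm{BM}\, C(\lambda))$ — λ = 1 is
   Brownian motion, λ = 0 independent tips;
3. ploidy flags (Bernoulli) with polyploid 1C multiplied by a
   configurable factor ≥ 1, creating the genome-size/ploidy association
   observed in real communities (its magnitude in any particular
   grassland is unknown — the multiplier is a free parameter, not an
   estimate); C-S-R triples from a Dirichlet distribution, summing to 1
   by construction;
4. a balanced 2×2 factorial design (with four subplots per plot, every
   plot carries each cell once), nitrate/ammonium doses from the
   classical dose sets {48, 96} and {48, 96, 144} kg N ha^-1^ yr^-1^,
   and pH uniform on [4.5, 7.0], the inclusion range of limed subplots;
5. biomass from the mixed model above, with occupancy an independent
   Bernoulli per pair (independent of treatment, keeping the generative
   model identifiable; richness-dependent occupancy can be layered on by
   the caller).

Defaults are 60 species on 16 plots × 4 subplots. The default
fixed-effect vector uses effect sizes of the magnitude estimated from
long-term grassland fertilization data — a positive P main effect
(0.907), a positive GS:N:P three-way interaction (0.71), a strong
positive GS:P:ploidy term (1.225) and negative GS:P and P:ploidy
two-way terms — so the canonical qualitative pattern (higher CWM genome
size on N+P subplots, driven by large-genomed polyploids) emerges in
expectation. Variance components default to a unit-scale baseline
(plot 0.25, species 0.5, phylogenetic 0.25, residual 1.0), values
typical of log-biomass data after covariate adjustment; occupancy
defaults to 0.5, matching communities where a subplot holds roughly half
the species pool. pH enters the generator centred at 5.75 (the midpoint
of the included range) so the intercept is interpretable.

What the generator does *not* emulate: temporal dynamics, competition,
dispersal or seed banks; treatment-dependent occupancy; measurement
error in 1C-values; and the particular unbalanced treatment replication
of any historical experiment (its design is balanced). Tests passing on
synthetic data therefore validate the *statistical machinery* — they do
not by themselves certify conclusions about any real grassland.

## A complete run

```{r pipeline, eval = FALSE}
com <- simulate_community(sim_params(seed = 1L))
cfg <- run_config(seed = 1L)
res <- run_pipeline(com$species, com$design, com$biomass, com$tree, cfg)

res$cwm_summary          # CWM 1C by treatment
tidy(res$anova_np)       # N, P, N:P sequential ANOVA
res$signal               # Blomberg K + permutation p, Pagel lambda + LR p
summary(res$pglmm)       # posterior means, CIs, ESS, pMCMC
```

`run_pipeline()` sweeps genome-size thresholds on request
(`thresholds = c(2.5, 3, 5, 6)`), can skip the MCMC stage
(`run_pglmm = FALSE`) without touching any other output, and
`write_pipeline()` emits every table as CSV plus a short markdown
report with seed and version provenance.

## Problem sizes and runtime

The default synthetic study (60 species, 64 subplots, ~1,900 occupied
pairs) runs the full pipeline, including the 60,000-iteration sampler,
in well under a minute on one core. The package's own simulation-based
checks use: 100 replicates of 200-tip trees for λ recovery, 20
generator seeds at the default schedule for posterior recovery of a
known P effect, 1,000 null replicates for the size of the
likelihood-ratio reduction test, and 10,000-draw chains for the ESS and
pMCMC identities. These sizes give Monte-Carlo error comfortably below
each check's tolerance.

## Known limitations

* Only Brownian (and λ-scaled) trait covariance; no Ornstein-Uhlenbeck
  or other correlation structures.
* The mixed models are Gaussian random-intercept models; no random
  slopes, non-Gaussian families, or denominator-df approximations
  (Satterthwaite/Kenward-Roger) — model reduction uses ML LRTs instead.
* Presence/absence is not modelled jointly with yield (no zero
  inflation).
* The phylogenetically corrected community mean is one documented
  interpretation of an under-specified construction (see above).
* The permutation test's smallest attainable p is bounded by the number
  of distinguishable permutations on small trees.
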