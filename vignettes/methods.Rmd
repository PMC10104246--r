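---
title: "Models and simulation design in noncogdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design in noncogdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`noncogdev` studies a single scientific question from several
methodological angles: how much of children's academic achievement, and of
its change from middle childhood to adolescence, traces back to genetic
dispositions toward *cognitive* skills (test performance) versus
*noncognitive* skills (motivation, self-regulation, educational attitudes),
and through which gene-environment pathways those dispositions act. Because
individual-level twin-cohort data and biobank GWAS summary statistics are
restricted, the package pairs every estimator with a synthetic-data engine
whose generative model encodes the assumed architecture, so every analysis
can be validated by parameter recovery against known truth.

This vignette documents the models, the generator's assumptions, the
numerical choices, and what passing tests do and do not establish.

## The generative model

### Genotypes and linkage disequilibrium

The LD reference (`build_ld_reference`) places `M` biallelic SNPs into
contiguous blocks. Haplotypes are drawn by Gaussian-copula thresholding: a
latent normal vector with AR(1) correlation within the block is cut at
`qnorm(maf)`. Thresholding attenuates correlation, so the reference stores
both the latent matrix (used for sampling) and the exact allele-scale
correlation it implies, obtained analytically from the Plackett identity
$\partial \Phi_2 / \partial \rho = \phi_2$ with fixed Gauss-Legendre
quadrature. All LD scores $\ell_j = \sum_k r^2_{jk}$ are computed on the
allele scale, which is the scale the realized genotypes actually exhibit;
we verified the quadrature against sampled haplotype correlations to three
decimals. The AR(1) parameter is graded across blocks from 0 up to the
configured `ld_decay` (default 0.9). This emulates variable recombination
intensity and, importantly, gives LD-score regression genuine leverage: a
constant-LD genome leaves the regression of $\chi^2$ on $\ell$ nearly
unidentified, which is a property of the design, not of the estimator.
Defaults are desk-scaled: `M = 5000` SNPs in 100 blocks, discovery
`N = 10000` per trait, 2000 twin families (one third MZ). Recombination is
free between blocks and absent within them, so LDpred windows coincide with
blocks by construction.

### Families and meiosis

`simulate_genotype_panel` builds nuclear families: two parents of two
haplotypes each; each child receives one haplotype per parent, chosen
independently per block. MZ pairs copy the first twin's transmissions
exactly, DZ pairs draw independently, giving the canonical expectations
(MZ genotype correlation 1; DZ sharing each parental transmission with
probability 1/2). True factor scores `G_cog` and `G_noncog` are weighted
sums of standardized genotypes with per-SNP effects drawn once per
configuration (infinitesimal by default: every SNP causal with variance
1/M), shared between the family panel and all discovery cohorts, and
standardized against the founder distribution.

### The two-factor GWAS architecture

Eight discovery traits mirror the extended GWAS-by-subtraction layout:
five cognitive-test traits (`CP`, `SD`, `ME`, `TM`, `RT`) load only on the
Cog genetic factor; educational attainment (`EA`) and two socioeconomic
indicators (`IN`, `DE`) load on both Cog and NonCog. Default loadings give
SNP heritabilities between about 0.17 and 0.41, in the range of
biobank-scale behavioural GWAS. Each trait gets its own independent
discovery cohort by default, so cross-trait LDSC intercepts are near zero;
`sample_overlap` plus an environmental correlation re-creates the
overlapping-cohort situation in which the intercept approaches the
phenotypic correlation times the overlap fraction.

### Twin phenotypes

`simulate_twin_phenotypes` draws twin pairs from the exact multivariate
normal implied by ACE component matrices: cross-twin genetic correlation 1
(MZ) or 0.5 (DZ), shared environment correlated 1, nonshared environment
uncorrelated. Measurement cells (domain x rater x age) each have a latent
factor with its own a2/c2/e2 and equally loaded indicators whose residual
variance is split over indicator-specific A/C/E, i.e. the data are exactly
a common-pathway model's implied distribution. The parent-reported
education-specific noncognitive cell at age 9 is generated with latent
heritability 0.93 — the strongest value the study conditions call for —
and the other cells use moderate values (0.5-0.6 heritability). The
measurement loadings themselves are free parameters of the simulator: the
source literature reports them only in supplementary material, so defaults
(0.65-0.8) were chosen once as typical questionnaire loadings and are not
calibrated to any cohort.

### Developmental achievement and gene-environment correlation

`simulate_developmental_outcomes` is the core of the design. A family
environment $F = \gamma\,\mathrm{midparent}(G_{noncog}) + u$ carries
passive rGE; achievement at age $t$ is

$$y_t = b_{cog}(t)\,G_{cog} + \left(b_{noncog}(t) + \lambda(t)\right)
G_{noncog} + \kappa F + \varepsilon_t,$$

with $\lambda(t)$ an age-indexed path from the child's own noncognitive
genetic value standing in for evocative/active rGE, which the source
literature describes only verbally; routing it additively through the
child's own genotype is the simplest mechanism with the right observable
signature (a within-family effect that grows with age). Default paths:
$b_{cog} = 0.24$ at every age (a flat cognitive profile),
$b_{noncog} = 0.10$, $\lambda = (0, 0.04, 0.08, 0.12)$ across ages 7, 9,
12, 16 — so the total child-side noncognitive effect rises from 0.10 to
0.22 — and $\gamma = 0.5$, $\kappa = 0.4$, giving a passive-rGE
contribution of $\kappa\gamma/2 = 0.10$ at the population level. Under
random mating $\mathrm{cov}(G_{child}, \mathrm{midparent}) = 1/2$, so with
$\lambda \equiv 0$ the population-level noncognitive effect (0.20) is
twice the direct effect (0.10), the regime in which the within-family
estimate is about half the population estimate. Residual variance is set
from the analytic budget so each age's achievement has unit variance
before standardization; a configuration whose paths exceed the budget is
rejected rather than silently rescaled. SES loads on the same family
environment (0.7); covariates (sex, age deviation, ten ancestry-PC
stand-ins, chip, batch) are generated independently of all genetic values.

What the generator does **not** emulate: real allele-frequency spectra or
recombination maps, genotyping error and imputation, assortative mating,
sibling interaction effects, rater-specific biases correlated across
domains, and longitudinal dependence of achievement residuals across ages.
Passing recovery tests therefore shows the estimators are correct under
the assumed architecture, not that real data satisfy that architecture.

## Estimators

### Twin models

`fit_ace` fits univariate, common-pathway, and Cholesky ACE models by
full-information normal-theory ML on pair vectors grouped by zygosity,
with expected covariance blocks $[T, A+C; A+C, T]$ (MZ) and
$[T, \tfrac12 A + C; \tfrac12 A + C, T]$ (DZ). Parameters are
unconstrained Cholesky/path coefficients, so all component matrices are
PSD by construction; the common-pathway latent a/c/e direction is
normalized to unit latent variance for identification, and loadings are
free. Optimization uses BFGS with five seeded starts (a method-of-moments
start from the observed cross-twin covariances plus jittered copies) and a
relative tolerance of 1e-12 on the deviance; standard errors, when
requested, come from the numerical Hessian. Intraclass correlations use
double-entered pairs with Fisher-z intervals on the pair count;
opposite-sex and same-sex DZ pairs are pooled. Standardization precedes
fitting, so components are reported as proportions of variance, and
`variance_shares_from_cholesky` reads achievement's genetic shares off the
squared standardized paths of the genetic Cholesky factor.

### LD score regression and the genomic SEM

`ldsc_univariate` regresses $\chi^2_j$ on $\ell_j$ under
$E[\chi^2_j] = a + N h^2 \ell_j / M$ with two-pass heteroskedasticity
weights $1/(1 + N \hat h^2 \ell/M)^2$ (first pass unweighted; weights then
held fixed, including across jackknife replicates). Standard errors are
delete-one-block jackknifes over contiguous SNP blocks (default 50).
`build_genetic_covariance` assembles S from all univariate and bivariate
regressions and estimates V, the sampling covariance of vech(S), from the
cross-entry jackknife using the same blocks for every entry; S and V are
smoothed to the nearest PSD matrix by eigenvalue clipping at 1e-6 only
when needed, with a flag recording that it happened.

`fit_path_model` minimizes the DWLS discrepancy
$(s - \sigma(\theta))' D^{-1} (s - \sigma(\theta))$ with $D =
\mathrm{diag}(V)$, then polishes with Gauss-Newton steps (which converge
quadratically and matter for exact-fit inputs), and reports sandwich
standard errors that restore the off-diagonal information in V. Factor
variances are fixed at 1; the Cog-NonCog covariance is fixed at 0 in the
default subtraction parameterization and freely estimated in the oblique
variant — the source analyses state the factors are specified uncorrelated
yet report a nonzero factor correlation, so both parameterizations are
available and neither is asserted as canonical. Residual variances are
free by default, residual covariances fixed at zero. Identification is
checked by the rank of the implied-moment Jacobian at the start values.

The per-SNP step holds the measurement model fixed and solves, for each
SNP, the two factor-on-SNP regressions by weighted least squares over the
eight SNP-trait genetic covariances $z_{ij}\sqrt{2p_j(1-p_j)/N_i}$. This
two-stage scheme has a closed form (no per-SNP optimization), with
effective sample sizes $1/(A^{-1})_{kk}$, $A = \Lambda' \mathrm{diag}(N)
\Lambda$; when the NonCog loadings collapse (e.g. duplicated cognitive
input) the normal matrix is pseudo-inverted, which sends the orphaned
factor's effects to zero instead of overflowing. Fixing the measurement
model per SNP is an approximation relative to refitting all parameters,
chosen for speed and documented as such.

### Polygenic scores and family designs

`ldpred_inf_weights` implements the infinitesimal-prior shrinkage
$w = (R + \lambda I)^{-1} \hat\beta_{std}$ per block, $\lambda = M/(N
h^2)$, on the standardized-genotype scale; the heritability plugged into
$\lambda$ is the package's own LDSC estimate of the factor by default
(clamped to [0.05, 1] so a noisy small-sample estimate cannot produce a
degenerate shrinkage). Scoring standardizes genotypes by founder moments
and standardizes scores among founders, so MZ co-twins share scores
exactly and DZ co-twin scores correlate 1/2 in expectation for any weight
vector.

Population-level regressions take one twin per family under a fixed seed
rather than clustered standard errors (a clustered variant was considered
and left out of the defaults for comparability between designs). The
within/between decomposition follows the sibling-difference design:
family-mean PGS (between; direct effects plus passive rGE and demography)
and deviation from the family mean (within; direct effects), estimated in
a random-intercept mixed model fitted by ML through `lme4`. The G x SES
models add PGS x SES and PGS x PGS interactions plus
predictor-by-covariate interactions, with BH correction over the
interaction terms.

### Phenotypic machinery

One-factor CFA goes through maximum likelihood on pairwise-complete
correlations (`stats::factanal` under the hood) with the latent variance
fixed at 1, a 1e-4 lower bound on uniquenesses (Heywood cases clamp and
flag rather than fail), Thomson regression scores, and a first-indicator
sign convention. Standardized regressions and BH correction are thin,
contract-checked wrappers over `lm` and `p.adjust`.

## Validation design and its limits

The test suite validates by construction (exact identities: Falconer
algebra, decomposition arithmetic, Cholesky share identities, closed-form
LDpred weights, jackknife-vs-brute-force equality), by parameter recovery
at the study's desk-scale sizes, and by calibration (null rejection rates
near 5%). Stochastic recoveries average three to five seeded replicates so
that the Monte-Carlo error of the check is comfortably inside the stated
tolerance — a single desk-scale replicate of, say, the common-pathway
latent heritability has a sampling SD of about 0.035, which would make a
±0.05 check a coin flip against one unlucky seed.

Two checks deliberately use perfect-weight scores (the simulator's true
genetic values): the recovery of the generating direct effect by the
within-family estimator, and the injected G x SES coefficient. Finite-N
LDpred scores attenuate every regression coefficient by a common
projection factor; ratio-style checks (within approximately half of
population; DZ score correlation 1/2; the rising NonCog age profile) are
attenuation-invariant and therefore use the full LDpred pipeline, while
absolute-recovery checks are run on the unattenuated scale where the
estimator's bias is the only thing being measured.

The developmental-profile check asserts monotonicity of the *median*
NonCog profile over five seeded replicates: per-age increments of the
generating model (0.03-0.04 after attenuation) are comparable to a single
replicate's sampling noise at 1200 families, so a one-replicate
monotonicity test would reflect luck, not the estimator.

Problem sizes used by the default test-and-acceptance runs — 4000+4000
twin pairs for univariate and common-pathway models, M = 5000 / N = 10000
for LD score regression, M = 1500 / N = 6000 / 1200 families for the
five profile replicates, 200 outcome replicates for interaction
calibration — were chosen once as the package's desk-scale study
conditions and are configurable.

## Known limitations

- The twin Cholesky operates on composite/factor scores rather than a
  latent-variable twin model; with reliable indicators the bias is small,
  but latent and composite decompositions are not identical.
- LDSC weights omit the 1/l oversampling factor used by some
  implementations; with block-bounded LD the difference is minor and the
  jackknife covers the remaining misspecification.
- The SNP-step standard errors ignore LD-induced inflation of the
  trait-level z statistics (they are exact under the null and slightly
  anticonservative for strongly tagged SNPs).
- The mixed model uses ML, not REML; with two fixed effects per score and
  thousands of families the variance-component bias is negligible.
- Confidence intervals for twin models are Hessian-based, not
  likelihood-profile; near boundary solutions (A or C at 0) they are
  approximate and the fit is flagged instead.
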