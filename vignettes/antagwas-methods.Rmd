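---
title: "Mapping sexually antagonistic variation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sexually antagonistic variation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(antagwas)
```

# The scientific problem

Sexual antagonism arises when an allele raises fitness in one sex while
lowering it in the other. Because selection then pulls the allele in
opposite directions in males and females, theory predicts such variants
are maintained as balanced polymorphisms, detectable as elevated minor
allele frequencies (MAF), elevated Tajima's D, reduced between-population
differentiation and elevated local linkage disequilibrium (LD).
`antagwas` implements the full inference chain from sex-specific fitness
assays on hemiclonal fly lines (lines whose members share one intact
haploid genome, so a haplotype's fitness can be measured repeatedly in
both sexes) to genome-wide antagonistic variant detection and
population-genomic tests of balancing selection, with a synthetic-data
generator supplying inputs with the statistical structure the analyses
assume.

# Fitness preprocessing and the antagonism index

Vial-level assays are quality-controlled (male competition vials keep all
focal males; female vials need a surviving female and at least 2 eggs —
boundary values are retained because the filters are strict
inequalities), Box-Cox transformed to approximate normality within each
assay block (profile log-likelihood over a lambda grid of [-5, 5], step
0.01; zeros are offset by half the smallest positive value), and scaled
and centred within block. Block averages give one male and one female
fitness value per line. The 45-degree rotation

$$R = \begin{pmatrix} -1/\sqrt2 & -1/\sqrt2 \\ -1/\sqrt2 & 1/\sqrt2 \end{pmatrix}$$

maps the (male, female) plane onto a sexually concordant and a sexually
antagonistic axis. Sign conventions are not fixed by the rotation itself
(association testing is sign-symmetric), so the package labels the
antagonism index positive for female-beneficial/male-detrimental lines,
and negates the concordant component so that "more concordant" means
fitter in both sexes. We scale within block only; whether a second global
scaling should follow the averaging is ambiguous in the field's practice,
and it would not change the rotated axes beyond an affine factor.

# The cross-sex G matrix

The bivariate line model is
$Y_{ijk} = X_{ij} + \epsilon_{ijk}$ with $(X_{mj}, X_{fj})' \sim N(0, G)$,
sex-specific residual variances, and residuals uncorrelated across sexes.
We fit it with a conjugate Gibbs sampler (multivariate-normal line
effects, inverse-Wishart update for $G$, inverse-gamma updates for the
residual variances). Defaults are 13,000 iterations, 3,000 burn-in,
thinning 10, priors IW($\nu = 3$, $V = 0.1 I$) and IG(0.001, 0.001); all
are arguments. Point estimates are posterior means and intervals are 95%
highest-posterior-density intervals. At ~200 lines the posterior is
moderately prior-sensitive, so the package's validation surface is
parameter recovery on synthetic data (bias within Monte-Carlo error),
not reproduction of any particular dataset's point estimates.

Heritability uses the hemiclonal factor 2,
$h^2_i = 2\sigma^2_{G,i}/(\sigma^2_{G,i} + \sigma^2_{R,i})$, because
assayed individuals share only the haploid hemiclonal genome. The
intersexual genetic correlation is
$r_{mf} = \mathrm{Cov}_{G,mf}/\sqrt{\sigma^2_{G,m}\sigma^2_{G,f}}$ (the
standard definition; the geometric-mean denominator is used).

# Kinship, SNP heritability and the mixed-model GWAS

The kinship matrix is $K = ZZ'/c$ with column
$j$ of $Z$ equal to $\sqrt{w_j}(x_j - p_j)[p_j(1-p_j)]^{\alpha/2}$,
$\alpha = -0.25$ by default and $c$ normalising the mean diagonal to 1.
The LD weights $w_j = 1/(1 + \sum_k r^2_{jk})$ (same-arm neighbours
within 100 kb) down-weight SNPs that tag the same signal; they are a
transparent inverse-sum approximation to solver-based LD weighting, and
documented as such. Missing genotypes are mean-imputed per SNP after QC
(<5% missingness by construction of the filters).

SNP heritability maximises the likelihood of
$y \sim N(0, \sigma^2_{SNP} K + \sigma^2_e I)$ on the eigenbasis of $K$;
with a centred phenotype and no fixed effects this equals REML.
Significance comes from 1,000 phenotype-label permutations with the
$+1$-corrected empirical p-value.

The GWAS is EMMAX-style: variance components are estimated once under
the null, each SNP is then a generalised least squares fit after
whitening by $V^{-1/2}$ ($V = \hat\sigma^2_g K + \hat\sigma^2_e I$), with
Wald $\chi^2_1$ p-values. With $K = I$ this collapses exactly onto the
per-SNP ordinary least squares test, which the tests exploit as an
oracle. Effects are reported per minor-allele dose on the haploid 0/1
coding. Empirical p-values use the whitening permutation: $z = A^{-1}y$
(with $A$ the symmetric PSD square root of $V$) has identity covariance,
so its entries are exchangeable; permuting $z$ against the transformed
genotypes turns the mixed model into OLS and the statistic is vectorised
over SNPs x permutations in memory-bounded blocks.

Candidates are SNPs with Benjamini-Hochberg $Q < 0.3$ (the step-up is
implemented directly and oracle-tested); antagonistic windows come from
a 1,000-bp/500-bp-step set-test with $Q < 0.1$. The window test fits
window-kinship plus background-kinship variance components (window SNPs
excluded from the background) and uses the boundary LRT mixture
$0.5\chi^2_0 + 0.5\chi^2_1$, since the tested variance sits on the edge
of its parameter space. The window component has low rank, so the scan
uses the Woodbury identity on the eigenbasis of the full kinship, making
the genome-wide scan linear in window count.

Independent regions come from greedy LD clumping (index p <= 0.00093,
members within 10 kb at $r^2 > 0.4$), and positional clustering is tested
by permuting candidate labels and comparing median adjacent distances,
separately for autosomes and the X chromosome.

# Partitioning and functional analyses

Heritability partitions fit one kinship per SNP class jointly; a class's
observed share $\sigma^2_c/\sum_{c'}\sigma^2_{c'}$ is compared with its
expected share (its fraction of LD-weight mass) by a Z-test with
delta-method SEs, and by a circular-permutation null that rotates the
annotation vector along the genome — preserving annotation order, class
counts and LD — before re-partitioning. Gene-level analyses use extended
gene regions (±5 kb): a chi-squared test of the sex-biased-expression
deficit among antagonistic genes, Wilcoxon and binomial-GLM analyses of
the quantitative degree of sex bias (quadratic term; quartic-vs-quadratic
for a twin-peaks shape), the tissue-specificity index
$\tau = \sum_i (1 - x_i/\max x)/(n-1)$ with sex-limited genes (extreme 5%
quantiles of sex bias) excluded, a quasipoisson GLM for protein-protein
interaction counts, and 2x2 chi-squared overlap tests without continuity
correction.

# Balancing-selection tests

Analysis A asks whether candidate sites are more polymorphic in an
independent population than matched controls. Focal MAF is residualised
on linked selection, controls are stratified into 20 quantile bins of
residual MAF, and each of 1,000 null sets reproduces the candidates' bin
histogram exactly (drawn without replacement within a set). Comparison
MAF applies the allele-matching rule: sites monomorphic in the
comparison population, or polymorphic for different variants, count as
MAF 0 rather than being dropped. The empirical p is one-sided (elevated
polymorphism) by default, matching the directional hypothesis; a
two-sided variant is available. Analysis B is a logistic regression of
polymorphism persistence on absolute effect size with focal MAF and
linked selection as covariates, tested by a 1-df LRT. Analysis C bins
sites in two dimensions (20 residual-MAF x 100 effect-size quantiles),
draws one site per non-empty bin (2,000 on a full grid) and uses
Spearman rank correlation.

Window statistics use the standard Tajima constants, with D undefined at
S = 0; F_ST is Hudson's estimator with sample-size correction,
aggregated over windows as a ratio of sums, residualised on linked
selection and contrasted by Wilcoxon tests (F_ST is far from normal). LD
decay is modelled as $r^2(d) = a e^{-d/b} + c$ by nonlinear least
squares with analytically seeded starts; class differences are tested on
the residuals. Trans-specific sites require shared polymorphism and an
order-free allele-pair match.

# The synthetic-data generator

The generator defines the study conditions rather than adapting to them:

* **Genotypes.** ~200 haploid lines over the five major arms. Founder
  haplotypes carry a latent Gaussian AR(1) along each arm (scale
  `ld_block_bp` = 1 kb) thresholded at per-site target frequencies, and
  lines copy founders with distance-dependent switching — together this
  reproduces the exponential-like r² decay within ~1 kb seen in fly
  panels. Realised MAFs are repaired into the configured range by
  flipping minimal numbers of carriers, so the MAF filter sees the
  intended spectrum.
* **Fitness.** Causal effects (sex-opposed at antagonistic sites,
  sex-aligned at concordant ones) are drawn from a normal and then
  recoloured by an exact linear map so the realised line-level
  (co)variance equals the target G — this makes parameter-recovery tests
  sharp rather than doubly stochastic. Defaults target the study-scale
  conditions $h^2_f = 0.42$, $h^2_m = 0.16$, $r_{mf} = 0.15$ with unit
  residual variances, 5 blocks x 5 vials x 5 flies (25 observations per
  line and sex). Block effects have SD 0.5 (removed by the within-block
  normalisation, so their scale only exercises the code path). Male
  values map to competition proportions by a bounded linear map
  (Box-Cox then recovers the latent scale at lambda near 1); female egg
  counts are rounded log-normal (lambda near 0), so both Box-Cox
  branches are exercised. QC failures are injected at 5% so every filter
  branch runs. The true genetic architecture (number and effect
  distribution of causal loci) is a free parameter of the generator, not
  an empirical claim; defaults use 40 + 40 causal sites.
* **Comparison panels.** Binomial Wright-Fisher drift (default 500
  generations at N = 200 haploids) from the focal frequencies; balanced
  sites get the deterministic pull $p \leftarrow p + s(p_{eq} - p)$
  (one parameter, monotone in s, $p_{eq} = 0.5$) before each binomial
  draw. Haplotypes are sampled site-independently from the final
  frequencies — adequate for frequency-based window statistics, but it
  means comparison-panel LD reflects only what the focal haplotypes
  induce, a stated limitation.
* **Annotations.** Category proportions are multinomial and
  configurable; linked selection is an AR(1) track per arm; sex bias is
  a two-component (unbiased/biased) mixture; tissue expression is gamma
  with a tissue-specific subset; PPI counts are negative binomial.

What passing tests therefore show: the estimators recover the parameters
of data generated under the model's own assumptions, at realistic sizes
and noise levels, and the permutation machinery is calibrated. What they
do not show: robustness to model misspecification present in real data —
assay-scale nonlinearities beyond monotone maps, LD in comparison
panels, non-additive genetic architecture, or annotation error.

# Numerical choices and degenerate inputs

* Variance-ratio profiles are optimised on a log scale over
  $[e^{-25}, e^{25}]$ with the boundary checked explicitly;
  multi-component fits use Nelder-Mead on log variances (reltol 1e-10).
* Tied or constant inputs fail loudly: constant Box-Cox blocks, all-zero
  expression rows, zero-variance PPI counts, monomorphic kinship columns
  and degenerate G configurations (zero variance with nonzero
  covariance) are errors, not silent NAs.
* Empirical p-values always use the +1 correction and can never be 0;
  the smallest attainable value is $1/(n_{perm}+1)$.
* All generators and fits are pure functions of (config, seed); the
  pipeline writes a manifest with MD5 hashes and is bit-identical under
  a repeated seed.
* The matched-null sampler errors (naming the bin) when a residual-MAF
  bin contains candidates but too few controls, rather than silently
  relaxing the match.

# Problem sizes used in validation

The shipped test-suite and acceptance script validate at deliberately
moderated scales chosen as the package's own validation design: G-matrix
recovery at 200 lines x 25 observations/sex over 10–20 replicates; GWAS
calibration on a 200 x 5,000 null panel; whitening-permutation
concordance at 10,000 permutations on a 200 x 2,000 panel (the
production setting would use 100,000); balancing-selection power over
replicates of 2,000-site panels with 200 candidate sites (s = 0.05, 500
generations) against 1,000 matched null sets; and an end-to-end demo at
80 lines x 240 sites. These sizes keep the full validation reproducible
on a laptop while leaving every code path identical to production use.

# Known limitations

* The Gibbs sampler mirrors the animal-model style of analysis but is
  not a drop-in replica of any specific package's priors; estimates at
  small n are prior-sensitive.
* LD weights are an inverse-sum approximation, not a solver-based
  weighting; kinships built with either differ slightly.
* The PCA outlier rule formalises what is usually a visual call
  (|score| > 6 SD on the leading PCs); any fixed threshold is a
  convention.
* Window linked-selection covariates are taken as given; on chromosomes
  lacking them a recombination-rate column can be supplied instead — the
  functions accept any per-window covariate.
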