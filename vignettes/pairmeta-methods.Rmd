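---
title: "Methods and design choices in pairmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in pairmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairmeta)
```

`pairmeta` assembles the standard summary-statistics toolkit for
localising shared genetic signal between an anchor disorder and a series
of partner phenotypes. This vignette explains the statistical models
behind each stage, the parameters that matter, and the choices we made
where the design was genuinely open.

## The gene-based test

For a gene tagged by $k$ SNPs with two-sided p-values $p_1,\dots,p_k$
and LD correlation matrix $R$, each p-value is mapped to a 1-df
chi-square quantile $q_j = [\Phi^{-1}(1-p_j/2)]^2$ and the test
statistic is $T = \sum_j q_j$. The two-sided convention makes the test
direction-free and lets p-value-only tables (no signed Z) enter the gene
layer; signed inputs are simply squared. Under the null, $T$ is
distributed as $\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the
eigenvalues of $R$ — this is Brown's method for combining dependent
p-values, with LD supplying the dependence structure.

**Evaluating the weighted-chi-square tail.** The classical Brown
approximation matches the first two moments of $T$ with a gamma law. We
found it adequate in the distribution body but measurably inaccurate in
the tails that matter for gene discovery: against a $10^6$-draw
Monte-Carlo oracle on AR(1) fixtures it can err by 0.3–0.4 log10 units
around $p \sim 10^{-3}$. The default is therefore a Lugannani–Rice
saddlepoint approximation to the tail of the cumulant generating
function (the same device SKAT uses for its variance-component
quadratic forms), computed in log space so p-values far below double
underflow remain exact on the log scale. Two refinements:

* when all eigenvalues are (numerically) equal the null is exactly a
  scaled chi-square and the exact tail is returned — so with identity LD
  the gene p equals the $\chi^2_k$ tail to machine precision, and a
  single-SNP gene passes its p-value through unchanged;
* the saddlepoint is singular at the distribution mean, so within a
  narrow band around it the two-moment gamma (accurate there) is used
  instead.

The two-moment gamma remains available as `method = "gamma"` and a
Monte-Carlo estimator (`method = "montecarlo"`, add-one estimator, never
exactly zero) serves as the validation oracle. Eigenvalues of $R$ are
clipped at zero with a tolerance of `1e-8`; matrices violating PSD
beyond that tolerance are rejected rather than silently repaired.

**MHC masking and multiple testing.** Genes overlapping
chr6:28,477,797–33,448,354 (hg19, 1-based closed interval, any-overlap
rule) are removed before testing: the region's extreme LD makes genic
attribution there unreliable. The Bonferroni threshold is
$\alpha/n_{\text{tested}}$ with $n_{\text{tested}}$ the genes actually
tested after annotation and masking; at the scale of a full autosomal
protein-coding annotation (18,297 genes) this is the conventional
$2.7\times10^{-6}$. Both the mapped and tested counts are reported in
the result attributes.

**SNP-to-gene annotation** uses 1-based closed intervals with a
symmetric window, default `window_kb = 0` (the MAGMA default); the
window is recorded in the annotation object. Strand is ignored — the
test is strand-agnostic. Alleles are carried but not harmonised across
traits: the meta-analysis operates on gene-level statistics, which are
allele-free, while SNP-level cross-trait operations demand identical
panels and identical a1/a2 orientation and treat any mismatch as an
error, never a silent flip.

## Pairwise meta-analysis

Gene p-values are probit-transformed, $z_i = \Phi^{-1}(1-p_i)$ (computed
from $\log p$ so the transform is exact far into the tail), and combined
as

$$z_{\text{meta}} = \frac{\sqrt{N_1}\,z_1 + \sqrt{N_2}\,z_2}
                         {\sqrt{N_1+N_2}},$$

the sample-size weighted Stouffer statistic. This is the weighting under
which the combined statistic has unit variance for independent inputs,
and it reproduces the published worked examples this package ships
(`inst/extdata/sz_sud_gene_examples.tsv`) to within the 5% relative
slack implied by their 3-significant-figure inputs. Sample sizes are
cases + controls; effective-N weighting is deliberately not the default.
The combination is one-sided on the all-positive gene scale, since gene
p-values are inherently one-sided.

The Cauchy combination (ACAT) companion,
$T = \sum_i w_i \tan((0.5-p_i)\pi)$ with $w_i = N_i/\sum N$, is
insensitive to dependence between the inputs — the relevant failure mode
here being overlapping GWAS samples, which correlate the two gene
p-values and inflate naive Stouffer. Numerical stability: for
$p < 10^{-15}$, $\tan((0.5-p)\pi)$ is replaced by its asymptote
$1/(p\pi)$, and for $T > 10^{15}$ the tail is evaluated as $1/(T\pi)$.

The meta-analysis intersects the two traits' gene universes and reports
the intersected count; the Bonferroni denominator for downstream
filtering refers to that universe.

**The novel-signal filter** retains a gene iff (i)
$p_{\text{meta}} < \alpha_{\text{gene}}$, (ii) both single-trait
p-values are below the nominal level (default 0.05), and (iii) neither
single-trait p-value is below $\alpha_{\text{gene}}$. Condition (iii)
excludes genes driven by one well-powered GWAS alone; condition (ii)
requires genuine support from both. Recurrence of retained genes across
several trait pairs is tallied by `novel_signal_recurrence()`.

## LD score regression

Per trait, weighted least squares of $\chi^2_j$ on the LD score
$\ell_j$ estimates $h^2$ from the slope ($\times M/N$) with the
intercept capturing confounding; across traits, the regression of
$z_{1j}z_{2j}$ on $\ell_j$ estimates the genetic covariance, and its
intercept the cross-trait score-noise correlation
$\rho_e = r_{\text{pheno}} N_s/\sqrt{N_1N_2}$ induced by $N_s$ shared
samples. Heteroskedasticity weights
$1/[\ell_j (1 + N h^2 \ell_j/M)^2]$ are iterated twice.

We deliberately use a *single* weighted regression with a free
intercept rather than the two-step procedure (intercept from
$\chi^2 < 30$ SNPs, then constrained slope) used by some
implementations: at the panel sizes this package targets the two-step
gain is negligible and the single regression is simpler to jackknife
coherently. Uncertainty comes from a delete-one block jackknife over
contiguous SNP blocks (default 200; at least 20 are required), with the
*entire* procedure — both heritabilities, the covariance, the ratio —
re-estimated per left-out block so the SE of $r_g$ reflects all
estimation stages. Contiguous blocks are a proxy for independent genomic
segments; that proxy is exact for the simulator's disjoint LD blocks.

Estimates of $|r_g|$ slightly above 1 are allowed numerically (warned
above 1, flagged strongly above 1.25): the ratio of noisy estimates is
not constrained to the parameter space, and clamping would bias
downstream use. A cross-trait intercept with two-sided $p < 0.01$ is
flagged as "markedly non-zero" — the signal that motivates switching
attention to the Cauchy meta-analysis for that pair.

Multiple-testing across trait pairs is Bonferroni over the configured
pair count — a configuration value recorded in output metadata, not
asserted, since the appropriate family depends on the study design.

## The latent causal variable model

Normalised effects $\alpha_j = z_j/\sqrt{N}$ are rescaled to unit
LD-weighted second moment per trait (weights $1/\ell_j$, which
de-emphasise over-counted high-LD SNPs). The model assumes a single
latent factor with kurtotic per-SNP effects on which the two traits load
as $q_1, q_2$; the effect correlation is $\rho = q_1q_2$ and the excess
cokurtosis statistics

$$k_1 = E[\alpha_1^3\alpha_2] - 3\rho, \qquad
  k_2 = E[\alpha_1\alpha_2^3] - 3\rho$$

have model expectations $\kappa\,q_1^3q_2$ and $\kappa\,q_1q_2^3$, where
$\kappa$ is the latent excess kurtosis. The $-3\rho$ term removes the
Gaussian contribution, so bivariate-normal effects give $k_1 = k_2 = 0$:
the causality signal exists only when effects are kurtotic, which is why
the genetic causality proportion is unidentifiable under Gaussian
architectures.

We parameterise the loadings as $q_1 = |\rho|^{(1-g)/2}$,
$q_2 = |\rho|^{(1+g)/2}$, so $q_1q_2 = |\rho|$ for every $g$ and
$g = \log(q_2/q_1)/\log|\rho|$ is the causality proportion: $g = 1$
makes trait 1's effects project fully onto trait 2 ($q_1 = 1$,
$q_2 = |\rho|$), $g = -1$ the reverse, $g = 0$ symmetric pleiotropy.
The fit is a grid posterior over $g \in \{-1, -0.99, \dots, 1\}$
(resolution 0.01, uniform prior): at each grid point the nuisance
$\kappa$ is profiled out by generalised least squares under the
block-jackknife covariance of $(k_1, k_2)$, and the likelihood is the
bivariate normal density of the observed statistics at their
expectation. The posterior mean and SD give the GCP and its SE; the
reported p is the two-sided Wald test of GCP = 0. This grid-posterior
construction was chosen over the original derivative-based fit because
it is transparent, cannot leave $[-1,1]$, and its accuracy rests on the
simulation-recovery tests in this package rather than numeric identity
with any external implementation — exact moment weighting differs
between implementations and we make no claim of matching one.

Guard rails: $|\rho| < 0.05$ raises an error (the model is
uninformative without genetic correlation); negative $\rho$ is handled
by sign-flipping trait 2 and restoring the sign afterwards (flipping
negates both cokurtosis statistics); a near-singular jackknife
covariance is ridge-regularised with a warning; and when either trait's
heritability Z-score is below 7 the result carries an "interpret
cautiously" warning, reflecting the known sensitivity of cokurtosis
ratios to noisy heritability normalisation.

## Competitive gene-set association

OLS of gene Z-scores on membership plus confounders: gene size (SNP
count), log size, genic minor allele count ($\sum_j 2N_j\,\text{maf}_j$)
and its log — the covariates that absorb the mechanical tendency of
large, variant-dense genes to carry more association signal. The test is
one-sided for enrichment ($\beta > 0$), matching competitive-test
semantics. Covariates are centred and scaled before fitting (the
membership coefficient is invariant to this, but the normal equations
become well conditioned even when MAC is on the $10^5$ scale);
zero-variance covariates are dropped as uninformative and collinear
covariates are dropped with a warning, while a membership column
collinear with the covariates is an error.

Benjamini–Hochberg FDR is applied *within* each collection
(hallmark / canonical / miRNA-target collections are reported
separately in the workflow this package supports); sets below
`min_set_size = 3` after intersection with the analysed universe are
skipped and listed. "Novelty" of a set is operationalised as:
significant (q < `fdr_alpha`) in the meta-analysed run and not
significant in the supplied single-trait run.

## The simulator and what it does (not) emulate

`build_ld_structure()` models the genome as disjoint blocks with AR(1)
correlation $r_{jk} = \rho^{|j-k|}$ — positive definite for
$0 \le \rho < 1$, with LD scores $\ell_j = \sum_k r_{jk}^2$ computable
in closed form. `simulate_pair()` draws per-SNP standardised joint
effects (bivariate normal with correlation $r_g$, or the point-normal
latent architecture with causal proportion `p_causal = 0.1` by default —
small enough to give substantial excess kurtosis, large enough that a
few thousand SNPs carry signal), scales them to $h^2/M$ per SNP, and
forms marginal scores

$$z = \sqrt{N}\,R\beta + \varepsilon,\qquad
  \varepsilon \sim N(0, R),$$

with cross-trait noise correlation
$r_{\text{pheno}}\,N_s/\sqrt{N_1N_2}$ — sample overlap is modelled only
in the noise term, the standard LDSC intercept form, not via
individual-level simulation. Block noise is drawn through a symmetric
PSD square root (eigenvalue clipping at zero with a warning). RNG
substreams are derived per block from the master seed, so adding blocks
never changes earlier blocks.

What the simulator does *not* emulate: realistic human LD maps (block
sizes and $\rho$ are homogeneous), allele-frequency-dependent
architecture (effects are drawn independently of MAF), ancestry
structure, and attenuation from imperfect imputation. Tests passing on
these simulations therefore validate the estimators under their own
generative assumptions; they do not certify behaviour under real-data
pathologies such as long-range LD or stratification.

## Numerical and scale choices in the test-suite

The suite validates stochastic behaviour at desk scale, with sizes
chosen as the smallest that give stable verdicts: genetic-correlation
recovery uses $M = 10{,}000$ SNPs (400 AR(1) blocks of 25,
$\rho = 0.5$), $N = 60{,}000$, 50 replicates; causality-proportion
recovery uses $M = 20{,}000$, $N = 100{,}000$, 25 replicates per
architecture; the gene-test calibration check compares 20 random AR(1)
fixtures against a $10^6$-draw Monte-Carlo oracle; type-I error checks
use 20,000 single-SNP genes. The narrow LD-score range of small AR(1)
panels makes single-replicate LDSC estimates noisy (intercept and slope
are nearly collinear when $\ell$ spans only $[1.3, 2]$); recovery is
therefore asserted on replicate means, and demonstrations use
$\rho = 0.8$ blocks where the spread is wider.

## Known limitations

* LD for gene tests is supplied as an explicit block structure; there is
  no reference-panel reader for arbitrary external LD matrices beyond
  the AR(1) generator parameters accepted by the pipeline config.
* The LDSC implementation is the single-regression variant; intercepts
  are free, which costs a little efficiency relative to constrained
  two-step fits on very large panels.
* The LCV fit assumes a single latent factor and cannot model mediators
  or confounders; like all such models it is bivariate by construction.
* Only two-trait meta-analysis is implemented; multi-trait effect
  estimation (MTAG-style) and heterogeneity statistics are out of scope.
* X-chromosome genes are excluded at the annotation layer.
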