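---
title: "Methods: comparing two closely related populations with popstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing two closely related populations with popstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popstrat)
```

# Scope

`popstrat` quantifies the degree of stratification between two closely
related populations (the motivating case is two national dairy-cattle
populations genotyped on a common 50K SNP chip, with deregressed breeding
values from routine evaluation as pseudo-phenotypes). The pipeline has six
analysis stages — marker QC and intersection, linkage-disequilibrium decay,
SNP-BLUP marker effects, base-population allele frequencies, window-based
regional tests, and a bivariate cross-population (co)variance fit — plus a
synthetic-data generator that emulates the study design so that every stage
can be exercised and validated without access to proprietary evaluation
data.

# Marker QC and intersection

Each population's panel is filtered on minor allele frequency
(default `>= 0.01`, computed from non-missing genotypes and folded to the
minor side) and call rate (default `>= 0.90`); both thresholds are
inclusive, and a SNP with no non-missing call fails the call-rate criterion
rather than producing a divide-by-zero MAF. Filtering is applied per
population *first*, and the marker lists are intersected afterwards — the
order matters, and this is the order the study design prescribes. When
allele labels are available, the intersection harmonizes the counted allele
to the first panel's orientation by sign-flipping genotype columns coded on
the opposite allele; a pair of irreconcilable labels drops the SNP with a
warning. Strand-ambiguous (A/T, C/G) resolution is out of scope; the
generator never produces it.

Missing genotypes are set to 0 — the heterozygote code — before entering
the SNP-BLUP design matrix. This is this package's choice (the source
material is silent on the point); at the ~1% missingness the generator
defaults to, its effect on effect estimates is negligible.

# Linkage disequilibrium

LD between two loci is the squared allelic correlation
$r^2 = D^2 / \bigl(p_1(1-p_1)\,p_2(1-p_2)\bigr)$, with
$D = f_{AB} - p_1 p_2$ computed from phased haplotypes. Phasing itself is
out of scope: the pipeline consumes a phased panel when one exists (the
generator always provides one), and otherwise falls back on a two-locus EM
(`em_two_locus_freqs()`) that maximizes the genotype likelihood over the
four haplotype frequencies; only double heterozygotes are phase-ambiguous,
so the EM reproduces direct counting in their absence.

Same-chromosome pairs up to 5 Mbp apart are binned into the nine distance
intervals `[0, 0.025), [0.025, 0.05), [0.05, 0.075), [0.075, 0.12),
[0.12, 0.2), [0.2, 0.5), [0.5, 1.5), [1.5, 3), [3, 5]` (Mbp; all half-open
except the closed last one), and the decay regression
$\bar r^2_i = \alpha + \beta/\sqrt{d_i}$ is fitted by OLS with $d_i$ the
*upper* boundary of interval $i$. Using the upper boundary rather than the
midpoint follows the stated definition of the source design; the choice
changes $\alpha$ and $\beta$ individually but not the between-population
comparison, which is the quantity of interest. Under this model the
predicted decrease in mean LD between two distances is
$\beta(1/\sqrt{d_1} - 1/\sqrt{d_2})$, so the ratio of two populations'
decreases over a common distance pair equals $\beta_1/\beta_2$ — the
"decays $x$ times faster" summary is a pure statement about the betas.

Per-interval population differences are tested with a paired $t$-test on
per-SNP-pair differences $r^2_A - r^2_B$ (pairing key: the ordered SNP-id
pair), two-sided with $n-1$ degrees of freedom. A window with identical
records returns $t = 0$, $p = 1$; a constant nonzero difference has zero
within-pair variance and is reported with $p = 0$ and a `degenerate` flag
rather than an error.

# SNP-BLUP with Gauss–Seidel and residual update

Marker effects per population and trait come from the weighted ridge
model $y = Xb + Zg + e$ where $y$ holds deregressed breeding values, $b$ is
a general mean, $Z$ is the genotype design matrix coded $-1/0/+1$
(deliberately *not* frequency-centred: the coding is kept exactly as the
model was stated, and the general mean absorbs the resulting offset),
$g \sim N(0, I\,\sigma^2_a/n_{\text{snp}})$ and
$e \sim N(0, D\,\sigma^2_e)$ with $D = \mathrm{diag}(1/\text{EDC}_i)$ —
records from bulls with many effective daughter contributions carry
proportionally smaller residual variance. $\sigma^2_a$ is the trait's total
additive genetic variance, taken as an input (from the routine evaluation
in the real design, from the generator's truth in synthetic runs);
$n_{\text{snp}}$ is the post-intersection marker count and is exposed as a
configuration value. The residual variance $\sigma^2_e$ is likewise an
input: it is not published for the real traits, so synthetic runs use the
generator's value and real-data runs must supply one.

The mixed-model equations are solved by iteration on data: one sweep
updates the mean and then every SNP effect in map order, and the residual
vector $e = y - Xb - Zg$ is maintained incrementally after *every*
single-effect update (the "residuals update" that makes each effect update
$O(n)$). The inner loop is compiled (Rcpp). Convergence is declared when
the relative L2 change of the full solution vector over a sweep drops
below `tol` (default `1e-10`; the update order and criterion are this
package's choices). A zero-variance genotype column is confounded with the
mean and its effect is pinned at 0. The test suite checks the solver
against a dense direct solve of the MME up to 200 animals x 500 SNPs and
verifies that the incrementally maintained residual never drifts from a
from-scratch recomputation. Note that strong LD makes the system poorly
conditioned and Gauss–Seidel correspondingly slow — thousands of sweeps at
tight tolerances — which is the main cost of a pipeline run.

# Base-population allele frequencies

The per-SNP additive variance $\hat a = 2\hat g^2 p(1-p)$ requires allele
frequencies of the *base* population — the non-genotyped founders — rather
than of the genotyped animals, which are several generations of selection
and drift downstream. Gene-content BLUP treats the gene content (0/1/2
copies of the counted allele) of genotyped animals as a quantitative trait
with pedigree covariance: $gc = \mathbf{1}\mu + u + e$,
$u \sim N(0, A\sigma^2_u)$, $\lambda = \sigma^2_e/\sigma^2_u$. The fixed
mean estimates twice the founder allele frequency, so
$\hat p_{\text{base}} = \hat\mu/2$, clamped to $[0,1]$ because BLUP can
overshoot slightly. $A^{-1}$ is assembled directly from the pedigree by
Henderson's rules; inbreeding is ignored, which is exact for the shallow
non-inbred pedigrees the generator builds and a standard approximation
otherwise. The default $\lambda = 0.01$ treats gene content as almost
perfectly heritable (it is transmitted mechanically, so the "residual" only
absorbs Mendelian sampling not captured by $A$); as $\lambda \to \infty$
the estimator degenerates to half the sample mean of the genotyped animals,
a limit the tests pin down. Frequencies are estimated per SNP
independently, but the MME coefficient matrix depends only on the pedigree
and $\lambda$, so one sparse Cholesky factorization serves all SNPs as a
multi-right-hand-side solve.

# Regional window tests

The genome is tiled into windows of a fixed bp length anchored at
coordinate 0 on each chromosome (the anchor is a package choice). For each
window with at least two SNPs, the statistic
$$t^i = \frac{\bar a^i_{A} - \bar a^i_{B}}
{\sqrt{(\hat\sigma^{2i}_{A} + \hat\sigma^{2i}_{B})/N_{SNP_i}}}$$
compares the mean per-SNP additive variances between populations, with
$\hat\sigma^{2i}_x$ the within-window variance of those per-SNP values.
Two-sided p-values use $2N_{SNP_i} - 2$ degrees of freedom — the statistic
pools the two populations' variances with a common $N$, so the pooled-df
form is the consistent choice (Welch would not match the printed
denominator). The hypothesis concerns "average SNP effects"; the variance
formula the design defines operates on the additive variances $\hat a$, so
the test defaults to $\hat a$ and a switch (`statistic = "effect"`) tests
raw $\hat g$ instead. Windows with fewer than two SNPs are excluded from
both testing and the FDR family. Multiple testing is controlled per window
length and trait with Benjamini–Hochberg at a default maximum FDR of 10%,
and the scan is repeated for window lengths 0.3–1.5 Mbp in 0.1-Mbp steps,
reporting the proportion of significant windows per length — single-window
identities are unstable across lengths, the proportion pattern is the
reproducible signal.

# Cross-population SNP (co)variance

The two populations' effect estimates are joined per SNP and modelled as
$\hat g = P\mu + Zq + \varepsilon$ with one mean per population,
$q \sim N(0, I \otimes G)$ for a 2x2 between-population (co)variance matrix
$G$, and a single shared residual variance $\sigma^2_\varepsilon$
(population-specific residuals would be wholly confounded with $G$'s
diagonal). Estimation is EM-REML on the per-SNP sufficient statistics, with
a monotone restricted likelihood and projection to the nearest PSD matrix
if an update leaves the cone. The genetic correlation is
$\rho_g = G_{12}/\sqrt{G_{11}G_{22}}$ and the variance ratio $G_{22}/G_{11}$
(second population over first).

**A genuine identifiability limit.** With exactly one observation per SNP
per population the likelihood depends on $(G, \sigma^2_\varepsilon)$ only
through $V = G + \sigma^2_\varepsilon I$. The covariance $G_{12} = V_{12}$
and the marginal totals $V_{11}, V_{22}$ are therefore identified, but the
split of each diagonal into genetic and residual parts is not: every
$\sigma^2_\varepsilon \in [0, \lambda_{\min}(V)]$ yields an identical
likelihood, and *no* estimator can recover the split from these data. EM
converges to a point on that ridge determined by its starting values;
`fit_bivariate()` documents and fixes the convention (equal split of the
sample covariance). Consequently $\rho_g$ and the variance ratio inherit
the convention: they are reproducible and comparable across traits run
through the same code, but their absolute level should not be
over-interpreted. The ridge collapses only where the sample covariance is
singular — e.g. two identical effect vectors force
$\sigma^2_\varepsilon \to 0$ and $\rho_g \to 1$, which the tests verify.
The package's validation therefore asserts recovery only for the identified
quantities ($G_{12}$, the marginal totals, and their implications) and
treats the full decomposition as a known limitation.

# The synthetic-data generator

`simulate_study()` draws, from one seed, everything the pipeline consumes.
Design choices and defaults:

* **Base frequencies** uniform on $[0.05, 0.95]$ — the flat spectrum of
  chip-ascertained markers, not a neutral site-frequency spectrum.
* **Drift**: each population's frequencies are Balding–Nichols,
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F = 0.01$, which implies a
  cross-population base-frequency correlation near 0.97 at this frequency
  spectrum — the level of agreement the real comparison reports.
* **LD**: founder haplotypes come from a first-order copying process — a
  latent Gaussian AR(1) along each chromosome with adjacent-SNP correlation
  $\exp(-\text{rate} \cdot d_{bp})$, thresholded at each SNP's frequency.
  A Markovian process was chosen over a coalescent simulator because it is
  desk-scale and the decay rate is directly tunable; the implied $r^2(d)$
  curve is *not* exactly $\alpha + \beta/\sqrt d$, so recovery tests
  compare fitted betas against the generator's *implied* betas
  (`implied_decay_beta()`, computed from bivariate-normal orthant
  probabilities plus the first-order finite-sample inflation of $r^2$),
  and compare populations against each other rather than against absolute
  targets. Default rates are `6e-8`/bp and `1.02e-7`/bp — a 1.7-fold
  difference, the factor reported between the two real populations, with
  the second population decaying faster. The rates sit in the weak-decay
  regime (rate x 5 Mbp of order one) where the fitted beta scales roughly
  linearly with the rate; the price is that absolute $r^2$ is higher and
  longer-ranged than on a real 50K panel. Because the copying process is
  Markovian the fitted beta *ratio* is mildly attenuated toward 1 relative
  to the rate ratio (about 1.4 observed at the default rates); the
  between-population ordering is preserved essentially always, which is
  what the acceptance checks assert.
* **Pedigree**: two non-genotyped generations (founders plus one) above a
  genotyped final generation, random mating without selfing,
  whole-chromosome transmission (no recombination). This matches the
  base-population definition used by the gene-content BLUP stage; the
  recovery target for base frequencies is the realized founder-pool
  frequency.
* **Effects and proofs**: per-trait true SNP effects are bivariate normal
  across populations with configurable correlation and variances (defaults:
  a production-like trait with correlation 0.9 and equal variances, and an
  udder-health-like trait with correlation 0.3 and a 1:2 variance ratio —
  a stylized version of "similar selection history" vs "divergent
  selection history"). Proofs are $y = \mu + Zg_{\text{true}} + e$ with
  $e_i \sim N(0, \sigma^2_e/\text{EDC}_i)$ and EDC log-normal
  (meanlog 4, sdlog 0.7, a spread resembling progeny-tested bulls; purely a
  fixture choice). The total additive variance handed to SNP-BLUP is
  `n_snp * effect_var`, making the prior per-SNP variance equal the
  generating one.

What passing tests on this generator do *not* show: realism of absolute LD
levels, recombination, mutation, selection, ascertainment beyond the
frequency bound, or the behaviour of deregression itself (proofs are
generated directly from the weighting model, not deregressed from EBVs).

# Numerical choices

* Gauss–Seidel convergence: relative L2 change of the solution vector,
  default `1e-10`; pipeline runs use `1e-8` where only downstream summaries
  are needed. Problem sizes in the tests (up to 200 x 500 for the
  solver-oracle comparison, 1,000–2,000 SNPs for LD recovery, m = 10,000
  for the bivariate fit, 20 replicates for stochastic checks) were chosen
  as the smallest designs at which the checked quantities stabilize.
* The two-locus EM starts at linkage equilibrium and stops on a `1e-10`
  max-change; non-convergence returns the last iterate with a warning.
* `bh_fdr()` delegates to `stats::p.adjust(method = "BH")`; OLS fits
  delegate to `stats::lm`; the sparse MME uses the Matrix package. The
  Gauss–Seidel solver, Henderson rules, gene-content BLUP assembly,
  two-locus EM and the EM-REML are authored here.
* Windows and LD bins use half-open intervals; the last LD bin `[3, 5]` is
  closed per its stated bracket notation. Genome coordinates are 0-based
  half-open internally and 1-based only at the PLINK boundary.
* Degenerate inputs: all-missing SNPs fail QC rather than dividing by
  zero; monomorphic loci yield `NA` r2 and leave the pair out of the bins;
  single-SNP windows are skipped with their absence logged in the window
  count; a singular total covariance in the bivariate fit stops at the
  boundary with a flag.

# Known limitations

* The bivariate decomposition is set-identified, not point-identified (see
  above); only $G_{12}$ and the marginal totals are estimable.
* The paired LD test treats SNP-pair differences as independent, which LD
  itself violates; p-values are anti-conservative to an unknown degree, as
  in the original design.
* The window t-test applies a normal-theory test to per-SNP additive
  variances, which are skewed; under a global null the symmetry of the
  two samples keeps the type-I error near nominal (verified by
  simulation), but heavy tails at very small window sizes warrant caution.
* Gene-content BLUP ignores inbreeding in $A^{-1}$ and estimates each SNP
  independently.
* The command-line surface is the R API plus `scripts/acceptance.R`; the
  package is a library, not a shell tool.
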