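# popstrat

Tools for assessing the degree of stratification between two closely
related populations genotyped on a common SNP panel — the motivating case
is a pair of national Holstein-Friesian bull populations with deregressed
breeding values (dEBVs) and effective daughter contributions (EDCs) from
routine genetic evaluation. Because such evaluation data are proprietary,
the package ships a seeded synthetic-data generator that reproduces the
study design (two populations drifted from a common base, population-
specific linkage-disequilibrium decay, cross-population correlated SNP
effects, EDC-weighted proofs), so the whole pipeline is testable end to
end.

## What it computes

For populations *A* and *B* sharing a marker map:

1. **QC + intersection** — per-population filtering on minor allele
   frequency (≥ 0.01) and call rate (≥ 0.90), then intersection of the
   surviving marker lists with allele-orientation harmonization.
2. **LD decay** — pairwise `r² = D² / (p₁(1−p₁)p₂(1−p₂))` from phased
   haplotypes (or a two-locus EM fallback), averaged over nine distance
   bins up to 5 Mbp, and the decay regression `r̄²ᵢ = α + β/√dᵢ` per
   population with `d` the bin's upper boundary (Mbp). The ratio of
   predicted LD decreases over a common distance pair equals `β_A/β_B`.
   Paired t-tests compare the populations' mean r² per bin.
3. **SNP-BLUP** — random marker effects per population and trait from
   `y = Xb + Zg + e`, `g ~ N(0, I·σ²ₐ/n_snp)`, `e ~ N(0, D·σ²ₑ)` with
   `D = diag(1/EDC)`, solved by Gauss–Seidel iteration on data with
   residual update (Rcpp core, checked against a dense MME solve).
4. **Base-population frequencies** — gene-content BLUP: gene content of
   genotyped animals modelled with pedigree covariance (Henderson's
   `A⁻¹`); half the estimated fixed mean is the founder allele frequency.
5. **Regional tests** — per-SNP additive variances `â = 2ĝ²p(1−p)` are
   averaged in genome windows (lengths 0.3–1.5 Mbp) and compared between
   populations with `tⁱ = (āᵢ_A − āᵢ_B)/√((σ̂²ᵢ_A+σ̂²ᵢ_B)/N_SNPᵢ)`,
   with Benjamini–Hochberg FDR control at 10% per window length.
6. **Cross-population (co)variance** — a bivariate EM-REML fit of
   `ĝ = Pμ + Zq + ε`, `q ~ N(0, I⊗G)`, yielding the 2×2 SNP-effect
   (co)variance `G`, the genetic correlation `ρ_g = G₁₂/√(G₁₁G₂₂)` and the
   variance ratio `G₂₂/G₁₁`. (Note: with one observation per SNP and
   population only `G₁₂` and the marginal totals are point-identified; see
   the methods vignette.)

## Worked example

```r
library(popstrat)

cfg   <- sim_config(n_animals = 200, n_snp = 1000, n_chrom = 3, seed = 1)
study <- simulate_study(cfg)           # two populations, pedigree, proofs
run   <- run_full_analysis(study, snp_blup_tol = 1e-8)
print(run)
```

```
qc: 1000 / 1000 SNPs retained (PL: 1000, DE: 1000 before intersection)
ld: beta PL=0.0174 DE=0.0238 (ratio 1.37)
basefreq: cross-population correlation 0.956 (slope 0.973)
crosspop prod: rho_g=0.427 ratio=1.02
crosspop scs: rho_g=0.134 ratio=4.99
popstrat run
  markers: 1000 after QC + intersection
  LD decay beta: PL=0.0174 DE=0.0238 (ratio 1.37)
  base-frequency agreement: r=0.956 slope=0.973
  prod: rho_g=0.427, variance ratio=1.02, signif. windows (mean over lengths)=0.3%
  scs: rho_g=0.134, variance ratio=4.99, signif. windows (mean over lengths)=12.0%
```

Reading the output: the second population was generated with 1.7× faster
LD decay, and its fitted decay coefficient β is correspondingly larger
(the fitted ratio is attenuated below 1.7 by the generator's threshold
model — see the vignette). Base-population allele frequencies estimated
independently from the two pedigrees agree at r ≈ 0.96, reflecting the
common base they drifted from (F = 0.01). The production-like trait
(`prod`, true cross-population effect correlation 0.9, equal variances)
shows almost no significant regional differences, while the udder-health-
like trait (`scs`, correlation 0.3, 1:2 variance ratio) shows many and a
larger fitted variance ratio — the qualitative signature of traits under
similar vs divergent selection histories.

Per-stage results live in the returned object (`run$ld`, `run$effects`,
`run$base_freqs`, `run$window_scan`, `run$crosspop`), and
`run_full_analysis(..., out_dir = "out")` writes every stage as TSV.

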