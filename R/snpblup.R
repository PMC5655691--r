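#' Variance specification for SNP-BLUP
#'
#' The random SNP effects are assigned the prior `g ~ N(0, I sigma2_a /
#' n_snp)`: the total additive genetic variance of the trait divided equally
#' over markers. Residuals are `e ~ N(0, D sigma2_e)` with `D` the diagonal
#' matrix of reciprocals of the effective daughter contributions.
#'
#' @param sigma2_a total additive genetic variance of the trait (trait
#'   units squared).
#' @param sigma2_e residual variance (trait units squared).
#' @param n_snp number of markers sharing `sigma2_a`.
#' @return An object of class `variance_spec`.
#' @export
variance_spec <- function(sigma2_a, sigma2_e, n_snp) {
  stopifnot(sigma2_a > 0, sigma2_e > 0, n_snp >= 1)
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 n_snp = as.integer(n_snp),
                 sigma2_g = sigma2_a / n_snp),
            class = "variance_spec")
}

#' Estimate random additive SNP effects by weighted SNP-BLUP
#'
#' Solves the mixed model `y = X b + Z g + e` where `y` holds deregressed
#' breeding values, `b` is a general mean, `Z` is the -1/0/+1 genotype design
#' matrix, `g ~ N(0, I sigma2_a / n_snp)` and `e ~ N(0, D sigma2_e)` with
#' `D = diag(1 / edc)`. The mixed model equations are solved by Gauss-Seidel
#' iteration on data with residual update: the residual vector
#' `e = y - X b - Z g` is maintained incrementally after every single-effect
#' update. Missing genotypes are set to 0 (the heterozygote code) before
#' solving. SNP columns with zero variance across animals have their effect
#' fixed at 0.
#'
#' @param panel a [genotype_panel()].
#' @param proofs a [deregressed_proofs()] object; animals must be present in
#'   the panel (order may differ).
#' @param var a [variance_spec()]; `var$n_snp` need not equal the panel's
#'   SNP count (the divisor of `sigma2_a` is a modelling choice).
#' @param tol relative L2 change of the full solution vector below which the
#'   solver stops.
#' @param max_iter maximum number of full sweeps.
#' @return An object of class `snp_effect_set`: `snp_ids`, `g_hat`,
#'   `mu_hat`, `residuals`, `converged`, `n_iter`, plus map info and labels.
#' @export
solve_snp_blup <- function(panel, proofs, var, tol = 1e-10, max_iter = 20000L) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(proofs, "deregressed_proofs"),
            inherits(var, "variance_spec"))
  idx <- match(proofs$animal_ids, panel$animal_ids)
  if (anyNA(idx)) {
    stop("proof animals absent from panel: ",
         paste(head(proofs$animal_ids[is.na(idx)], 5L), collapse = ", "))
  }
  Z <- panel$genotypes[idx, , drop = FALSE]
  Z[is.na(Z)] <- 0L
  storage.mode(Z) <- "double"
  colsd <- apply(Z, 2L, function(z) max(z) - min(z))
  active <- colsd > 0
  w <- proofs$edc / var$sigma2_e          # R^{-1} diagonal
  shrink <- 1 / var$sigma2_g              # G^{-1} diagonal = n_snp / sigma2_a
  sol <- snpblup_gs_cpp(Z, proofs$y, w, shrink, tol, as.integer(max_iter),
                        active)
  if (!sol$converged) {
    warning("SNP-BLUP Gauss-Seidel did not converge in ", max_iter, " sweeps")
  }
  structure(
    list(
      population_id = panel$population_id, trait = proofs$trait,
      snp_ids = panel$snp_ids, chrom = panel$chrom, pos_bp = panel$pos_bp,
      g_hat = setNames(as.numeric(sol$g), panel$snp_ids),
      mu_hat = sol$mu, residuals = as.numeric(sol$e),
      converged = sol$converged, n_iter = sol$n_iter
    ),
    class = "snp_effect_set"
  )
}

#' @export
print.snp_effect_set <- function(x, ...) {
  cat(sprintf("snp_effect_set '%s'/'%s': %d SNPs, mu_hat=%.4g, %s after %d sweeps\n",
              x$population_id, x$trait, length(x$g_hat), x$mu_hat,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Per-SNP additive variance contribution
#'
#' `a = 2 g^2 p (1 - p)`: the additive genetic variance explained by a
#' marker with allele substitution effect `g` segregating at frequency `p`
#' (typically the base-population frequency). Vectorized over SNPs.
#'
#' @param g_hat estimated SNP effect(s).
#' @param p allele frequency (or frequencies) in `[0, 1]`.
#' @return Additive variance contribution(s), zero at `p = 0` or `p = 1`.
#' @export
snp_additive_variance <- function(g_hat, p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * g_hat^2 * p * (1 - p)
}

#' Write an SNP effect set with additive variances as TSV
#'
#' @param eff a `snp_effect_set`.
#' @param base_freqs a `base_freq_set` supplying per-SNP frequencies.
#' @param file output path.
#' @export
write_effects <- function(eff, base_freqs, file) {
  p <- base_freqs$p_base[match(eff$snp_ids, base_freqs$snp_ids)]
  data.table::fwrite(
    data.table::data.table(
      snp_id = eff$snp_ids, chrom = eff$chrom, pos_bp = eff$pos_bp,
      g_hat = unname(eff$g_hat),
      additive_variance = unname(snp_additive_variance(eff$g_hat, p))
    ),
    file, sep = "\t"
  )
  invisible(file)
}
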