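#' The nine distance intervals used for LD binning
#'
#' Half-open Mbp intervals `[0, 0.025), [0.025, 0.05), [0.05, 0.075),
#' [0.075, 0.12), [0.12, 0.2), [0.2, 0.5), [0.5, 1.5), [1.5, 3)` and the
#' closed last interval `[3, 5]`. The `d_upper` column (upper boundary, Mbp)
#' is the distance covariate of the decay regression.
#'
#' @return A data.frame with columns `lower`, `upper`, `d_upper`, `label`.
#' @export
ld_bins <- function() {
  lower <- c(0, 0.025, 0.05, 0.075, 0.12, 0.2, 0.5, 1.5, 3)
  upper <- c(0.025, 0.05, 0.075, 0.12, 0.2, 0.5, 1.5, 3, 5)
  data.frame(
    lower = lower, upper = upper, d_upper = upper,
    label = paste0("[", lower, "-", upper, ifelse(upper == 5, "]", ")")),
    stringsAsFactors = FALSE
  )
}

#' Squared allelic correlation (r2) between two loci from phased haplotypes
#'
#' `r2 = D^2 / (p1 (1 - p1) p2 (1 - p2))` with `D = freq(AB) - pA * pB`, the
#' deviation of the two-locus haplotype frequency from linkage equilibrium.
#' The result is clamped to `[0, 1]` against rounding.
#'
#' @param hap_a,hap_b equal-length binary (0/1) allele vectors, one entry per
#'   haplotype.
#' @return r2 in `[0, 1]`, or `NA` when either locus is monomorphic in the
#'   sample (r2 undefined).
#' @export
pair_r2 <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b))
  p1 <- mean(hap_a)
  p2 <- mean(hap_b)
  den <- p1 * (1 - p1) * p2 * (1 - p2)
  if (den <= 0) return(NA_real_)
  D <- mean(hap_a * hap_b) - p1 * p2
  min(max(D * D / den, 0), 1)
}

#' All pairwise LD records within a distance limit
#'
#' Enumerates same-chromosome SNP pairs with `0 < distance <= max_dist_bp`
#' and computes r2 from phased haplotypes (vectorized evaluation of the same
#' haplotype-frequency formula as [pair_r2()]). Pairs involving a
#' monomorphic locus get `NA` r2 and are excluded from binning downstream.
#'
#' @param hpanel a [haplotype_panel()].
#' @param max_dist_bp maximum pair distance in bp (default 5 Mbp, the upper
#'   end of the last binning interval).
#' @return A data.frame with columns `snp_i`, `snp_j`, `chrom`,
#'   `distance_bp`, `r2`.
#' @export
ld_records <- function(hpanel, max_dist_bp = 5e6) {
  stopifnot(inherits(hpanel, "haplotype_panel"))
  out <- vector("list", length(unique(hpanel$chrom)))
  k <- 0L
  for (cc in unique(hpanel$chrom)) {
    sel <- which(hpanel$chrom == cc)
    if (length(sel) < 2L) next
    H <- hpanel$haplotypes[, sel, drop = FALSE]
    pos <- hpanel$pos_bp[sel]
    ids <- hpanel$snp_ids[sel]
    nh <- nrow(H)
    p <- colMeans(H)
    # freq(AB) for every pair, then D and r2 in one shot
    PAB <- crossprod(H) / nh
    D <- PAB - tcrossprod(p)
    den <- tcrossprod(p * (1 - p))
    r2 <- D * D / den
    r2[den <= 0] <- NA_real_
    r2 <- pmin(pmax(r2, 0), 1)
    idx <- which(upper.tri(r2), arr.ind = TRUE)
    dist <- pos[idx[, 2L]] - pos[idx[, 1L]]
    keep <- dist > 0 & dist <= max_dist_bp
    idx <- idx[keep, , drop = FALSE]
    k <- k + 1L
    out[[k]] <- data.frame(
      snp_i = ids[idx[, 1L]], snp_j = ids[idx[, 2L]], chrom = cc,
      distance_bp = pos[idx[, 2L]] - pos[idx[, 1L]],
      r2 = r2[idx], stringsAsFactors = FALSE
    )
  }
  if (k == 0L) {
    return(data.frame(snp_i = character(), snp_j = character(),
                      chrom = character(), distance_bp = integer(),
                      r2 = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(k)])
}

#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Fallback for panels without phased haplotypes: maximizes the two-locus
#' likelihood over (p_AB, p_Ab, p_aB, p_ab) by expectation-maximization. Only
#' double heterozygotes are phase-ambiguous; all other genotype pairs
#' contribute exact haplotype counts, so in their absence the EM reproduces
#' direct counting in one step.
#'
#' @param geno_a,geno_b genotype columns coded -1/0/+1 (NA allowed; pairs with
#'   a missing genotype at either locus are ignored).
#' @param tol convergence tolerance on the max absolute frequency change.
#' @param max_iter maximum EM iterations.
#' @return Named numeric vector `c(pAB, pAb, paB, pab)` summing to 1, with
#'   attributes `converged` and `n_iter`.
#' @export
em_two_locus_freqs <- function(geno_a, geno_b, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(geno_a) & !is.na(geno_b)
  ga <- geno_a[ok] + 1L  # counted-allele dosage 0/1/2
  gb <- geno_b[ok] + 1L
  n <- length(ga)
  if (n == 0L) stop("no complete genotype pairs")
  dh <- ga == 1L & gb == 1L    # double heterozygotes: phase unknown
  sga <- ga[!dh]; sgb <- gb[!dh]
  # With at least one locus homozygous the pairing of alleles into haplotypes
  # is forced and the AB count per individual is dosage1 * dosage2 / 2.
  cAB <- sum(sga * sgb) / 2
  cAb <- sum(sga) - cAB
  caB <- sum(sgb) - cAB
  cab <- 2L * length(sga) - cAB - cAb - caB
  ndh <- sum(dh)
  tot <- 2 * n
  # init from allele frequencies (linkage-equilibrium start)
  pA <- sum(ga) / tot
  pB <- sum(gb) / tot
  f <- c(pAB = pA * pB, pAb = pA * (1 - pB), paB = (1 - pA) * pB,
         pab = (1 - pA) * (1 - pB))
  f <- pmax(f, 1e-12); f <- f / sum(f)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step: split double heterozygotes between AB/ab and Ab/aB phases
    w <- unname(f["pAB"] * f["pab"])
    v <- unname(f["pAb"] * f["paB"])
    pr <- if (w + v > 0) w / (w + v) else 0.5
    nAB <- cAB + ndh * pr
    nab <- cab + ndh * pr
    nAb <- cAb + ndh * (1 - pr)
    naB <- caB + ndh * (1 - pr)
    fn <- c(pAB = nAB, pAb = nAb, paB = naB, pab = nab) / tot
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) warning("two-locus EM did not converge in ", max_iter, " iterations")
  attr(f, "converged") <- converged
  attr(f, "n_iter") <- it
  f
}

#' r2 between two loci from unphased genotypes via the two-locus EM
#'
#' @inheritParams em_two_locus_freqs
#' @return r2 in `[0, 1]` or `NA` for a monomorphic locus.
#' @export
pair_r2_em <- function(geno_a, geno_b, tol = 1e-10, max_iter = 1000L) {
  f <- em_two_locus_freqs(geno_a, geno_b, tol = tol, max_iter = max_iter)
  p1 <- f[["pAB"]] + f[["pAb"]]
  p2 <- f[["pAB"]] + f[["paB"]]
  den <- p1 * (1 - p1) * p2 * (1 - p2)
  if (den <= 0) return(NA_real_)
  D <- f[["pAB"]] - p1 * p2
  min(max(D * D / den, 0), 1)
}

#' Bin LD records into the nine distance intervals
#'
#' Each record is assigned to exactly one interval by `distance_bp / 1e6`;
#' all intervals are half-open `[lower, upper)` except the last, which is
#' closed `[3, 5]`. Pairs beyond 5 Mbp and pairs with undefined (NA) r2 are
#' discarded. Empty bins are reported with `n_pairs = 0` and `NA` mean.
#'
#' @param records a data.frame as returned by [ld_records()].
#' @return A data.frame with one row per interval: `label`, `lower`, `upper`,
#'   `d_upper`, `n_pairs`, `mean_r2`.
#' @export
bin_ld <- function(records) {
  bins <- ld_bins()
  d <- records$distance_bp / 1e6
  keep <- !is.na(records$r2) & d <= 5
  d <- d[keep]
  r2 <- records$r2[keep]
  idx <- findInterval(d, bins$lower)  # [lower_k, lower_{k+1}) ; d = 5 -> bin 9
  n_pairs <- tabulate(idx, nbins = nrow(bins))
  mean_r2 <- rep(NA_real_, nrow(bins))
  if (length(idx)) {
    sums <- vapply(seq_len(nrow(bins)), function(k) sum(r2[idx == k]), 0)
    mean_r2[n_pairs > 0] <- sums[n_pairs > 0] / n_pairs[n_pairs > 0]
  }
  cbind(bins[, c("label", "lower", "upper", "d_upper")],
        n_pairs = n_pairs, mean_r2 = mean_r2)
}

#' Fit the LD decay regression r2 = alpha + beta / sqrt(d)
#'
#' Ordinary least squares of per-bin mean r2 on `1 / sqrt(d)`, where `d` is
#' the upper boundary of each distance interval in Mbp. At least three
#' non-empty bins are required; a negative fitted beta (LD increasing with
#' distance) triggers a warning, not an error.
#'
#' @param bins a data.frame from [bin_ld()] (rows with `n_pairs == 0` or `NA`
#'   mean are dropped).
#' @return An object of class `ld_decay_fit` with `alpha`, `beta`,
#'   `residuals`, the underlying `lm` fit, and `predict(d_mbp)`.
#' @export
fit_decay <- function(bins) {
  use <- bins[!is.na(bins$mean_r2) & bins$n_pairs > 0, , drop = FALSE]
  if (nrow(use) < 3L) stop("fit_decay needs >= 3 non-empty bins")
  if (any(use$d_upper <= 0)) stop("d_upper must be positive")
  x <- 1 / sqrt(use$d_upper)
  fit <- lm(use$mean_r2 ~ x)
  beta <- unname(coef(fit)[2L])
  if (is.finite(beta) && beta < 0) {
    warning("fitted beta is negative: LD increases with distance")
  }
  structure(
    list(
      alpha = unname(coef(fit)[1L]), beta = beta,
      residuals = unname(fit$residuals), d_upper = use$d_upper,
      n_bins = nrow(use), lm = fit,
      predict = function(d_mbp) unname(coef(fit)[1L] + coef(fit)[2L] / sqrt(d_mbp))
    ),
    class = "ld_decay_fit"
  )
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay fit on %d bins: r2(d) = %.5f + %.5f / sqrt(d Mbp)\n",
              x$n_bins, x$alpha, x$beta))
  invisible(x)
}

#' Predicted decrease in LD between two distances
#'
#' Under `r2 = alpha + beta / sqrt(d)` the predicted decrease from `d1` to
#' `d2 > d1` is `beta * (1/sqrt(d1) - 1/sqrt(d2))`; consequently the ratio of
#' two populations' decreases over a common distance pair equals the ratio of
#' their betas.
#'
#' @param fit an `ld_decay_fit`.
#' @param d1,d2 distances in Mbp, `d1 < d2`.
#' @return Predicted decrease of mean r2 (non-negative for beta > 0).
#' @export
predicted_decrease <- function(fit, d1, d2) {
  stopifnot(d1 > 0, d2 > d1)
  fit$beta * (1 / sqrt(d1) - 1 / sqrt(d2))
}

#' Paired t-test of mean LD difference within a distance interval
#'
#' Restricts both record sets to SNP pairs present in both (pairing key:
#' ordered SNP-id pair), selects pairs whose distance falls in the interval,
#' and performs a one-sample t-test on the per-pair differences
#' `r2_a - r2_b` with `n - 1` degrees of freedom (two-sided).
#'
#' @param ld_a,ld_b LD record data.frames from [ld_records()].
#' @param interval numeric `c(lower, upper)` in Mbp, or a row of [ld_bins()].
#' @param closed_upper treat the upper boundary as included (used for the
#'   last interval `[3, 5]`); default picks this automatically when the
#'   interval matches the last bin.
#' @return A list `t`, `p`, `n`, `mean_diff`, `degenerate` (TRUE when the
#'   within-pair variance is zero).
#' @export
paired_interval_test <- function(ld_a, ld_b, interval, closed_upper = NULL) {
  if (is.data.frame(interval)) interval <- c(interval$lower[1L], interval$upper[1L])
  if (is.null(closed_upper)) closed_upper <- interval[2L] >= 5
  key_a <- paste(pmin(ld_a$snp_i, ld_a$snp_j), pmax(ld_a$snp_i, ld_a$snp_j))
  key_b <- paste(pmin(ld_b$snp_i, ld_b$snp_j), pmax(ld_b$snp_i, ld_b$snp_j))
  ib <- match(key_a, key_b)
  shared <- !is.na(ib)
  d <- ld_a$distance_bp[shared] / 1e6
  in_int <- d >= interval[1L] & (if (closed_upper) d <= interval[2L] else d < interval[2L])
  ra <- ld_a$r2[shared][in_int]
  rb <- ld_b$r2[ib[shared]][in_int]
  ok <- !is.na(ra) & !is.na(rb)
  diffs <- ra[ok] - rb[ok]
  n <- length(diffs)
  if (n < 2L) {
    return(list(t = NA_real_, p = NA_real_, n = n, mean_diff = NA_real_,
                degenerate = FALSE, flag = "fewer than 2 shared pairs"))
  }
  m <- mean(diffs)
  s <- sd(diffs)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, n = n, mean_diff = 0, degenerate = TRUE))
    return(list(t = sign(m) * Inf, p = 0, n = n, mean_diff = m, degenerate = TRUE))
  }
  tt <- m / (s / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), df = n - 1L), n = n, mean_diff = m,
       degenerate = FALSE)
}

#' Paired LD tests for all nine intervals
#'
#' @inheritParams paired_interval_test
#' @return A data.frame with one row per interval: `label`, `n`, `t`, `p`,
#'   `mean_diff`.
#' @export
paired_ld_tests <- function(ld_a, ld_b) {
  bins <- ld_bins()
  res <- lapply(seq_len(nrow(bins)), function(k) {
    r <- paired_interval_test(ld_a, ld_b, c(bins$lower[k], bins$upper[k]),
                              closed_upper = bins$upper[k] >= 5)
    data.frame(label = bins$label[k], n = r$n, t = r$t, p = r$p,
               mean_diff = r$mean_diff, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
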