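#' Tile a marker map into fixed-length windows
#'
#' Windows `[k L, (k+1) L)` are anchored at coordinate 0 on each chromosome
#' and extend to just beyond the last SNP. Every SNP falls in exactly one
#' window; windows containing no SNP are dropped (they cannot be tested), so
#' the `n_snp` column sums to the total SNP count.
#'
#' @param map a data.frame with columns `chrom` and `pos_bp` (a
#'   [genotype_panel()] is also accepted).
#' @param length_bp window length in base pairs.
#' @return An object of class `window_spec`: `length_bp` and a data.frame
#'   `windows` with `chrom`, `start_bp`, `end_bp` (half-open) and `n_snp`.
#' @export
make_windows <- function(map, length_bp) {
  if (inherits(map, "genotype_panel") || inherits(map, "haplotype_panel")) {
    map <- data.frame(chrom = map$chrom, pos_bp = map$pos_bp,
                      stringsAsFactors = FALSE)
  }
  stopifnot(length_bp > 0, all(c("chrom", "pos_bp") %in% names(map)))
  k <- floor(map$pos_bp / length_bp)
  key <- paste(map$chrom, k)
  tab <- table(key)
  parts <- strsplit(names(tab), " (?=[^ ]+$)", perl = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  kk <- as.numeric(vapply(parts, `[`, "", 2L))
  ord <- order(chrom, kk)
  win <- data.frame(
    chrom = chrom[ord],
    start_bp = kk[ord] * length_bp,
    end_bp = (kk[ord] + 1) * length_bp,
    n_snp = as.integer(tab)[ord],
    stringsAsFactors = FALSE
  )
  rownames(win) <- NULL
  structure(list(length_bp = length_bp, windows = win), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("window_spec: %d occupied windows of %.1f kbp, mean %.2f SNPs/window\n",
              nrow(x$windows), x$length_bp / 1e3, mean(x$windows$n_snp)))
  invisible(x)
}

#' Window-based two-sample test of regional effect differences
#'
#' For each window `i` the regional additive effect of population `x` is the
#' arithmetic mean of the per-SNP additive variances `a = 2 g^2 p (1 - p)`
#' (see [snp_additive_variance()]) of the SNPs in the window, and the test
#' statistic is
#' `t_i = (abar_A - abar_B) / sqrt((s2_A + s2_B) / N_SNP)`,
#' with `s2_x` the within-window variance of the per-SNP values and `N_SNP`
#' the common SNP count. Two-sided p-values use a t distribution with
#' `2 N_SNP - 2` degrees of freedom (pooled-count form of the statistic).
#' Windows with fewer than `min_snp` SNPs are excluded from testing and from
#' the FDR family. Setting `statistic = "effect"` tests the raw effects
#' `g_hat` instead of the additive variances.
#'
#' @param eff_a,eff_b `snp_effect_set` objects over a shared SNP list.
#' @param freq_a,freq_b `base_freq_set` objects supplying the per-SNP
#'   frequencies of each population (ignored for `statistic = "effect"`).
#' @param spec a [make_windows()] result (or a `length_bp` value, in which
#'   case windows are built from `eff_a`'s map).
#' @param min_snp minimum SNPs per tested window (default 2; a variance is
#'   undefined below that).
#' @param statistic `"additive_variance"` (default) or `"effect"`.
#' @return A data.frame with one row per tested window: `chrom`, `start_bp`,
#'   `end_bp`, `n_snp`, `mean_a_a`, `mean_a_b`, `var_a_a`, `var_a_b`, `t`,
#'   `p`.
#' @export
window_t_test <- function(eff_a, eff_b, freq_a = NULL, freq_b = NULL, spec,
                          min_snp = 2L,
                          statistic = c("additive_variance", "effect")) {
  statistic <- match.arg(statistic)
  if (!identical(eff_a$snp_ids, eff_b$snp_ids)) {
    shared <- intersect(eff_a$snp_ids, eff_b$snp_ids)
    if (!length(shared)) stop("no shared SNPs between effect sets")
    ia <- match(shared, eff_a$snp_ids)
    ib <- match(shared, eff_b$snp_ids)
  } else {
    shared <- eff_a$snp_ids
    ia <- ib <- seq_along(shared)
  }
  if (is.numeric(spec) && length(spec) == 1L) {
    spec <- make_windows(data.frame(chrom = eff_a$chrom[ia],
                                    pos_bp = eff_a$pos_bp[ia]), spec)
  }
  stopifnot(inherits(spec, "window_spec"))
  if (statistic == "additive_variance") {
    if (is.null(freq_a) || is.null(freq_b)) {
      stop("base-frequency sets required for the additive-variance statistic")
    }
    pa <- freq_a$p_base[match(shared, freq_a$snp_ids)]
    pb <- freq_b$p_base[match(shared, freq_b$snp_ids)]
    va <- snp_additive_variance(eff_a$g_hat[ia], pa)
    vb <- snp_additive_variance(eff_b$g_hat[ib], pb)
  } else {
    va <- eff_a$g_hat[ia]
    vb <- eff_b$g_hat[ib]
  }
  chrom <- eff_a$chrom[ia]
  pos <- eff_a$pos_bp[ia]
  L <- spec$length_bp
  wkey <- paste(chrom, floor(pos / L))
  win <- spec$windows
  win_key <- paste(win$chrom, floor(win$start_bp / L))
  grp <- match(wkey, win_key)
  res <- lapply(seq_len(nrow(win)), function(i) {
    sel <- which(grp == i)
    N <- length(sel)
    if (N < min_snp) return(NULL)
    ma <- mean(va[sel]); mb <- mean(vb[sel])
    s2a <- var(va[sel]); s2b <- var(vb[sel])
    den <- sqrt((s2a + s2b) / N)
    tt <- if (den > 0) (ma - mb) / den else if (ma == mb) 0 else sign(ma - mb) * Inf
    pp <- if (is.finite(tt)) 2 * pt(-abs(tt), df = 2L * N - 2L) else 0
    data.frame(chrom = win$chrom[i], start_bp = win$start_bp[i],
               end_bp = win$end_bp[i], n_snp = N,
               mean_a_a = ma, mean_a_b = mb, var_a_a = s2a, var_a_b = s2b,
               t = tt, p = pp, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    stop("no window holds >= ", min_snp, " SNPs")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()] with
#' `method = "BH"`); a test is flagged significant iff its adjusted value is
#' at most `q_max`.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param q_max maximum tolerated FDR, default 0.10.
#' @return A list with `q` (adjusted values) and `significant` (logical).
#' @export
bh_fdr <- function(p_values, q_max = 0.10) {
  if (!length(p_values)) return(list(q = numeric(0), significant = logical(0)))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- p.adjust(p_values, method = "BH")
  list(q = q, significant = !is.na(q) & q <= q_max)
}

#' Proportion of significant windows over a grid of window lengths
#'
#' Runs [window_t_test()] plus [bh_fdr()] for every window length of a grid
#' (by default 0.3 to 1.5 Mbp in steps of 0.1 Mbp) and reports the
#' proportion of tested windows flagged significant — the summary surface
#' behind the window-length comparison. The FDR family is per window length.
#'
#' @inheritParams window_t_test
#' @param lengths_bp vector of window lengths in bp.
#' @param q_max FDR level, default 0.10.
#' @return A data.frame with `length_bp`, `n_windows`, `n_significant`,
#'   `prop_significant`.
#' @export
window_scan <- function(eff_a, eff_b, freq_a, freq_b,
                        lengths_bp = seq(3e5, 15e5, by = 1e5),
                        q_max = 0.10, min_snp = 2L,
                        statistic = "additive_variance") {
  res <- lapply(lengths_bp, function(L) {
    wt <- window_t_test(eff_a, eff_b, freq_a, freq_b, L, min_snp = min_snp,
                        statistic = statistic)
    fdr <- bh_fdr(wt$p, q_max)
    data.frame(length_bp = L, n_windows = nrow(wt),
               n_significant = sum(fdr$significant),
               prop_significant = mean(fdr$significant))
  })
  do.call(rbind, res)
}
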