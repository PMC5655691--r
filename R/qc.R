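#' Filter a genotype panel on MAF and call rate
#'
#' A SNP is retained iff its observed minor allele frequency (computed from
#' non-missing genotypes only) is `>= maf_min` and its call rate is
#' `>= callrate_min`; both thresholds are inclusive. A SNP with all genotypes
#' missing fails the call-rate criterion (its MAF is never evaluated).
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency, default 0.01.
#' @param callrate_min minimum fraction of non-missing genotypes, default 0.90.
#' @return An object of class `qc_report` with counts (`n_input`,
#'   `n_failed_maf`, `n_failed_callrate`, `n_retained`), `retained_ids`, a
#'   per-SNP `detail` table, and the filtered panel in `$panel`.
#' @export
filter_panel <- function(panel, maf_min = 0.01, callrate_min = 0.90) {
  stopifnot(inherits(panel, "genotype_panel"),
            maf_min >= 0, maf_min <= 1, callrate_min >= 0, callrate_min <= 1)
  if (length(panel$snp_ids) == 0L) stop("empty panel")
  cr <- panel_callrate(panel)
  maf <- panel_maf(panel)
  fail_cr <- cr < callrate_min
  # all-missing SNPs have NaN MAF; they already fail call rate (callrate_min > 0)
  fail_maf <- !is.nan(maf) & maf < maf_min
  fail_maf[is.nan(maf)] <- FALSE
  keep <- !fail_cr & !fail_maf & !is.nan(maf)
  detail <- data.frame(
    snp_id = panel$snp_ids, maf = maf, callrate = cr,
    failed_maf = fail_maf, failed_callrate = fail_cr | is.nan(maf),
    retained = keep, stringsAsFactors = FALSE
  )
  structure(
    list(
      n_input = length(panel$snp_ids),
      n_failed_maf = sum(fail_maf),
      n_failed_callrate = sum(fail_cr | is.nan(maf)),
      n_retained = sum(keep),
      retained_ids = panel$snp_ids[keep],
      detail = detail,
      panel = subset_snps(panel, panel$snp_ids[keep])
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d SNPs in, %d retained (%d failed MAF, %d failed call rate)\n",
              x$n_input, x$n_retained, x$n_failed_maf, x$n_failed_callrate))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per removed SNP plus a `# summary` header comment.
#'
#' @param report a `qc_report`.
#' @param file output path.
#' @export
write_qc_report <- function(report, file) {
  removed <- report$detail[!report$detail$retained, , drop = FALSE]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# qc summary: input=%d retained=%d failed_maf=%d failed_callrate=%d",
                     report$n_input, report$n_retained,
                     report$n_failed_maf, report$n_failed_callrate), con)
  utils::write.table(removed, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Intersect two QC-filtered panels and harmonize allele orientation
#'
#' Both returned panels contain exactly the SNPs present in both inputs, in
#' panel `a`'s map order. When allele labels are available in both panels the
#' counted allele is harmonized to `a`'s orientation: a SNP whose labels are
#' swapped in `b` has its genotype column sign-flipped; a SNP whose labels
#' cannot be reconciled is dropped with a warning. Panels without allele
#' labels are assumed to share the same counted allele.
#'
#' @param a,b [genotype_panel()] objects.
#' @return A list with elements `a` and `b`, panels over the identical SNP
#'   list in identical order.
#' @export
intersect_panels <- function(a, b) {
  stopifnot(inherits(a, "genotype_panel"), inherits(b, "genotype_panel"))
  common <- a$snp_ids[a$snp_ids %in% b$snp_ids]
  ia <- match(common, a$snp_ids)
  ib <- match(common, b$snp_ids)
  flip <- rep(FALSE, length(common))
  drop <- rep(FALSE, length(common))
  if (!is.null(a$alleles) && !is.null(b$alleles)) {
    aa <- a$alleles[ia, , drop = FALSE]
    ba <- b$alleles[ib, , drop = FALSE]
    same <- !is.na(aa[, 1L]) & !is.na(ba[, 1L])
    match_fwd <- aa[, 1L] == ba[, 1L] & (is.na(aa[, 2L]) | is.na(ba[, 2L]) | aa[, 2L] == ba[, 2L])
    match_rev <- !is.na(ba[, 2L]) & aa[, 1L] == ba[, 2L] &
      (is.na(aa[, 2L]) | aa[, 2L] == ba[, 1L])
    flip <- same & !ifelse(is.na(match_fwd), FALSE, match_fwd) &
      ifelse(is.na(match_rev), FALSE, match_rev)
    drop <- same & !ifelse(is.na(match_fwd), FALSE, match_fwd) & !flip
    if (any(drop)) {
      warning(sum(drop), " SNP(s) dropped: irreconcilable allele labels (",
              paste(head(common[drop], 5L), collapse = ", "), ")")
    }
  }
  keep <- !drop
  common <- common[keep]
  pa <- subset_snps(a, common)
  pb <- subset_snps(b, common)
  fl <- flip[keep]
  if (any(fl)) {
    pb$genotypes[, fl] <- -pb$genotypes[, fl, drop = FALSE]
    if (!is.null(pb$alleles)) {
      pb$alleles[fl, ] <- pb$alleles[fl, c(2L, 1L), drop = FALSE]
    }
  }
  list(a = pa, b = pb)
}
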