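#' Construct a genotype panel
#'
#' A genotype panel holds biallelic genotypes for one population, coded
#' -1 (homozygote), 0 (heterozygote), +1 (alternative homozygote), with `NA`
#' for missing calls, together with the marker map. The +1 homozygote carries
#' two copies of the counted allele, so the per-genotype count of the counted
#' allele is `code + 1`.
#'
#' @param population_id single label for the population.
#' @param animal_ids character vector of animal identifiers (unique).
#' @param snp_ids character vector of SNP identifiers (unique).
#' @param chrom per-SNP chromosome label.
#' @param pos_bp per-SNP integer base-pair position, strictly increasing
#'   within each chromosome.
#' @param genotypes integer matrix, animals x SNPs, values in
#'   \{-1, 0, +1, NA\}.
#' @param alleles optional SNPs x 2 character matrix giving the counted and
#'   the alternative allele label; used to harmonize orientation when
#'   intersecting panels.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(population_id, animal_ids, snp_ids, chrom, pos_bp,
                           genotypes, alleles = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(
    length(population_id) == 1L,
    nrow(genotypes) == length(animal_ids),
    ncol(genotypes) == length(snp_ids),
    length(chrom) == length(snp_ids),
    length(pos_bp) == length(snp_ids)
  )
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (anyDuplicated(animal_ids)) stop("animal_ids must be unique")
  ok <- genotypes %in% c(-1L, 0L, 1L) | is.na(genotypes)
  if (!all(ok)) stop("genotypes must be coded -1/0/+1 with NA for missing")
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  for (cc in unique(chrom)) {
    p <- pos_bp[chrom == cc]
    if (any(diff(p) <= 0)) {
      stop("pos_bp must be strictly increasing within chromosome ", cc)
    }
  }
  if (!is.null(alleles)) {
    alleles <- as.matrix(alleles)
    stopifnot(nrow(alleles) == length(snp_ids), ncol(alleles) == 2L)
  }
  dimnames(genotypes) <- list(as.character(animal_ids), as.character(snp_ids))
  structure(
    list(
      population_id = as.character(population_id),
      animal_ids = as.character(animal_ids),
      snp_ids = as.character(snp_ids),
      chrom = chrom,
      pos_bp = pos_bp,
      genotypes = genotypes,
      alleles = alleles
    ),
    class = "genotype_panel"
  )
}

#' Construct a phased haplotype panel
#'
#' Companion container to [genotype_panel()]: each animal contributes two
#' binary haplotype rows (1 = counted allele present).
#'
#' @param population_id single label.
#' @param haplotypes binary matrix with `2 * n_animals` rows and one column
#'   per SNP.
#' @inheritParams genotype_panel
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(population_id, haplotypes, snp_ids, chrom, pos_bp) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(
    length(population_id) == 1L,
    ncol(haplotypes) == length(snp_ids),
    nrow(haplotypes) %% 2L == 0L,
    all(haplotypes %in% c(0L, 1L))
  )
  colnames(haplotypes) <- as.character(snp_ids)
  structure(
    list(
      population_id = as.character(population_id),
      haplotypes = haplotypes,
      snp_ids = as.character(snp_ids),
      chrom = as.character(chrom),
      pos_bp = as.integer(pos_bp)
    ),
    class = "haplotype_panel"
  )
}

#' Subset a panel to a set of SNPs
#'
#' @param panel a `genotype_panel` or `haplotype_panel`.
#' @param snp_ids SNP identifiers to keep; retained in the order given.
#' @return A panel of the same class restricted to `snp_ids`.
#' @export
subset_snps <- function(panel, snp_ids) {
  idx <- match(snp_ids, panel$snp_ids)
  if (anyNA(idx)) stop("unknown snp_ids: ", paste(snp_ids[is.na(idx)], collapse = ", "))
  if (inherits(panel, "genotype_panel")) {
    genotype_panel(panel$population_id, panel$animal_ids, panel$snp_ids[idx],
                   panel$chrom[idx], panel$pos_bp[idx],
                   panel$genotypes[, idx, drop = FALSE],
                   alleles = if (!is.null(panel$alleles)) panel$alleles[idx, , drop = FALSE])
  } else if (inherits(panel, "haplotype_panel")) {
    haplotype_panel(panel$population_id, panel$haplotypes[, idx, drop = FALSE],
                    panel$snp_ids[idx], panel$chrom[idx], panel$pos_bp[idx])
  } else {
    stop("not a panel object")
  }
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel '%s': %d animals x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              x$population_id, length(x$animal_ids), length(x$snp_ids),
              length(unique(x$chrom)), 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d haplotypes x %d SNPs\n",
              x$population_id, nrow(x$haplotypes), length(x$snp_ids)))
  invisible(x)
}

# counted-allele frequency per SNP from non-missing genotypes; NaN when all missing
counted_allele_freq <- function(panel) {
  g <- panel$genotypes
  colMeans(g + 1L, na.rm = TRUE) / 2
}

#' Observed minor allele frequency per SNP
#'
#' Counted-allele frequency folded to the minor side, computed from
#' non-missing genotypes only.
#'
#' @param panel a `genotype_panel`.
#' @return Numeric vector of MAF values in `[0, 0.5]`; `NaN` for SNPs with
#'   no non-missing genotypes.
#' @export
panel_maf <- function(panel) {
  f <- counted_allele_freq(panel)
  pmin(f, 1 - f)
}

#' Observed call rate per SNP
#'
#' @param panel a `genotype_panel`.
#' @return Fraction of non-missing genotypes per SNP.
#' @export
panel_callrate <- function(panel) {
  colMeans(!is.na(panel$genotypes))
}
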