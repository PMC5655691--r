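#' Read a PLINK ped/map file pair into a genotype panel
#'
#' Standard 6-column ped layout (family, animal, sire, dam, sex, phenotype)
#' followed by two allele columns per SNP; `0` marks a missing allele. The
#' counted allele of each SNP is the lexicographically first allele observed
#' at that SNP, recorded in the panel's `alleles` slot so that orientation can
#' be harmonized across panels.
#'
#' @param ped_file path to the .ped file.
#' @param map_file path to the .map file (chrom, snp id, cM, bp).
#' @param population_id label for the resulting panel.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(ped_file, map_file, population_id = "pop") {
  map <- data.table::fread(map_file, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp"))
  ped <- data.table::fread(ped_file, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) {
    stop("ped has ", ncol(ped), " columns; expected ", 6L + 2L * m)
  }
  animal_ids <- ped[[2L]]
  a1 <- as.matrix(ped[, seq(7L, by = 2L, length.out = m), with = FALSE])
  a2 <- as.matrix(ped[, seq(8L, by = 2L, length.out = m), with = FALSE])
  geno <- matrix(NA_integer_, nrow(ped), m)
  alleles <- matrix(NA_character_, m, 2L)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    lev <- sort(setdiff(unique(obs), "0"))
    if (length(lev) > 2L) stop("SNP ", map$snp_id[j], " has >2 alleles")
    if (length(lev) == 0L) lev <- c("A", "B")
    if (length(lev) == 1L) lev <- c(lev, NA_character_)
    alleles[j, ] <- lev
    cnt <- (a1[, j] == lev[1L]) + (a2[, j] == lev[1L])
    cnt[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    geno[, j] <- as.integer(cnt) - 1L
  }
  ord <- order(map$chrom, map$pos_bp)
  genotype_panel(population_id, animal_ids, map$snp_id[ord], map$chrom[ord],
                 map$pos_bp[ord], geno[, ord, drop = FALSE],
                 alleles = alleles[ord, , drop = FALSE])
}

#' Write a genotype panel as a PLINK ped/map pair
#'
#' @param panel a [genotype_panel()].
#' @param ped_file,map_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink <- function(panel, ped_file, map_file) {
  al <- panel$alleles
  if (is.null(al)) {
    al <- matrix(rep(c("A", "B"), each = length(panel$snp_ids)), ncol = 2L)
  }
  al[is.na(al)] <- "B"
  m <- length(panel$snp_ids)
  n <- length(panel$animal_ids)
  out <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    g <- panel$genotypes[, j]
    c1 <- ifelse(is.na(g), "0", ifelse(g >= 0L, al[j, 1L], al[j, 2L]))
    c2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, al[j, 1L], al[j, 2L]))
    out[, 2L * j - 1L] <- c1
    out[, 2L * j] <- c2
  }
  ped <- data.table::data.table(
    fid = panel$population_id, iid = panel$animal_ids,
    pat = "0", mat = "0", sex = "0", pheno = "-9"
  )
  data.table::fwrite(cbind(ped, data.table::as.data.table(out)), ped_file,
                     sep = " ", col.names = FALSE)
  data.table::fwrite(
    data.table::data.table(panel$chrom, panel$snp_ids, 0, panel$pos_bp),
    map_file, sep = "\t", col.names = FALSE
  )
  invisible(c(ped_file, map_file))
}

#' Read deregressed proofs from a TSV file
#'
#' Expected columns: `animal_id`, `trait`, `debv` (deregressed breeding
#' value) and `edc` (effective daughter contribution, a positive weight; the
#' residual variance of a record is modelled as sigma2_e / edc).
#'
#' @param file path to the TSV.
#' @param trait optional trait label to filter on.
#' @return A `deregressed_proofs` object (see [deregressed_proofs()]).
#' @export
read_proofs <- function(file, trait = NULL) {
  d <- data.table::fread(file)
  if (!is.null(trait)) d <- d[d$trait == trait, ]
  deregressed_proofs(d$animal_id, d$debv, d$edc,
                     trait = if (nrow(d)) d$trait[1L] else "unknown")
}

#' Construct a deregressed-proofs record set
#'
#' @param animal_ids animal labels.
#' @param y deregressed breeding values (trait units).
#' @param edc effective daughter contributions; must be strictly positive.
#' @param trait trait label.
#' @return An object of class `deregressed_proofs`.
#' @export
deregressed_proofs <- function(animal_ids, y, edc, trait = "trait") {
  stopifnot(length(animal_ids) == length(y), length(y) == length(edc))
  if (any(!is.finite(edc)) || any(edc <= 0)) stop("edc must be positive")
  structure(
    list(animal_ids = as.character(animal_ids), trait = as.character(trait)[1L],
         y = as.numeric(y), edc = as.numeric(edc)),
    class = "deregressed_proofs"
  )
}

#' Read a pedigree TSV (animal, sire, dam[, genotyped])
#'
#' `0`, `NA` or the empty string denote an unknown parent.
#'
#' @param file path to the TSV.
#' @return A `pedigree` object (see [pedigree()]).
#' @export
read_pedigree <- function(file) {
  d <- data.table::fread(file, colClasses = "character")
  gt <- if ("genotyped" %in% names(d)) {
    tolower(d$genotyped) %in% c("1", "true", "t", "yes")
  } else FALSE
  pedigree(d$animal_id, d$sire_id, d$dam_id, genotyped = gt)
}
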