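#' Construct a pedigree
#'
#' Unknown parents are denoted by `NA`, `""` or `"0"`. Animals are
#' topologically sorted so that parents precede offspring; a cycle raises an
#' error. The base population is the set of founders (animals with both
#' parents unknown) — in the intended use these are the non-genotyped
#' ancestors of the genotyped animals.
#'
#' @param animal_id,sire_id,dam_id character vectors of equal length.
#' @param genotyped logical flag per animal (recycled).
#' @return An object of class `pedigree`: a data.frame with columns
#'   `animal_id`, `sire_id`, `dam_id`, `genotyped`, sorted ancestors-first.
#' @export
pedigree <- function(animal_id, sire_id, dam_id, genotyped = FALSE) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  animal_id <- as.character(animal_id)
  sire_id <- norm(sire_id)
  dam_id <- norm(dam_id)
  stopifnot(length(sire_id) == length(animal_id),
            length(dam_id) == length(animal_id))
  if (anyDuplicated(animal_id)) stop("duplicated animal_id in pedigree")
  unknown_parents <- setdiff(c(sire_id, dam_id), c(animal_id, NA_character_))
  if (length(unknown_parents)) {
    stop("parents absent from pedigree: ",
         paste(head(unknown_parents, 5L), collapse = ", "))
  }
  d <- data.frame(animal_id = animal_id, sire_id = sire_id, dam_id = dam_id,
                  genotyped = rep_len(as.logical(genotyped), length(animal_id)),
                  stringsAsFactors = FALSE)
  # Kahn topological sort; leftover animals imply a cycle
  placed <- character(0)
  remaining <- d
  while (nrow(remaining)) {
    ready <- (is.na(remaining$sire_id) | remaining$sire_id %in% placed) &
      (is.na(remaining$dam_id) | remaining$dam_id %in% placed)
    if (!any(ready)) stop("pedigree contains a cycle")
    placed <- c(placed, remaining$animal_id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  d <- d[match(placed, d$animal_id), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("pedigree", "data.frame")
  d
}

#' Inverse of the numerator relationship matrix
#'
#' Assembles `A^{-1}` directly from the pedigree by Henderson's rules,
#' ignoring inbreeding: for an animal with both parents known the
#' contributions are 2 on its diagonal, -1 to each animal-parent pair and
#' 1/2 to every parent-parent pair; with one known parent 4/3, -2/3 and 1/3;
#' founders contribute 1 on the diagonal.
#'
#' @param ped a [pedigree()].
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with
#'   dimnames = animal ids in pedigree order.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  id <- ped$animal_id
  si <- match(ped$sire_id, id)
  di <- match(ped$dam_id, id)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (k in seq_len(n)) {
    s <- si[k]; dd <- di[k]
    if (!is.na(s) && !is.na(dd)) {
      add(k, k, 2)
      add(k, s, -1); add(s, k, -1)
      add(k, dd, -1); add(dd, k, -1)
      add(s, s, 0.5); add(dd, dd, 0.5)
      add(s, dd, 0.5); add(dd, s, 0.5)
    } else if (!is.na(s) || !is.na(dd)) {
      p <- if (is.na(s)) dd else s
      add(k, k, 4 / 3)
      add(k, p, -2 / 3); add(p, k, -2 / 3)
      add(p, p, 1 / 3)
    } else {
      add(k, k, 1)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(id, id))
  methods::as(Matrix::forceSymmetric(A), "symmetricMatrix")
}

#' Base-population allele frequency by gene-content BLUP
#'
#' Treats the gene content (0/1/2 copies of the counted allele) of genotyped
#' animals as a quantitative trait with pedigree covariance: `gc = 1 mu + u
#' + e`, `u ~ N(0, A sigma2_u)`, `lambda = sigma2_e / sigma2_u`. The fixed
#' mean `mu` estimates twice the allele frequency of the pedigree founders,
#' so the base frequency is `mu / 2`, clamped to `[0, 1]`. The mixed model
#' equations use `A^{-1}` from [a_inverse()]; their coefficient matrix
#' depends only on the pedigree, the genotyped set and `lambda`, so one
#' sparse Cholesky factorization serves every SNP (multi-RHS solve).
#'
#' @param ped a [pedigree()].
#' @param gene_content numeric vector (one SNP) or matrix (animals x SNPs)
#'   of 0/1/2 counts, with rownames or names giving animal ids; only
#'   genotyped animals may carry observations.
#' @param lambda variance ratio `sigma2_e / sigma2_u`; the default 0.01
#'   treats gene content as almost perfectly heritable.
#' @return Numeric vector of base frequencies in `[0, 1]`, one per SNP
#'   column.
#' @export
gene_content_blup <- function(ped, gene_content, lambda = 0.01) {
  stopifnot(inherits(ped, "pedigree"), lambda > 0)
  gc <- if (is.matrix(gene_content)) gene_content else
    matrix(gene_content, ncol = 1L,
           dimnames = list(names(gene_content), NULL))
  if (is.null(rownames(gc))) stop("gene_content must carry animal ids")
  obs <- match(rownames(gc), ped$animal_id)
  if (anyNA(obs)) stop("gene-content animals absent from pedigree")
  n <- nrow(ped)
  r <- nrow(gc)
  Ainv <- a_inverse(ped)
  # MME for gc = 1 mu + u + e, records indexing the observed animals
  Zo <- Matrix::sparseMatrix(i = seq_len(r), j = obs, x = 1, dims = c(r, n))
  C11 <- r
  C12 <- Matrix::colSums(Zo)
  C22 <- Matrix::crossprod(Zo) + lambda * Ainv
  C <- rbind(
    cbind(Matrix::Matrix(C11, 1, 1), Matrix::Matrix(C12, 1, n)),
    cbind(Matrix::Matrix(C12, n, 1), C22)
  )
  rhs <- rbind(Matrix::colSums(gc), as.matrix(Matrix::crossprod(Zo, gc)))
  sol <- Matrix::solve(C, rhs)
  mu <- as.numeric(sol[1L, ])
  pmin(pmax(mu / 2, 0), 1)
}

#' Base-population frequencies for every SNP of a panel
#'
#' Convenience wrapper around [gene_content_blup()]: converts the panel's
#' -1/0/+1 genotypes to gene content (`code + 1`), using only animals that
#' appear in the pedigree as genotyped. Missing genotypes are handled per
#' SNP by solving with the non-missing subset mean imputed (missing records
#' contribute the SNP's observed mean, which leaves `mu` essentially
#' unaffected).
#'
#' @param ped a [pedigree()] whose genotyped animals match the panel.
#' @param panel a [genotype_panel()].
#' @param lambda variance ratio as in [gene_content_blup()].
#' @return An object of class `base_freq_set`: `snp_ids`, `p_base`,
#'   `population_id`.
#' @export
estimate_base_freqs <- function(ped, panel, lambda = 0.01) {
  keep <- panel$animal_ids %in% ped$animal_id
  if (!any(keep)) stop("no panel animals present in pedigree")
  gc <- panel$genotypes[keep, , drop = FALSE] + 1
  rownames(gc) <- panel$animal_ids[keep]
  if (anyNA(gc)) {
    mns <- colMeans(gc, na.rm = TRUE)
    for (j in which(colSums(is.na(gc)) > 0L)) {
      gc[is.na(gc[, j]), j] <- mns[j]
    }
  }
  structure(
    list(snp_ids = panel$snp_ids,
         p_base = setNames(gene_content_blup(ped, gc, lambda), panel$snp_ids),
         population_id = panel$population_id),
    class = "base_freq_set"
  )
}

#' @export
print.base_freq_set <- function(x, ...) {
  cat(sprintf("base_freq_set '%s': %d SNPs, mean p = %.3f\n",
              x$population_id, length(x$p_base), mean(x$p_base)))
  invisible(x)
}

#' Construct a base-frequency set directly from frequencies
#'
#' @param snp_ids SNP labels.
#' @param p_base frequencies in `[0, 1]`.
#' @param population_id label.
#' @return A `base_freq_set`.
#' @export
base_freq_set <- function(snp_ids, p_base, population_id = "pop") {
  stopifnot(length(snp_ids) == length(p_base),
            all(p_base >= 0 & p_base <= 1))
  structure(list(snp_ids = as.character(snp_ids),
                 p_base = setNames(as.numeric(p_base), snp_ids),
                 population_id = population_id),
            class = "base_freq_set")
}

#' Agreement between two base-frequency sets
#'
#' Pearson correlation and ordinary least-squares regression of `b`'s
#' frequencies on `a`'s over the shared SNPs.
#'
#' @param a,b `base_freq_set` objects.
#' @return A list `pearson_r`, `intercept`, `slope`, `r_squared`,
#'   `n_shared`.
#' @export
base_freq_agreement <- function(a, b) {
  shared <- intersect(a$snp_ids, b$snp_ids)
  if (length(shared) < 3L) stop("fewer than 3 shared SNPs")
  pa <- a$p_base[shared]
  pb <- b$p_base[shared]
  fit <- lm(pb ~ pa)
  r <- cor(pa, pb)
  list(
    pearson_r = r,
    intercept = unname(coef(fit)[1L]),
    slope = unname(coef(fit)[2L]),
    r_squared = r^2,   # = OLS R^2 for a single regressor
    n_shared = length(shared)
  )
}
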