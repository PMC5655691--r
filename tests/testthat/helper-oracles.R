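# Independent oracles and small fixture builders shared across test files.
# Everything here is deliberately naive (dense algebra, direct formulas) so
# that it stays independent of the package's iterative implementations.

# dense direct solve of the SNP-BLUP mixed model equations
# [ 1'W1  1'WZ        ] [mu]   [1'Wy]
# [ Z'W1  Z'WZ + kI   ] [g ] = [Z'Wy]
dense_mme_solve <- function(Z, y, w, shrink) {
  X <- matrix(1, nrow(Z), 1L)
  C <- rbind(
    cbind(crossprod(X, X * w), crossprod(X, Z * w)),
    cbind(crossprod(Z, X * w), crossprod(Z, Z * w) + diag(shrink, ncol(Z)))
  )
  rhs <- c(sum(w * y), crossprod(Z, w * y))
  sol <- solve(C, rhs)
  list(mu = sol[1L], g = sol[-1L])
}

# numerator relationship matrix by the tabular method (pedigree must be
# sorted ancestors-first, as the pedigree() constructor guarantees)
dense_A_tabular <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal_id
  si <- match(ped$sire_id, id)
  di <- match(ped$dam_id, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    A[k, k] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    for (j in seq_len(k - 1L)) {
      val <- 0
      if (!is.na(s)) val <- val + 0.5 * A[j, s]
      if (!is.na(d)) val <- val + 0.5 * A[j, d]
      A[k, j] <- A[j, k] <- val
    }
  }
  A
}

# dense direct solve of the gene-content BLUP equations for one SNP
dense_gene_content_solve <- function(ped, gc, lambda) {
  n <- nrow(ped)
  obs <- match(names(gc), ped$animal_id)
  Zo <- matrix(0, length(gc), n)
  Zo[cbind(seq_along(gc), obs)] <- 1
  A <- dense_A_tabular(ped)
  C <- rbind(
    cbind(length(gc), t(colSums(Zo))),
    cbind(colSums(Zo), crossprod(Zo) + lambda * solve(A))
  )
  rhs <- c(sum(gc), crossprod(Zo, gc))
  sol <- solve(C, rhs)
  sol[1L] / 2
}

# quick genotype panel around a raw matrix (one chromosome, unit spacing)
make_panel <- function(geno, pop = "pop", pos = NULL, chrom = NULL,
                       alleles = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  genotype_panel(
    pop, sprintf("a%03d", seq_len(nrow(geno))), sprintf("s%03d", seq_len(m)),
    chrom %||% rep("1", m), pos %||% (seq_len(m) * 1000L), geno,
    alleles = alleles
  )
}

make_hap_panel <- function(H, pop = "pop", pos = NULL, chrom = NULL) {
  H <- as.matrix(H)
  m <- ncol(H)
  haplotype_panel(pop, H, sprintf("s%03d", seq_len(m)),
                  chrom %||% rep("1", m), pos %||% (seq_len(m) * 1000L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force paired t statistic on differences
paired_t_oracle <- function(d) {
  m <- mean(d); s <- sd(d); n <- length(d)
  tt <- m / (s / sqrt(n))
  c(t = tt, p = 2 * pt(-abs(tt), df = n - 1))
}
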