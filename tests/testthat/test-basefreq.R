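test_that("A-inverse follows Henderson's rules and inverts the tabular A", {
  # unrelated founders
  ped0 <- pedigree(c("a", "b", "c"), c(NA, NA, NA), c(NA, NA, NA))
  expect_equal(as.matrix(a_inverse(ped0)), diag(3),
               ignore_attr = TRUE)

  # trio: known closed-form entries
  ped1 <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
  Ainv <- as.matrix(a_inverse(ped1))
  expect_equal(Ainv["o", "o"], 2)
  expect_equal(Ainv["o", "s"], -1)
  expect_equal(Ainv["o", "d"], -1)
  expect_equal(Ainv["s", "d"], 0.5)
  expect_equal(Ainv["s", "s"], 1.5)
  # against dense inversion of the tabular A
  expect_equal(Ainv, solve(dense_A_tabular(ped1)), tolerance = 1e-12)

  # single known parent
  ped2 <- pedigree(c("s", "o"), c(NA, "s"), c(NA, NA))
  Ainv2 <- as.matrix(a_inverse(ped2))
  expect_equal(Ainv2["o", "o"], 4 / 3)
  expect_equal(Ainv2["o", "s"], -2 / 3)
})

test_that("A %*% A-inverse is the identity on random non-inbred pedigrees", {
  set.seed(41)
  for (rep in 1:5) {
    # three non-overlapping generations so no inbreeding loops arise
    n0 <- 6L; n1 <- 7L; n2 <- 7L
    ids <- c(sprintf("f%d", 1:n0), sprintf("m%d", 1:n1), sprintf("k%d", 1:n2))
    sire <- c(rep(NA, n0),
              sprintf("f%d", sample(n0 / 2, n1, TRUE)),
              sprintf("m%d", sample(n1 %/% 2, n2, TRUE)))
    dam <- c(rep(NA, n0),
             sprintf("f%d", n0 / 2 + sample(n0 / 2, n1, TRUE)),
             sprintf("m%d", n1 %/% 2 + sample(n1 - n1 %/% 2, n2, TRUE)))
    ped <- pedigree(ids, sire, dam)
    A <- dense_A_tabular(ped)
    P <- A %*% as.matrix(a_inverse(ped))
    expect_equal(P, diag(nrow(A)), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("pedigree construction sorts ancestors first and rejects cycles", {
  ped <- pedigree(c("kid", "pa", "ma"), c("pa", NA, NA), c("ma", NA, NA))
  expect_equal(ped$animal_id[3L], "kid")
  expect_error(pedigree(c("x", "y"), c("y", "x"), c(NA, NA)), "cycle")
})

test_that("gene-content BLUP degenerates to half the sample mean without pedigree links", {
  ped <- pedigree(sprintf("a%d", 1:4), rep(NA, 4L), rep(NA, 4L),
                  genotyped = TRUE)
  gc <- setNames(c(0, 1, 2, 1), ped$animal_id)
  expect_equal(gene_content_blup(ped, gc), 0.5, tolerance = 1e-9)
  # monomorphic SNP fixed for the counted allele
  gc2 <- setNames(rep(2, 4L), ped$animal_id)
  expect_equal(gene_content_blup(ped, gc2), 1, tolerance = 1e-9)
})

test_that("gene-content BLUP equals a dense direct MME solve on a two-generation pedigree", {
  set.seed(43)
  n0 <- 10L; n1 <- 20L
  ids <- c(sprintf("f%02d", 1:n0), sprintf("g%02d", 1:n1))
  sire <- c(rep(NA, n0), sprintf("f%02d", sample(5L, n1, TRUE)))
  dam <- c(rep(NA, n0), sprintf("f%02d", 5L + sample(5L, n1, TRUE)))
  ped <- pedigree(ids, sire, dam, genotyped = c(rep(FALSE, n0), rep(TRUE, n1)))
  gc <- setNames(sample(0:2, n1, TRUE), sprintf("g%02d", 1:n1))
  for (lambda in c(0.01, 0.5)) {
    p_pkg <- gene_content_blup(ped, gc, lambda)
    p_oracle <- dense_gene_content_solve(ped, gc, lambda)
    expect_equal(p_pkg, min(max(p_oracle, 0), 1), tolerance = 1e-8)
  }
})

test_that("huge lambda ignores the pedigree entirely", {
  set.seed(44)
  ids <- c("f1", "f2", sprintf("g%d", 1:6))
  ped <- pedigree(ids, c(NA, NA, rep("f1", 6L)), c(NA, NA, rep("f2", 6L)),
                  genotyped = c(FALSE, FALSE, rep(TRUE, 6L)))
  gc <- setNames(c(2, 1, 1, 0, 2, 1), sprintf("g%d", 1:6))
  expect_equal(gene_content_blup(ped, gc, lambda = 1e8), mean(gc) / 2,
               tolerance = 1e-5)
})

test_that("base frequency is equivariant under allele relabeling", {
  set.seed(45)
  cfg <- sim_config(n_animals = 60L, n_snp = 30L, n_chrom = 1L, seed = 45L)
  st <- simulate_study(cfg)
  pp <- st$pops$PL
  bf <- estimate_base_freqs(pp$pedigree, pp$panel)
  flipped <- pp$panel
  flipped$genotypes <- -flipped$genotypes
  bf_fl <- estimate_base_freqs(pp$pedigree, flipped)
  expect_equal(unname(bf_fl$p_base), 1 - unname(bf$p_base), tolerance = 1e-9)
})

test_that("estimated base frequencies recover the founder pool frequencies", {
  cfg <- sim_config(n_animals = 120L, n_snp = 300L, n_chrom = 2L,
                    missing_rate = 0, seed = 46L)
  st <- simulate_study(cfg)
  pp <- st$pops$DE
  bf <- estimate_base_freqs(pp$pedigree, pp$panel)
  mae <- mean(abs(unname(bf$p_base) - pp$founder_freqs))
  expect_lt(mae, 0.05)
})

test_that("base-frequency agreement reports correlation and regression", {
  set.seed(47)
  p <- runif(200L, 0.05, 0.95)
  a <- base_freq_set(sprintf("s%03d", 1:200), p, "A")
  same <- base_freq_agreement(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$r_squared, 1)

  b <- base_freq_set(sprintf("s%03d", 1:200), 1 - p, "B")
  flip <- base_freq_agreement(a, b)
  expect_equal(flip$pearson_r, -1)
  expect_equal(flip$slope, -1, tolerance = 1e-12)

  expect_error(base_freq_agreement(a, base_freq_set("s001", 0.5)), "3 shared")
})

test_that("two Balding-Nichols draws from a common base are highly correlated", {
  set.seed(48)
  m <- 5000L
  base <- simulate_base_freqs(m)
  F <- 0.01
  p1 <- rbeta(m, base * (1 - F) / F, (1 - base) * (1 - F) / F)
  p2 <- rbeta(m, base * (1 - F) / F, (1 - base) * (1 - F) / F)
  a <- base_freq_set(sprintf("s%04d", 1:m), pmin(pmax(p1, 0), 1), "A")
  b <- base_freq_set(sprintf("s%04d", 1:m), pmin(pmax(p2, 0), 1), "B")
  agr <- base_freq_agreement(a, b)
  # brute-force correlation formula as the independent check
  r_bf <- sum((p1 - mean(p1)) * (p2 - mean(p2))) /
    sqrt(sum((p1 - mean(p1))^2) * sum((p2 - mean(p2))^2))
  expect_equal(agr$pearson_r, r_bf, tolerance = 1e-12)
  expect_gte(agr$pearson_r, 0.95)
})
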