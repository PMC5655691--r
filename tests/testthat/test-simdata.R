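test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_animals = 50L, n_snp = 80L, n_chrom = 2L, seed = 71L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pops$PL$panel$genotypes, s2$pops$PL$panel$genotypes)
  expect_identical(s1$pops$DE$haplotypes$haplotypes,
                   s2$pops$DE$haplotypes$haplotypes)
  expect_identical(s1$traits$scs$effects, s2$traits$scs$effects)
  expect_identical(s1$traits$prod$proofs$PL$y, s2$traits$prod$proofs$PL$y)

  s3 <- simulate_study(sim_config(n_animals = 50L, n_snp = 80L, n_chrom = 2L,
                                  seed = 72L))
  expect_false(identical(s1$pops$PL$panel$genotypes,
                         s3$pops$PL$panel$genotypes))
})

test_that("base frequencies have the configured support and centre", {
  set.seed(73)
  p <- simulate_base_freqs(10000L)
  expect_true(all(p >= 0.05 & p <= 0.95))
  expect_equal(mean(p), 0.5, tolerance = 0.01)
  expect_identical(simulate_base_freqs(50L, seed = 9L),
                   simulate_base_freqs(50L, seed = 9L))
})

test_that("population frequencies collapse onto the base as drift vanishes", {
  cfg <- sim_config(n_animals = 30L, n_snp = 500L, n_chrom = 1L,
                    fst = 1e-6, seed = 74L)
  set.seed(74)
  map <- simulate_map(cfg)
  base <- simulate_base_freqs(cfg$n_snp)
  pp <- simulate_population(base, cfg, 1L, map)
  expect_lt(max(abs(pp$pop_freqs - base)), 0.01)
})

test_that("genotypes are haplotype sums and close to Hardy-Weinberg proportions", {
  cfg <- sim_config(n_animals = 500L, n_snp = 60L, n_chrom = 1L,
                    missing_rate = 0, seed = 75L)
  set.seed(75)
  map <- simulate_map(cfg)
  base <- simulate_base_freqs(cfg$n_snp)
  pp <- simulate_population(base, cfg, 2L, map)
  H <- pp$haplotypes$haplotypes
  n <- cfg$n_animals
  g_from_h <- H[seq_len(n) * 2L - 1L, ] + H[seq_len(n) * 2L, ] - 1L
  expect_identical(unname(pp$panel$genotypes), unname(g_from_h))

  # chi-square HWE statistic should be unremarkable for nearly every SNP
  p_hwe <- vapply(seq_len(ncol(H)), function(j) {
    g <- pp$panel$genotypes[, j]
    p <- mean(g + 1L) / 2
    if (p <= 0 || p >= 1) return(1)
    expc <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 2L, 3L)
    pchisq(sum((obs - expc)^2 / pmax(expc, 1e-9)), df = 1L, lower.tail = FALSE)
  }, 0)
  expect_lt(mean(p_hwe < 0.01), 0.06)
})

test_that("EDC weighting makes var(e) * edc constant by construction", {
  cfg <- sim_config(n_animals = 2000L, n_snp = 20L, n_chrom = 1L, seed = 76L)
  set.seed(76)
  geno <- matrix(sample(c(-1L, 0L, 1L), 2000L * 20L, TRUE), 2000L)
  g0 <- rep(0, 20L)  # null effects isolate the residual
  pr <- simulate_proofs(geno, sprintf("a%04d", 1:2000), g0, cfg,
                        sigma2_e = 400)
  z <- pr$y * sqrt(pr$edc)  # should be iid N(0, sqrt(400))
  expect_equal(sd(z), 20, tolerance = 0.05 * 20)
  # noiseless limit
  g1 <- rnorm(20L)
  pr0 <- simulate_proofs(geno, sprintf("a%04d", 1:2000), g1, cfg,
                         sigma2_e = 1e-12, mu = 1.5)
  expect_equal(pr0$y, 1.5 + as.numeric(geno %*% g1), tolerance = 1e-4)
})

test_that("the faster-decaying population yields the larger fitted decay beta", {
  wins <- sapply(1:6, function(s) {
    cfg <- sim_config(n_animals = 200L, n_snp = 1000L, n_chrom = 2L,
                      seed = 700L + s)
    set.seed(700L + s)
    map <- simulate_map(cfg)
    base <- simulate_base_freqs(cfg$n_snp)
    b1 <- fit_decay(bin_ld(ld_records(simulate_population(base, cfg, 1L, map)$haplotypes)))$beta
    b2 <- fit_decay(bin_ld(ld_records(simulate_population(base, cfg, 2L, map)$haplotypes)))$beta
    b2 > b1
  })
  expect_gte(sum(wins), 5L)
})

test_that("fitted decay betas agree with the generator's implied betas", {
  reps <- 6L
  fitted <- implied <- matrix(0, reps, 2L)
  for (s in seq_len(reps)) {
    cfg <- sim_config(n_animals = 250L, n_snp = 2000L, n_chrom = 4L,
                      seed = 710L + s)
    set.seed(710L + s)
    map <- simulate_map(cfg)
    base <- simulate_base_freqs(cfg$n_snp)
    for (p in 1:2) {
      pp <- simulate_population(base, cfg, p, map)
      fitted[s, p] <- fit_decay(bin_ld(ld_records(pp$haplotypes)))$beta
      implied[s, p] <- implied_decay_beta(map, pp$pop_freqs,
                                          cfg$ld_decay_rate[p],
                                          n_hap = 2L * cfg$n_animals,
                                          max_pairs_per_bin = 200L)
    }
  }
  expect_equal(mean(fitted[, 1L]) / mean(implied[, 1L]), 1, tolerance = 0.1)
  expect_equal(mean(fitted[, 2L]) / mean(implied[, 2L]), 1, tolerance = 0.1)
  # and the between-population ordering carries over
  expect_gt(mean(fitted[, 2L]), mean(fitted[, 1L]))
})

test_that("a written study round-trips through the plain-text files", {
  cfg <- sim_config(n_animals = 40L, n_snp = 60L, n_chrom = 2L, seed = 78L)
  st <- simulate_study(cfg)
  dir <- tempfile("study")
  write_study(st, dir)
  pl <- read_plink(file.path(dir, "PL.ped"), file.path(dir, "PL.map"), "PL")
  # allele orientation is recoverable only where both alleles were observed
  both_seen <- apply(st$pops$PL$panel$genotypes, 2L, function(g) {
    any(g > -1L, na.rm = TRUE) && any(g < 1L, na.rm = TRUE)
  })
  expect_gt(mean(both_seen), 0.9)
  expect_equal(unname(pl$genotypes[, both_seen]),
               unname(st$pops$PL$panel$genotypes[, both_seen]))
  ped <- read_pedigree(file.path(dir, "PL_pedigree.tsv"))
  expect_equal(ped$animal_id, st$pops$PL$pedigree$animal_id)
  expect_equal(ped$genotyped, st$pops$PL$pedigree$genotyped)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$base_freq, st$base_freqs, tolerance = 1e-9)
  expect_equal(truth$g_scs_DE, st$traits$scs$effects[, 2L], tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
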