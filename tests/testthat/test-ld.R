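test_that("pair_r2 matches the haplotype-frequency formula", {
  # complete LD: only AB and ab haplotypes at p1 = p2 = 0.5
  a <- rep(c(1L, 0L), each = 10L)
  expect_equal(pair_r2(a, a), 1)

  # full 2x2 cross: statistically independent alleles
  a2 <- rep(c(1L, 1L, 0L, 0L), 5L)
  b2 <- rep(c(1L, 0L, 1L, 0L), 5L)
  expect_equal(pair_r2(a2, b2), 0)

  # 100 haplotypes, counts AB=40 Ab=10 aB=10 ab=40:
  # p1 = p2 = 0.5, D = 0.40 - 0.25 = 0.15, r2 = 0.15^2 / 0.5^4 = 0.36
  h1 <- c(rep(1L, 50L), rep(0L, 50L))
  h2 <- c(rep(1L, 40L), rep(0L, 10L), rep(1L, 10L), rep(0L, 40L))
  expect_equal(pair_r2(h1, h2), 0.36)

  # monomorphic locus: undefined
  expect_true(is.na(pair_r2(rep(1L, 20L), a)))
})

test_that("pair_r2 is symmetric and invariant under allele relabeling", {
  set.seed(11)
  for (k in 1:20) {
    x <- rbinom(60L, 1L, 0.5)
    y <- as.integer(runif(60L) < 0.3 + 0.4 * x)
    if (var(x) == 0 || var(y) == 0) next
    r <- pair_r2(x, y)
    expect_equal(pair_r2(y, x), r)
    expect_equal(pair_r2(1L - x, y), r)
    expect_equal(pair_r2(x, 1L - y), r)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("ld_records agrees with pair_r2 and respects the distance cap", {
  set.seed(3)
  H <- matrix(rbinom(200L * 6L, 1L, 0.4), 200L)
  pos <- c(1e5L, 2e5L, 1.2e6L, 4.9e6L, 5.2e6L, 9e6L)
  hp <- make_hap_panel(H, pos = pos)
  rec <- ld_records(hp)
  # every same-chromosome pair within 5 Mbp, none beyond
  expect_true(all(rec$distance_bp <= 5e6))
  for (r in seq_len(nrow(rec))) {
    i <- match(rec$snp_i[r], hp$snp_ids)
    j <- match(rec$snp_j[r], hp$snp_ids)
    expect_equal(rec$r2[r], pair_r2(H[, i], H[, j]), tolerance = 1e-12)
  }
  # cross-check the enumeration count
  dd <- abs(outer(pos, pos, "-"))
  expect_equal(nrow(rec), sum(dd[upper.tri(dd)] <= 5e6))
})

test_that("two-locus EM reproduces direct counts and haplotype r2", {
  # no double heterozygotes: counting is exact
  ga <- c(1L, 1L, -1L, 0L, 0L)
  gb <- c(1L, -1L, -1L, 1L, -1L)
  f <- em_two_locus_freqs(ga, gb)
  # direct haplotype counting: dosages (2,2),(2,0),(0,0),(1,2),(1,0)
  # -> AB 2+0+0+1+0 = 3, Ab 0+2+0+0+1 = 3, aB 0+0+0+1+0 = 1, ab 3
  expect_equal(as.numeric(f), c(3, 3, 1, 3) / 10, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(attr(f, "converged"))

  # independent loci: pAB converges to pA * pB
  set.seed(5)
  ga2 <- sample(c(-1L, 0L, 1L), 800L, replace = TRUE, prob = c(.25, .5, .25))
  gb2 <- sample(c(-1L, 0L, 1L), 800L, replace = TRUE, prob = c(.25, .5, .25))
  f2 <- em_two_locus_freqs(ga2, gb2)
  pA <- mean(ga2 + 1) / 2; pB <- mean(gb2 + 1) / 2
  expect_lt(abs(f2[["pAB"]] - pA * pB), 0.02)

  # phased haplotypes collapsed to genotypes: EM r2 matches haplotype r2
  set.seed(6)
  n <- 2000L
  z <- rbinom(n, 1L, 0.5)
  h1 <- matrix(rbinom(2L * n, 1L, 0.45), ncol = 2L)
  h2 <- ifelse(matrix(runif(2L * n), ncol = 2L) < 0.8, h1, rbinom(2L * n, 1L, 0.45))
  hapA <- h1[, 1L]; hapB <- h2[, 1L]
  # pair up consecutive rows as diploids
  i1 <- seq(1L, n, by = 2L); i2 <- seq(2L, n, by = 2L)
  gA <- hapA[i1] + hapA[i2] - 1L
  gB <- hapB[i1] + hapB[i2] - 1L
  r2_hap <- pair_r2(hapA, hapB)
  r2_em <- pair_r2_em(gA, gB)
  expect_equal(r2_em, r2_hap, tolerance = 0.05)
})

test_that("bin_ld assigns half-open intervals with a closed last bin", {
  rec <- data.frame(
    snp_i = "a", snp_j = "b", chrom = "1",
    distance_bp = c(25000L, 24999L, 5000000L, 5000001L, 300000L, 300001L),
    r2 = c(0.5, 0.5, 0.5, 0.5, 0.2, 0.4)
  )
  bins <- bin_ld(rec)
  expect_equal(bins$n_pairs[bins$label == "[0-0.025)"], 1L)     # 24999 only
  expect_equal(bins$n_pairs[bins$label == "[0.025-0.05)"], 1L)  # 25000 rolls up
  expect_equal(bins$n_pairs[bins$label == "[3-5]"], 1L)          # 5.0 included
  expect_equal(sum(bins$n_pairs), 5L)                            # 5.000001 dropped
  expect_equal(bins$mean_r2[bins$label == "[0.2-0.5)"], 0.3)     # arithmetic mean
  expect_true(is.na(bins$mean_r2[bins$label == "[0.5-1.5)"]))
  expect_equal(bins$n_pairs[bins$label == "[0.5-1.5)"], 0L)
})

test_that("n_pairs over bins partitions the same-chromosome pairs within 5 Mbp", {
  set.seed(9)
  H <- matrix(rbinom(100L * 40L, 1L, 0.5), 100L)
  pos <- sort(sample.int(8e6L, 40L))
  hp <- make_hap_panel(H, pos = pos)
  rec <- ld_records(hp)
  bins <- bin_ld(rec)
  dd <- outer(pos, pos, function(a, b) b - a)
  expected <- sum(dd[upper.tri(dd)] > 0 & dd[upper.tri(dd)] <= 5e6) -
    sum(is.na(rec$r2))
  expect_equal(sum(bins$n_pairs), expected)
})

test_that("fit_decay recovers an exact alpha + beta/sqrt(d) law and matches closed-form OLS", {
  bins <- ld_bins()
  bins$n_pairs <- 10L
  bins$mean_r2 <- 0.05 + 0.03 / sqrt(bins$d_upper)
  fit <- fit_decay(bins)
  expect_equal(fit$alpha, 0.05, tolerance = 1e-12)
  expect_equal(fit$beta, 0.03, tolerance = 1e-12)
  expect_equal(fit$predict(4), 0.05 + 0.03 / 2, tolerance = 1e-12)

  # noisy bins: equals the closed-form OLS solution
  set.seed(2)
  bins$mean_r2 <- bins$mean_r2 + rnorm(nrow(bins), 0, 0.01)
  fit2 <- fit_decay(bins)
  x <- 1 / sqrt(bins$d_upper); y <- bins$mean_r2
  beta_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit2$beta, beta_cf, tolerance = 1e-10)
  expect_equal(fit2$alpha, mean(y) - beta_cf * mean(x), tolerance = 1e-10)

  expect_error(fit_decay(bins[1:2, ]), ">= 3")
})

test_that("ratio of predicted decreases over a common distance pair equals the beta ratio", {
  bins <- ld_bins(); bins$n_pairs <- 1L
  mk <- function(alpha, beta) {
    b <- bins; b$mean_r2 <- alpha + beta / sqrt(b$d_upper); fit_decay(b)
  }
  f1 <- mk(0.08, 0.044)
  f2 <- mk(0.03, 0.026)
  d_pairs <- list(c(0.025, 0.075), c(3, 5), c(0.12, 1.5))
  for (dp in d_pairs) {
    r <- predicted_decrease(f1, dp[1], dp[2]) / predicted_decrease(f2, dp[1], dp[2])
    expect_equal(r, f1$beta / f2$beta, tolerance = 1e-10)
  }
})

test_that("paired interval test matches a brute-force paired t computation", {
  # identical record sets: zero differences
  rec <- data.frame(snp_i = sprintf("s%02d", 1:30), snp_j = sprintf("t%02d", 1:30),
                    chrom = "1", distance_bp = 40000L,
                    r2 = runif(30))
  res0 <- paired_interval_test(rec, rec, c(0.025, 0.05))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # constant positive shift (binary-exact values): degenerate variance, p -> 0
  rec$r2 <- (1:30) / 64
  rec2 <- rec; rec2$r2 <- rec$r2 - 1 / 32
  res1 <- paired_interval_test(rec, rec2, c(0.025, 0.05))
  expect_true(res1$degenerate)
  expect_equal(res1$p, 0)

  # simulated differences vs independent recomputation
  set.seed(21)
  d <- rnorm(50L, 0.05, 0.01)
  ra <- runif(50L, 0.2, 0.6)
  recA <- data.frame(snp_i = sprintf("s%02d", 1:50), snp_j = sprintf("t%02d", 1:50),
                     chrom = "1", distance_bp = 2e6L, r2 = ra)
  recB <- recA; recB$r2 <- ra - d
  res2 <- paired_interval_test(recA, recB, c(1.5, 3))
  oracle <- paired_t_oracle(d)
  expect_equal(res2$t, unname(oracle["t"]), tolerance = 1e-12)
  expect_equal(res2$p, unname(oracle["p"]), tolerance = 1e-12)
  expect_equal(res2$n, 50L)

  # pairs present in only one population are excluded
  recC <- rbind(recB, data.frame(snp_i = "x1", snp_j = "x2", chrom = "1",
                                 distance_bp = 2e6L, r2 = 0.9))
  expect_equal(paired_interval_test(recA, recC, c(1.5, 3))$n, 50L)
})
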