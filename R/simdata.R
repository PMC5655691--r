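#' Configuration for the two-population synthetic-data generator
#'
#' Defaults encode the study design the pipeline targets: two populations
#' drifted from a common base with `fst = 0.01` (base-frequency agreement
#' around 0.97 across populations), distance-dependent LD whose copying rate
#' differs between populations by the factor 1.7 reported between the two
#' real populations (the second population carries the faster decay),
#' cross-population SNP effects correlated at 0.3 with a 1:2 variance ratio,
#' and deregressed proofs whose residual variance is inversely proportional
#' to a log-normal effective daughter contribution (meanlog 4, sdlog 0.7, a
#' spread resembling progeny-tested bulls).
#'
#' Copying rates are deliberately placed in the weak-decay regime
#' (`rate * 5 Mbp` of order one): there the fitted decay coefficient beta of
#' `r2 = alpha + beta / sqrt(d)` scales approximately linearly with the
#' copying rate, which is the property the recovery tests rely on. Absolute
#' r2 magnitudes are consequently higher and longer-ranged than on a real
#' 50K chip.
#'
#' @param n_animals animals per generation and population.
#' @param n_snp total SNPs across chromosomes.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param ld_decay_rate named length-2 vector, per-bp copying decay rate of
#'   the latent haplotype process for each population.
#' @param fst Balding-Nichols drift parameter between base and each
#'   population, in (0, 1).
#' @param effect_corr true cross-population correlation of SNP effects.
#' @param effect_var length-2 per-SNP true effect variances (trait units^2);
#'   the implied total additive variance handed to SNP-BLUP is
#'   `n_snp * effect_var`.
#' @param sigma2_e residual variance of the proofs (scaled by 1/EDC per
#'   record).
#' @param edc_meanlog,edc_sdlog log-normal parameters of the effective
#'   daughter contributions.
#' @param pedigree_depth non-genotyped generations above the genotyped one.
#' @param missing_rate genotype missingness rate in the released panel.
#' @param pop_ids labels of the two populations.
#' @param traits named list of per-trait overrides (`effect_corr`,
#'   `effect_var`, `sigma2_e`); defaults hold a production-like trait
#'   (highly correlated, equal variances) and an udder-health-like trait
#'   (weakly correlated, unequal variances).
#' @param seed integer seed driving all randomness of [simulate_study()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 400L, n_snp = 1200L, n_chrom = 3L,
                       chrom_length_bp = 25e6,
                       ld_decay_rate = c(6e-8, 1.02e-7),
                       fst = 0.01,
                       effect_corr = 0.3, effect_var = c(1, 2),
                       sigma2_e = 1000,
                       edc_meanlog = 4, edc_sdlog = 0.7,
                       pedigree_depth = 2L, missing_rate = 0.01,
                       pop_ids = c("PL", "DE"),
                       traits = NULL, seed = 1L) {
  stopifnot(fst > 0, fst < 1, abs(effect_corr) <= 1,
            length(ld_decay_rate) == 2L, all(ld_decay_rate > 0),
            length(effect_var) == 2L, all(effect_var > 0),
            pedigree_depth >= 1L, missing_rate >= 0, missing_rate < 1)
  if (is.null(traits)) {
    traits <- list(
      prod = list(effect_corr = 0.9, effect_var = effect_var[c(1L, 1L)],
                  sigma2_e = sigma2_e),
      scs = list(effect_corr = effect_corr, effect_var = effect_var,
                 sigma2_e = sigma2_e)
    )
  }
  traits <- lapply(traits, function(tr) {
    tr$effect_var <- setNames(as.numeric(tr$effect_var), pop_ids)
    tr
  })
  structure(
    list(n_animals = as.integer(n_animals), n_snp = as.integer(n_snp),
         n_chrom = as.integer(n_chrom), chrom_length_bp = chrom_length_bp,
         ld_decay_rate = setNames(as.numeric(ld_decay_rate), pop_ids),
         fst = fst, effect_corr = effect_corr,
         effect_var = setNames(as.numeric(effect_var), pop_ids),
         sigma2_e = sigma2_e, edc_meanlog = edc_meanlog,
         edc_sdlog = edc_sdlog, pedigree_depth = as.integer(pedigree_depth),
         missing_rate = missing_rate, pop_ids = pop_ids, traits = traits,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Draw base-population allele frequencies
#'
#' Uniform on `[0.05, 0.95]`, a flat spectrum mimicking chip-ascertained
#' markers.
#'
#' @param n_snp number of SNPs.
#' @param seed optional seed; omit to draw from the current RNG stream.
#' @return Numeric vector of frequencies.
#' @export
simulate_base_freqs <- function(n_snp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runif(n_snp, 0.05, 0.95)
}

#' Shared random marker map
#'
#' Uniformly placed, strictly increasing positions on each chromosome.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `snp_id`, `chrom`, `pos_bp`.
#' @export
simulate_map <- function(cfg) {
  per <- rep(cfg$n_snp %/% cfg$n_chrom, cfg$n_chrom)
  per[seq_len(cfg$n_snp %% cfg$n_chrom)] <- per[seq_len(cfg$n_snp %% cfg$n_chrom)] + 1L
  out <- lapply(seq_len(cfg$n_chrom), function(cc) {
    pos <- sort(sample.int(cfg$chrom_length_bp, per[cc]))
    data.frame(chrom = as.character(cc), pos_bp = pos)
  })
  map <- do.call(rbind, out)
  map$snp_id <- sprintf("snp%05d", seq_len(nrow(map)))
  map[, c("snp_id", "chrom", "pos_bp")]
}

# founder haplotypes: latent Gaussian AR(1) along each chromosome with
# adjacent correlation exp(-rate * gap_bp), thresholded at the population
# allele frequency
draw_founder_haplotypes <- function(n_hap, map, freqs, rate) {
  m <- nrow(map)
  H <- matrix(0L, n_hap, m)
  thr <- qnorm(freqs)
  for (cc in unique(map$chrom)) {
    sel <- which(map$chrom == cc)
    z <- rnorm(n_hap)
    H[, sel[1L]] <- as.integer(z < thr[sel[1L]])
    if (length(sel) > 1L) {
      for (k in 2L:length(sel)) {
        j <- sel[k]
        r <- exp(-rate * (map$pos_bp[j] - map$pos_bp[sel[k - 1L]]))
        z <- r * z + sqrt(1 - r * r) * rnorm(n_hap)
        H[, j] <- as.integer(z < thr[j])
      }
    }
  }
  H
}

#' Simulate one population: haplotypes, genotypes, pedigree
#'
#' Population allele frequencies are drawn Balding-Nichols around the base
#' frequencies (`Beta(p(1-F)/F, (1-p)(1-F)/F)`). Founder haplotypes follow a
#' first-order copying process along each chromosome whose adjacent-SNP
#' correlation decays as `exp(-rate * d_bp)`; `pedigree_depth` non-genotyped
#' generations of random mating (whole-chromosome transmission) precede the
#' final, genotyped generation. Genotypes are haplotype-pair sums recoded to
#' -1/0/+1, with missingness injected at the configured rate in the released
#' genotype panel (the phased haplotype panel stays complete).
#'
#' @param base_freqs base-population allele frequencies.
#' @param cfg a [sim_config()].
#' @param pop which population, 1 or 2 (selects label and decay rate).
#' @param map shared marker map from [simulate_map()]; drawn fresh when
#'   omitted.
#' @return A list: `haplotypes` ([haplotype_panel()] of the genotyped
#'   generation), `panel` ([genotype_panel()]), `pedigree` ([pedigree()]),
#'   `pop_freqs` (realized Balding-Nichols frequencies), `founder_freqs`
#'   (allele frequencies realized in the founder haplotype pool),
#'   `genotypes_complete` (genotype matrix before missingness).
#' @export
simulate_population <- function(base_freqs, cfg, pop = 1L, map = NULL) {
  stopifnot(inherits(cfg, "sim_config"), pop %in% c(1L, 2L))
  if (is.null(map)) map <- simulate_map(cfg)
  label <- cfg$pop_ids[pop]
  rate <- cfg$ld_decay_rate[pop]
  F <- cfg$fst
  pf <- rbeta(length(base_freqs), base_freqs * (1 - F) / F,
              (1 - base_freqs) * (1 - F) / F)
  pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
  n <- cfg$n_animals
  n_gen <- cfg$pedigree_depth + 1L
  # generation 0 founders
  hap1 <- vector("list", n_gen)
  hap2 <- vector("list", n_gen)
  Hf <- draw_founder_haplotypes(2L * n, map, pf, rate)
  hap1[[1L]] <- Hf[seq_len(n) * 2L - 1L, , drop = FALSE]
  hap2[[1L]] <- Hf[seq_len(n) * 2L, , drop = FALSE]
  ids <- lapply(seq_len(n_gen), function(g) sprintf("%s_G%d_%03d", label, g - 1L, seq_len(n)))
  ped_rows <- data.frame(animal_id = ids[[1L]], sire_id = NA_character_,
                         dam_id = NA_character_, genotyped = FALSE,
                         stringsAsFactors = FALSE)
  chrom_of <- map$chrom
  for (g in 2L:n_gen) {
    sire <- sample.int(n, n, replace = TRUE)
    dam <- sample.int(n, n, replace = TRUE)
    clash <- sire == dam
    while (any(clash)) {   # forbid selfing
      dam[clash] <- sample.int(n, sum(clash), replace = TRUE)
      clash <- sire == dam
    }
    h1 <- matrix(0L, n, nrow(map))
    h2 <- matrix(0L, n, nrow(map))
    for (cc in unique(chrom_of)) {
      sel <- chrom_of == cc
      pick_s <- runif(n) < 0.5
      pick_d <- runif(n) < 0.5
      h1[pick_s, sel] <- hap1[[g - 1L]][sire[pick_s], sel, drop = FALSE]
      h1[!pick_s, sel] <- hap2[[g - 1L]][sire[!pick_s], sel, drop = FALSE]
      h2[pick_d, sel] <- hap1[[g - 1L]][dam[pick_d], sel, drop = FALSE]
      h2[!pick_d, sel] <- hap2[[g - 1L]][dam[!pick_d], sel, drop = FALSE]
    }
    hap1[[g]] <- h1
    hap2[[g]] <- h2
    ped_rows <- rbind(ped_rows, data.frame(
      animal_id = ids[[g]], sire_id = ids[[g - 1L]][sire],
      dam_id = ids[[g - 1L]][dam], genotyped = g == n_gen,
      stringsAsFactors = FALSE))
  }
  ped <- pedigree(ped_rows$animal_id, ped_rows$sire_id, ped_rows$dam_id,
                  ped_rows$genotyped)
  Hg <- matrix(0L, 2L * n, nrow(map))
  Hg[seq_len(n) * 2L - 1L, ] <- hap1[[n_gen]]
  Hg[seq_len(n) * 2L, ] <- hap2[[n_gen]]
  geno <- hap1[[n_gen]] + hap2[[n_gen]] - 1L
  geno_released <- geno
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(length(geno)) < cfg$missing_rate, nrow(geno))
    geno_released[miss] <- NA_integer_
  }
  founder_freqs <- colMeans(Hf)
  alleles <- matrix(rep(c("A", "B"), each = nrow(map)), ncol = 2L)
  list(
    haplotypes = haplotype_panel(label, Hg, map$snp_id, map$chrom, map$pos_bp),
    panel = genotype_panel(label, ids[[n_gen]], map$snp_id, map$chrom,
                           map$pos_bp, geno_released, alleles = alleles),
    pedigree = ped,
    pop_freqs = pf,
    founder_freqs = founder_freqs,
    genotypes_complete = geno
  )
}

#' Simulate deregressed proofs for one population and trait
#'
#' `y = mu + Z g_true + e` with `Z` the complete -1/0/+1 genotype matrix,
#' `e_i ~ N(0, sigma2_e / edc_i)` and EDC drawn log-normal. By construction
#' `var(e_i) * edc_i` is constant across animals.
#'
#' @param genotypes complete genotype matrix (animals x SNPs, -1/0/+1).
#' @param animal_ids animal labels matching the rows.
#' @param g_true true per-SNP effects.
#' @param cfg a [sim_config()] (supplies EDC parameters).
#' @param sigma2_e residual variance before EDC scaling.
#' @param mu general mean.
#' @param trait trait label.
#' @return A [deregressed_proofs()] object with attribute `tbv` (true
#'   breeding values).
#' @export
simulate_proofs <- function(genotypes, animal_ids, g_true, cfg,
                            sigma2_e = cfg$sigma2_e, mu = 0, trait = "trait") {
  stopifnot(ncol(genotypes) == length(g_true))
  tbv <- as.numeric(genotypes %*% g_true)
  edc <- rlnorm(nrow(genotypes), cfg$edc_meanlog, cfg$edc_sdlog)
  y <- mu + tbv + rnorm(nrow(genotypes), 0, sqrt(sigma2_e / edc))
  pr <- deregressed_proofs(animal_ids, y, edc, trait = trait)
  attr(pr, "tbv") <- tbv
  pr
}

#' Simulate a complete two-population study
#'
#' One seeded call generates everything the pipeline consumes: a shared
#' map, base frequencies, two drifted populations with population-specific
#' LD decay, per-trait cross-population correlated true SNP effects, and
#' deregressed proofs per population and trait. All randomness flows from
#' `cfg$seed`, so equal configurations yield byte-identical studies.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_study`: `cfg`, `map`, `base_freqs`,
#'   `pops` (per-population output of [simulate_population()]), `traits`
#'   (per trait: `true_G`, `effects` matrix SNPs x 2, `sigma2_e`, `proofs`
#'   per population).
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  map <- simulate_map(cfg)
  base_freqs <- simulate_base_freqs(cfg$n_snp)
  pops <- list(simulate_population(base_freqs, cfg, 1L, map),
               simulate_population(base_freqs, cfg, 2L, map))
  names(pops) <- cfg$pop_ids
  traits <- lapply(cfg$traits, function(tr) {
    sdv <- sqrt(tr$effect_var)
    true_G <- diag(sdv) %*% matrix(c(1, tr$effect_corr, tr$effect_corr, 1), 2L) %*% diag(sdv)
    L <- chol(true_G)
    eff <- matrix(rnorm(2L * cfg$n_snp), cfg$n_snp, 2L) %*% L
    colnames(eff) <- cfg$pop_ids
    proofs <- lapply(1:2, function(p) {
      simulate_proofs(pops[[p]]$genotypes_complete,
                      pops[[p]]$panel$animal_ids, eff[, p], cfg,
                      sigma2_e = tr$sigma2_e, trait = "set_below")
    })
    names(proofs) <- cfg$pop_ids
    list(true_G = true_G, effects = eff, sigma2_e = tr$sigma2_e,
         proofs = proofs)
  })
  for (tn in names(traits)) {
    for (p in cfg$pop_ids) traits[[tn]]$proofs[[p]]$trait <- tn
  }
  structure(
    list(cfg = cfg, map = map, base_freqs = base_freqs, pops = pops,
         traits = traits),
    class = "sim_study"
  )
}

#' Write a simulated study to plain-text files
#'
#' Emits, per population, a PLINK ped/map pair, a phased-haplotype TSV and a
#' pedigree TSV, plus per-trait proofs TSVs and a truth TSV holding base and
#' realized frequencies and true effects.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(study$pops)) {
    pp <- study$pops[[p]]
    write_plink(pp$panel, file.path(dir, paste0(p, ".ped")),
                file.path(dir, paste0(p, ".map")))
    data.table::fwrite(data.table::as.data.table(pp$haplotypes$haplotypes),
                       file.path(dir, paste0(p, "_haplotypes.tsv")), sep = "\t")
    data.table::fwrite(as.data.frame(pp$pedigree),
                       file.path(dir, paste0(p, "_pedigree.tsv")), sep = "\t")
  }
  for (tn in names(study$traits)) {
    tr <- study$traits[[tn]]
    pr <- do.call(rbind, lapply(names(tr$proofs), function(p) {
      q <- tr$proofs[[p]]
      data.frame(population = p, animal_id = q$animal_ids, trait = tn,
                 debv = q$y, edc = q$edc)
    }))
    data.table::fwrite(pr, file.path(dir, paste0("proofs_", tn, ".tsv")),
                       sep = "\t")
  }
  truth <- data.frame(
    snp_id = study$map$snp_id, base_freq = study$base_freqs,
    p1_freq = study$pops[[1L]]$pop_freqs,
    p2_freq = study$pops[[2L]]$pop_freqs
  )
  for (tn in names(study$traits)) {
    truth[[paste0("g_", tn, "_", names(study$pops)[1L])]] <- study$traits[[tn]]$effects[, 1L]
    truth[[paste0("g_", tn, "_", names(study$pops)[2L])]] <- study$traits[[tn]]$effects[, 2L]
  }
  data.table::fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation r,
# by one-dimensional quadrature (no closed form needed at test scale)
binorm_cdf <- function(t1, t2, r) {
  if (abs(r) < 1e-12) return(pnorm(t1) * pnorm(t2))
  s <- sqrt(1 - r * r)
  stats::integrate(function(z) stats::dnorm(z) * pnorm((t2 - r * z) / s),
                   -8, t1, rel.tol = 1e-8)$value
}

# expected estimated r2 for a thresholded-Gaussian SNP pair: exact orthant
# probability plus the first-order finite-sample inflation of a squared
# correlation estimated from n_hap haplotypes
expected_pair_r2 <- function(r_latent, p1, p2, n_hap = Inf) {
  p11 <- binorm_cdf(qnorm(p1), qnorm(p2), r_latent)
  D <- p11 - p1 * p2
  r2 <- D * D / (p1 * (1 - p1) * p2 * (1 - p2))
  if (is.finite(n_hap)) r2 <- r2 + (1 - r2)^2 / n_hap
  min(r2, 1)
}

#' Decay-regression beta implied by a copying rate
#'
#' The generator's ground truth for the LD decay coefficient: given the map,
#' the population allele frequencies and the copying rate, the latent
#' correlation of a SNP pair at distance `d` is `exp(-rate * d)` and the
#' expected estimated r2 follows from the bivariate-normal orthant
#' probability (plus the first-order finite-sample inflation for `n_hap`
#' haplotypes). Expected r2 values are averaged over the nine distance
#' intervals with the map's actual pair counts and the decay regression
#' `r2 = alpha + beta / sqrt(d)` is fitted to the expected bin means. Bins
#' are subsampled to at most `max_pairs_per_bin` pairs (deterministically)
#' to bound the quadrature cost.
#'
#' @param map data.frame with `chrom`, `pos_bp`.
#' @param freqs per-SNP allele frequencies.
#' @param rate copying decay rate per bp.
#' @param n_hap number of haplotypes behind the empirical r2 estimates
#'   (`Inf` for the noiseless curve).
#' @param max_pairs_per_bin quadrature budget per bin.
#' @return The implied beta (Mbp^-1/2 scale, matching [fit_decay()]).
#' @export
implied_decay_beta <- function(map, freqs, rate, n_hap = Inf,
                               max_pairs_per_bin = 400L) {
  bins <- ld_bins()
  pairs <- list()
  for (cc in unique(map$chrom)) {
    sel <- which(map$chrom == cc)
    pos <- map$pos_bp[sel]
    dd <- outer(pos, pos, function(a, b) b - a)
    idx <- which(dd > 0 & dd <= 5e6, arr.ind = TRUE)
    pairs[[cc]] <- data.frame(i = sel[idx[, 1L]], j = sel[idx[, 2L]],
                              d_bp = pos[idx[, 2L]] - pos[idx[, 1L]])
  }
  pairs <- do.call(rbind, pairs)
  bi <- findInterval(pairs$d_bp / 1e6, bins$lower)
  mean_r2 <- rep(NA_real_, nrow(bins))
  for (k in seq_len(nrow(bins))) {
    rows <- which(bi == k)
    if (!length(rows)) next
    if (length(rows) > max_pairs_per_bin) {
      rows <- rows[round(seq(1L, length(rows), length.out = max_pairs_per_bin))]
    }
    mean_r2[k] <- mean(vapply(rows, function(q) {
      expected_pair_r2(exp(-rate * pairs$d_bp[q]),
                       freqs[pairs$i[q]], freqs[pairs$j[q]], n_hap)
    }, 0))
  }
  use <- !is.na(mean_r2)
  if (sum(use) < 3L) stop("fewer than 3 occupied bins in the map")
  x <- 1 / sqrt(bins$d_upper[use])
  unname(coef(lm(mean_r2[use] ~ x))[2L])
}
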