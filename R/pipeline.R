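#' Run the full two-population comparison pipeline
#'
#' Executes every stage on a dataset bundle: per-population marker QC and
#' intersection, LD records/binning/decay fits and paired interval tests,
#' SNP-BLUP per population and trait, base-population allele frequencies
#' and their agreement, the window-length scan of regional differences with
#' BH-FDR control, and the bivariate cross-population (co)variance fit per
#' trait. Defaults are the study's canonical settings: MAF 0.01, call rate
#' 0.90, the nine LD intervals, window lengths 0.3-1.5 Mbp in steps of
#' 0.1 Mbp, FDR 0.10.
#'
#' @param study a [simulate_study()] bundle, or an equivalently shaped list
#'   with `pops` (each holding `panel`, `haplotypes`, `pedigree`) and
#'   `traits` (each holding `proofs` per population and `sigma2_e`).
#' @param maf_min,callrate_min QC thresholds.
#' @param window_lengths_bp grid of window lengths for the regional scan.
#' @param fdr_q FDR level for window significance.
#' @param lambda_gc variance ratio of the gene-content BLUP.
#' @param snp_blup_tol,snp_blup_max_iter solver controls.
#' @param sigma2_a optional named-per-trait total additive variances; by
#'   default taken from the generator truth (`n_snp * effect_var`) when
#'   `study` carries a `cfg`.
#' @param sigma2_e optional named-per-trait residual variances; defaults to
#'   each trait's `sigma2_e` element.
#' @param out_dir optional directory: when given, every stage writes its
#'   TSV outputs there.
#' @return An object of class `popstrat_run`: `qc`, `panels`, `ld`
#'   (records, bins, fits, paired tests), `effects`, `base_freqs`,
#'   `freq_agreement`, `window_scan`, `crosspop`, `config`.
#' @export
run_full_analysis <- function(study,
                              maf_min = 0.01, callrate_min = 0.90,
                              window_lengths_bp = seq(3e5, 15e5, by = 1e5),
                              fdr_q = 0.10, lambda_gc = 0.01,
                              snp_blup_tol = 1e-10, snp_blup_max_iter = 20000L,
                              sigma2_a = NULL, sigma2_e = NULL,
                              out_dir = NULL) {
  pop_ids <- names(study$pops)
  stopifnot(length(pop_ids) == 2L)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: QC per population, then marker intersection
  qc <- lapply(study$pops, function(p) filter_panel(p$panel, maf_min, callrate_min))
  inter <- intersect_panels(qc[[1L]]$panel, qc[[2L]]$panel)
  panels <- list(inter$a, inter$b)
  names(panels) <- pop_ids
  snp_ids <- panels[[1L]]$snp_ids
  message(sprintf("qc: %d / %d SNPs retained (%s: %d, %s: %d before intersection)",
                  length(snp_ids), qc[[1L]]$n_input,
                  pop_ids[1L], qc[[1L]]$n_retained,
                  pop_ids[2L], qc[[2L]]$n_retained))

  ## stage 2: LD on the intersected marker set
  haps <- lapply(study$pops, function(p) subset_snps(p$haplotypes, snp_ids))
  ld_rec <- lapply(haps, ld_records)
  ld_bins_ <- lapply(ld_rec, bin_ld)
  ld_fits <- lapply(ld_bins_, fit_decay)
  ld_paired <- paired_ld_tests(ld_rec[[1L]], ld_rec[[2L]])
  message(sprintf("ld: beta %s=%.4f %s=%.4f (ratio %.2f)", pop_ids[1L],
                  ld_fits[[1L]]$beta, pop_ids[2L], ld_fits[[2L]]$beta,
                  ld_fits[[2L]]$beta / ld_fits[[1L]]$beta))

  ## stage 3: base-population allele frequencies (gene-content BLUP)
  base_freqs <- lapply(pop_ids, function(p) {
    estimate_base_freqs(study$pops[[p]]$pedigree, panels[[p]], lambda = lambda_gc)
  })
  names(base_freqs) <- pop_ids
  agreement <- base_freq_agreement(base_freqs[[1L]], base_freqs[[2L]])
  message(sprintf("basefreq: cross-population correlation %.3f (slope %.3f)",
                  agreement$pearson_r, agreement$slope))

  ## stage 4: SNP-BLUP per trait and population
  trait_names <- names(study$traits)
  n_snp <- length(snp_ids)
  effects <- lapply(trait_names, function(tn) {
    tr <- study$traits[[tn]]
    out <- lapply(pop_ids, function(p) {
      s2a <- if (!is.null(sigma2_a)) {
        sigma2_a[[tn]][[p]]
      } else if (!is.null(study$cfg)) {
        # generator truth: per-SNP effect variance times marker count
        ev <- study$cfg$traits[[tn]]$effect_var
        n_snp * if (!is.null(names(ev))) ev[[p]] else ev[[match(p, pop_ids)]]
      } else {
        stop("sigma2_a required when the study carries no generator config")
      }
      s2e <- if (!is.null(sigma2_e)) sigma2_e[[tn]] else tr$sigma2_e
      solve_snp_blup(panels[[p]], tr$proofs[[p]],
                     variance_spec(s2a, s2e, n_snp),
                     tol = snp_blup_tol, max_iter = snp_blup_max_iter)
    })
    names(out) <- pop_ids
    out
  })
  names(effects) <- trait_names

  ## stage 5: window scan per trait
  scans <- lapply(trait_names, function(tn) {
    window_scan(effects[[tn]][[1L]], effects[[tn]][[2L]],
                base_freqs[[1L]], base_freqs[[2L]],
                lengths_bp = window_lengths_bp, q_max = fdr_q)
  })
  names(scans) <- trait_names

  ## stage 6: cross-population (co)variance per trait
  crosspop <- lapply(trait_names, function(tn) {
    fit_bivariate(effect_pairs(effects[[tn]][[1L]], effects[[tn]][[2L]]))
  })
  names(crosspop) <- trait_names
  for (tn in trait_names) {
    message(sprintf("crosspop %s: rho_g=%.3f ratio=%.2f", tn,
                    crosspop[[tn]]$rho_g, variance_ratio(crosspop[[tn]])))
  }

  run <- structure(
    list(qc = qc, panels = panels,
         ld = list(records = ld_rec, bins = ld_bins_, fits = ld_fits,
                   paired = ld_paired),
         effects = effects, base_freqs = base_freqs,
         freq_agreement = agreement, window_scan = scans,
         crosspop = crosspop,
         config = list(maf_min = maf_min, callrate_min = callrate_min,
                       window_lengths_bp = window_lengths_bp, fdr_q = fdr_q,
                       lambda_gc = lambda_gc, snp_blup_tol = snp_blup_tol,
                       seed = if (!is.null(study$cfg)) study$cfg$seed else NA)),
    class = "popstrat_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write pipeline stage outputs as TSV files
#'
#' @param run a `popstrat_run`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop_ids <- names(run$panels)
  for (p in pop_ids) {
    write_qc_report(run$qc[[p]], file.path(dir, paste0("qc_", p, ".tsv")))
    data.table::fwrite(run$ld$records[[p]],
                       file.path(dir, paste0("ld_records_", p, ".tsv")), sep = "\t")
    data.table::fwrite(run$ld$bins[[p]],
                       file.path(dir, paste0("ld_bins_", p, ".tsv")), sep = "\t")
    data.table::fwrite(
      data.frame(snp_id = run$base_freqs[[p]]$snp_ids,
                 p_base = unname(run$base_freqs[[p]]$p_base)),
      file.path(dir, paste0("base_freqs_", p, ".tsv")), sep = "\t")
  }
  for (tn in names(run$effects)) {
    for (p in pop_ids) {
      write_effects(run$effects[[tn]][[p]], run$base_freqs[[p]],
                    file.path(dir, paste0("effects_", tn, "_", p, ".tsv")))
    }
    data.table::fwrite(run$window_scan[[tn]],
                       file.path(dir, paste0("window_scan_", tn, ".tsv")), sep = "\t")
    fit <- run$crosspop[[tn]]
    data.table::fwrite(
      data.frame(key = c("G11", "G22", "G12", "sigma2_eps", "rho_g", "ratio",
                         "n_iter"),
                 value = c(fit$G[1, 1], fit$G[2, 2], fit$G[1, 2],
                           fit$sigma2_eps, fit$rho_g, variance_ratio(fit),
                           fit$n_iter)),
      file.path(dir, paste0("crosspop_", tn, ".tsv")), sep = "\t")
  }
  summ <- data.frame(
    key = c("n_snp_retained",
            paste0("ld_alpha_", pop_ids), paste0("ld_beta_", pop_ids),
            "ld_beta_ratio", "base_freq_correlation"),
    value = c(length(run$panels[[1L]]$snp_ids),
              run$ld$fits[[1L]]$alpha, run$ld$fits[[2L]]$alpha,
              run$ld$fits[[1L]]$beta, run$ld$fits[[2L]]$beta,
              run$ld$fits[[2L]]$beta / run$ld$fits[[1L]]$beta,
              run$freq_agreement$pearson_r)
  )
  data.table::fwrite(summ, file.path(dir, "summary.tsv"), sep = "\t")
  invisible(dir)
}

#' @export
print.popstrat_run <- function(x, ...) {
  pop_ids <- names(x$panels)
  cat("popstrat run\n")
  cat(sprintf("  markers: %d after QC + intersection\n",
              length(x$panels[[1L]]$snp_ids)))
  cat(sprintf("  LD decay beta: %s=%.4f %s=%.4f (ratio %.2f)\n",
              pop_ids[1L], x$ld$fits[[1L]]$beta, pop_ids[2L],
              x$ld$fits[[2L]]$beta,
              x$ld$fits[[2L]]$beta / x$ld$fits[[1L]]$beta))
  cat(sprintf("  base-frequency agreement: r=%.3f slope=%.3f\n",
              x$freq_agreement$pearson_r, x$freq_agreement$slope))
  for (tn in names(x$crosspop)) {
    cat(sprintf("  %s: rho_g=%.3f, variance ratio=%.2f, signif. windows (mean over lengths)=%.1f%%\n",
                tn, x$crosspop[[tn]]$rho_g, variance_ratio(x$crosspop[[tn]]),
                100 * mean(x$window_scan[[tn]]$prop_significant)))
  }
  invisible(x)
}
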