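#' Pair SNP-effect estimates of two populations
#'
#' Joins two `snp_effect_set` objects on SNP id. Column order fixes the
#' population convention used downstream: `pop1` is the first argument
#' (e.g. PL), `pop2` the second (e.g. DE); [variance_ratio()] reports
#' `G22 / G11`, i.e. pop2 over pop1.
#'
#' @param eff_1,eff_2 `snp_effect_set` objects.
#' @return An object of class `effect_pairs`: a data.frame with `snp_id`,
#'   `ghat_1`, `ghat_2` and attributes `pops` and `trait`.
#' @export
effect_pairs <- function(eff_1, eff_2) {
  shared <- intersect(eff_1$snp_ids, eff_2$snp_ids)
  if (!length(shared)) stop("no shared SNPs")
  d <- data.frame(
    snp_id = shared,
    ghat_1 = unname(eff_1$g_hat[match(shared, eff_1$snp_ids)]),
    ghat_2 = unname(eff_2$g_hat[match(shared, eff_2$snp_ids)]),
    stringsAsFactors = FALSE
  )
  attr(d, "pops") <- c(eff_1$population_id, eff_2$population_id)
  attr(d, "trait") <- eff_1$trait
  class(d) <- c("effect_pairs", "data.frame")
  d
}

#' Bivariate EM-REML for the cross-population SNP-effect (co)variance
#'
#' Fits `ghat = P mu + Z q + eps` where the two rows per SNP are the effect
#' estimates of the two populations, `mu` holds one mean per population,
#' `q ~ N(0, I (x) G)` with `G` the 2x2 SNP-effect (co)variance matrix
#' between populations, and `eps ~ N(0, I sigma2_eps)` with a single shared
#' residual variance. Estimation is EM-REML on the per-SNP sufficient
#' statistics (the likelihood is iid bivariate normal across SNPs with
#' covariance `V = G + sigma2_eps I`); the restricted log-likelihood is
#' non-decreasing across iterations and convergence is declared on its
#' relative change.
#'
#' **Identifiability.** With one observation per SNP per population the
#' likelihood depends on `(G, sigma2_eps)` only through `V`: the off-diagonal
#' `G12 = V12` and the marginal totals `V11`, `V22` are identified, but the
#' split of each diagonal into genetic and residual parts is not — any
#' `sigma2_eps` in `[0, lambda_min(V)]` yields the same likelihood. The EM
#' therefore converges to a point on that ridge determined by its
#' initialization, which here is the documented equal split
#' (`G0 = S / 2`, `sigma2_0 = mean(diag(S)) / 2` with `S` the REML sample
#' covariance). The derived genetic correlation inherits this convention.
#' When the sample covariance is singular (e.g. the two effect vectors are
#' identical) the ridge collapses and `sigma2_eps` is driven to 0.
#'
#' @param pairs an [effect_pairs()] data.frame (or any data.frame whose
#'   second and third columns hold the two effect vectors).
#' @param tol relative change of the restricted log-likelihood below which
#'   iteration stops.
#' @param max_iter maximum EM iterations.
#' @return An object of class `crosspop_fit`: `G` (2x2, dimnames from the
#'   population labels), `sigma2_eps`, `rho_g`, `mu`, `V` (the identified
#'   total covariance), `converged`, `n_iter`, `loglik`.
#' @export
fit_bivariate <- function(pairs, tol = 1e-10, max_iter = 10000L) {
  Y <- cbind(pairs[[2L]], pairs[[3L]])
  if (!all(is.finite(Y))) stop("non-finite effect estimates")
  m <- nrow(Y)
  if (m < 50L) stop("need >= 50 SNPs for a meaningful (co)variance fit")
  pops <- attr(pairs, "pops")
  if (is.null(pops)) pops <- c("pop1", "pop2")
  mu <- colMeans(Y)                       # GLS = OLS here (common design)
  Yc <- sweep(Y, 2L, mu)
  S <- crossprod(Yc) / (m - 1)            # REML sample covariance
  G <- S / 2
  s2 <- mean(diag(S)) / 2
  inv2 <- function(V) {
    ev <- eigen(V, symmetric = TRUE)
    if (ev$values[2L] <= 1e-13 * max(ev$values[1L], 1e-300)) return(NULL)
    ev$vectors %*% diag(1 / ev$values) %*% t(ev$vectors)
  }
  reml_ll <- function(G, s2) {
    V <- G + diag(s2, 2L)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return(-Inf)
    W <- inv2(V)
    if (is.null(W)) return(-Inf)
    -0.5 * (m - 1) * (log(ev[1L]) + log(ev[2L]) + sum(W * S))
  }
  ll_old <- reml_ll(G, s2)
  converged <- FALSE
  flag_psd <- FALSE
  boundary <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    V <- G + diag(s2, 2L)
    W <- inv2(V)
    if (is.null(W)) {   # total covariance (near-)singular: parameter boundary
      boundary <- TRUE
      converged <- TRUE
      break
    }
    Gn <- G - G %*% W %*% G + G %*% W %*% S %*% W %*% G
    Gn <- (Gn + t(Gn)) / 2
    s2n <- s2 + (s2^2 / 2) * (sum(diag(W %*% S %*% W)) - sum(diag(W)))
    ev <- eigen(Gn, symmetric = TRUE)
    if (any(ev$values < 0)) {             # project to nearest PSD
      flag_psd <- TRUE
      ev$values <- pmax(ev$values, 0)
      Gn <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    }
    s2n <- max(s2n, 0)
    G <- Gn
    s2 <- s2n
    ll <- reml_ll(G, s2)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll) + 1e-300)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("EM-REML did not converge in ", max_iter, " iterations")
  dimnames(G) <- list(pops, pops)
  denom <- sqrt(G[1L, 1L] * G[2L, 2L])
  rho <- if (denom > 0) G[1L, 2L] / denom else NA_real_
  rho <- min(max(rho, -1), 1)
  structure(
    list(G = G, sigma2_eps = s2, rho_g = rho,
         mu = setNames(mu, pops), V = S, converged = converged,
         n_iter = it, loglik = ll_old, psd_projected = flag_psd,
         boundary = boundary, n_snp = m, trait = attr(pairs, "trait")),
    class = "crosspop_fit"
  )
}

#' @export
print.crosspop_fit <- function(x, ...) {
  cat(sprintf("crosspop_fit (%d SNPs): G11=%.4g G22=%.4g G12=%.4g  sigma2_eps=%.4g  rho_g=%.3f\n",
              x$n_snp, x$G[1, 1], x$G[2, 2], x$G[1, 2], x$sigma2_eps, x$rho_g))
  invisible(x)
}

#' Ratio of the two populations' SNP-effect variances
#'
#' `G22 / G11`: the second population's variance over the first's (with the
#' `effect_pairs(PL, DE)` convention, DE over PL).
#'
#' @param fit a `crosspop_fit`.
#' @return The variance ratio.
#' @export
variance_ratio <- function(fit) {
  stopifnot(inherits(fit, "crosspop_fit"))
  if (fit$G[1L, 1L] <= 0 || fit$G[2L, 2L] <= 0) {
    stop("variance ratio undefined: zero diagonal in G")
  }
  fit$G[2L, 2L] / fit$G[1L, 1L]
}
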