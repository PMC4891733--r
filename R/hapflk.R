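# hapFLK: FLK applied to local haplotype-cluster frequencies from a
# fastPHASE-style hidden Markov LD model fitted by EM.

#' Fit the haplotype-cluster hidden Markov model
#'
#' fastPHASE-style model: each haplotype follows a hidden cluster path along
#' the chromosome; between adjacent loci it stays in its cluster with
#' probability `1 - rho_l` or jumps to a cluster drawn from the weights
#' `alpha`; cluster `k` emits the alternate allele at locus `l` with
#' probability `theta[l, k]`.  Fitted by EM (scaled forward-backward
#' E-step in compiled code); each of `n_fits` independent restarts is run
#' until the change in mean log-likelihood per haplotype-locus drops below
#' `em_tol` or `max_iter` iterations.  The log-likelihood trace of every
#' fit is non-decreasing (EM guarantee), up to the tiny clamping of
#' `theta` away from 0/1.
#'
#' Missing genotypes are not supported: impute to the major allele first
#' (see `impute_major()`).
#'
#' @param gm haploid [genotype_matrix()] of one chromosome (no missing
#'   calls), or a 0/1 haplotype matrix (samples x sites).
#' @param K number of haplotype clusters (>= 2).
#' @param n_fits independent EM restarts.
#' @param em_tol convergence tolerance on the change in mean log-likelihood
#'   per haplotype-locus.
#' @param max_iter maximum EM iterations per fit.
#' @param seed integer seed (one restart seed derived per fit).
#' @return List of `n_fits` objects of class `hap_cluster_model`, each with
#'   `theta`, `alpha`, `rho`, `loglik_trace`, `popfreq` (K x npop x L
#'   posterior cluster frequencies per population) and `populations`.
#' @export
fit_cluster_model <- function(gm, K = 10, n_fits = 20, em_tol = 1e-5,
                              max_iter = 200, seed = 1) {
  if (inherits(gm, "genotype_matrix")) {
    H <- gm$calls
    if (any(is.na(H))) stop("missing calls: impute first (impute_major)")
    if (any(H == CALL_HET)) stop("haploid 0/1 haplotypes required")
    pops <- gm$samples$population
  } else {
    H <- as.matrix(gm)
    pops <- rep("ALL", nrow(H))
  }
  storage.mode(H) <- "integer"
  stopifnot(K >= 2)
  n <- nrow(H); L <- ncol(H)
  ndistinct <- length(unique(apply(H, 1, paste, collapse = "")))
  if (K > ndistinct)
    warning("K exceeds the number of distinct haplotypes (", ndistinct, ")")
  poplev <- unique(pops)
  popidx <- match(pops, poplev)
  pfreq <- colMeans(H)
  fits <- vector("list", n_fits)
  for (f in seq_len(n_fits)) {
    fits[[f]] <- withr_seed(seed + 1000L * f, {
      theta <- matrix(pmin(pmax(rep(pfreq, K) +
                                  rnorm(L * K, 0, 0.15), 0.01), 0.99), L, K)
      alpha <- rep(1 / K, K)
      rho <- rep(0.1, max(L - 1, 1))
      trace <- numeric(0)
      est <- NULL
      for (it in seq_len(max_iter)) {
        est <- .cluster_em_estep(H, theta, alpha, rho, popidx,
                                 length(poplev))
        trace <- c(trace, est$loglik)
        if (it >= 2 &&
            (trace[it] - trace[it - 1]) / (n * L) < em_tol) break
        # M-step (exact MLE; theta clamped for numerical safety)
        den <- est$thden
        theta <- ifelse(den > 0, est$thnum / pmax(den, 1e-300), 0.5)
        theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
        if (L > 1) {
          rho <- pmin(pmax(est$njump / n, 1e-6), 1 - 1e-6)
          ac <- est$init_counts + colSums(est$jump_in)
        } else ac <- est$init_counts
        alpha <- pmax(ac, 1e-12) / sum(pmax(ac, 1e-12))
      }
      structure(list(theta = theta, alpha = alpha, rho = rho,
                     loglik_trace = trace, popfreq = est$popfreq,
                     populations = poplev, K = K),
                class = "hap_cluster_model")
    })
  }
  fits
}

#' Impute missing haploid calls to the per-site major allele
#'
#' @param gm haploid [genotype_matrix()].
#' @return [genotype_matrix()] without missing calls (haploid het calls are
#'   also replaced, as the cluster model consumes clean 0/1 haplotypes).
#' @export
impute_major <- function(gm) {
  calls <- gm$calls
  calls[calls == CALL_HET] <- NA_integer_
  maj <- as.integer(colMeans(calls == CALL_ALT, na.rm = TRUE) >= 0.5)
  maj[is.na(maj)] <- 0L
  na_idx <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(na_idx)) calls[na_idx] <- maj[na_idx[, 2]]
  gm$calls <- calls
  gm$het_mode <- FALSE
  gm
}

#' hapFLK statistic from fitted cluster models
#'
#' At each locus, posterior cluster frequencies per population are read
#' from each fitted model; the hapFLK value is the sum over clusters of the
#' FLK quadratic form applied to that cluster's population frequency
#' vector (ancestral cluster frequency estimated per cluster by GLS, as
#' for a biallelic site), averaged over the independent EM fits.
#'
#' @param models list of fits from [fit_cluster_model()].
#' @param F kinship matrix; rownames must cover the model populations.
#' @return Numeric vector of per-locus hapFLK values.
#' @export
hapflk_statistic <- function(models, F) {
  stopifnot(length(models) >= 1)
  pops <- models[[1]]$populations
  if (!all(pops %in% rownames(F)))
    stop("kinship matrix lacks populations: ",
         paste(setdiff(pops, rownames(F)), collapse = ", "))
  F <- F[pops, pops, drop = FALSE]
  npop <- length(pops)
  if (npop < 2) stop("need at least 2 populations with >= 2 haplotypes")
  Finv <- solve_kinship(F)
  w <- as.vector(Finv %*% rep(1, npop)); sw <- sum(w)
  per_fit <- vapply(models, function(m) {
    pf <- m$popfreq                       # K x npop x L
    K <- dim(pf)[1]; L <- dim(pf)[3]
    tot <- numeric(L)
    for (k in seq_len(K)) {
      P <- matrix(pf[k, , ], npop, L)     # npop x L cluster frequencies
      p0 <- as.vector(crossprod(P, w)) / sw
      ok <- p0 > 1e-6 & p0 < 1 - 1e-6
      Pt <- sweep(P, 2, p0, `-`)
      Pt <- sweep(Pt, 2, sqrt(p0 * (1 - p0)), `/`)
      Tk <- colSums((Finv %*% Pt) * Pt)
      Tk[!ok] <- 0
      tot <- tot + Tk
    }
    tot
  }, numeric(dim(models[[1]]$popfreq)[3]))
  rowMeans(as.matrix(per_fit))
}

#' Full hapFLK selection scan on one chromosome
#'
#' Composes the pipeline: haplotype-cluster model fits, per-locus hapFLK,
#' empirical chi-squared p-value calibration, significance-region calling,
#' and spectral-decomposition assignment of the population under selection
#' (selection measures computed from the single-SNP FLK eigenvector
#' contributions, as in the source method).
#'
#' @param gm haploid [genotype_matrix()] of one chromosome.
#' @param F kinship matrix (rownames = populations of `gm`).
#' @param K,n_fits,em_tol,max_iter,seed cluster-model parameters
#'   (see [fit_cluster_model()]).
#' @param alpha,chain_bp,flank_bp region-calling parameters
#'   (see [call_regions()]).
#' @param sample_correction apply [kinship_sample_correction()] for the
#'   cohort's per-population sample sizes (recommended whenever `F` is the
#'   drift co-ancestry rather than the covariance of observed sample
#'   frequencies).
#' @return List with `track` (`chrom, pos, hapflk, p_value`), `flk`
#'   ([flk_scan()] result), `regions` (with `assigned_population` and
#'   selection measures), `chi2_fit` and `models`.
#' @export
hapflk_scan <- function(gm, F, K = 10, n_fits = 20, em_tol = 1e-5,
                        max_iter = 200, seed = 1, alpha = 1e-4,
                        chain_bp = 2000, flank_bp = 10000,
                        sample_correction = TRUE) {
  gm2 <- impute_major(gm)
  pops <- unique(gm2$samples$population)
  if (min(table(gm2$samples$population)) < 2)
    stop("every population needs >= 2 haplotypes")
  F <- as.matrix(F)[pops, pops, drop = FALSE]
  if (sample_correction) {
    nper <- as.integer(table(gm2$samples$population)[pops])
    F <- kinship_sample_correction(F, nper,
                                   ploidy = gm2$samples$ploidy[1])
  }
  models <- fit_cluster_model(gm2, K = K, n_fits = n_fits,
                              em_tol = em_tol, max_iter = max_iter,
                              seed = seed)
  hap <- hapflk_statistic(models, F)
  cal <- pvalues_from_chi2(hap)
  track <- data.frame(chrom = gm2$sites$chrom, pos = gm2$sites$pos,
                      hapflk = hap, p_value = cal$p_values,
                      stringsAsFactors = FALSE)
  freq <- pop_freq_table(gm2)[pops, , drop = FALSE]
  flk <- flk_scan(freq, F, sites = gm2$sites)
  regions <- call_regions(track, alpha = alpha, chain_bp = chain_bp,
                          flank_bp = flank_bp)
  if (nrow(regions)) {
    asg <- lapply(seq_len(nrow(regions)), function(i)
      assign_population(regions[i, ], flk))
    regions$assigned_population <-
      vapply(asg, function(a) a$assigned_population, character(1))
    regions$eigenvector <- vapply(asg, function(a) a$eigenvector,
                                  integer(1))
    regions$measures <- I(lapply(asg, function(a) a$measures))
  } else {
    regions$assigned_population <- character(0)
    regions$eigenvector <- integer(0)
  }
  list(track = track, flk = flk, regions = regions, chi2_fit = cal,
       models = models)
}
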