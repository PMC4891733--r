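# FLK: allele-frequency differentiation test against a drift covariance
# model, its spectral decomposition, p-value calibration, region calling
# and assignment of the population under selection.

#' Estimate the ancestral allele frequency under the drift model
#'
#' Generalized-least-squares estimator
#' `p0 = (1' F^-1 p) / (1' F^-1 1)`, i.e. the minimizer of
#' `(p - c 1)' F^-1 (p - c 1)` over `c`, clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param p population allele-frequency vector.
#' @param F kinship matrix (invertible).
#' @return Estimated ancestral frequency.
#' @export
estimate_p0 <- function(p, F) {
  Finv <- solve_kinship(F)
  w <- as.vector(Finv %*% rep(1, nrow(F)))
  est <- sum(w * p) / sum(w)
  min(max(est, 1e-6), 1 - 1e-6)
}

#' Sample-size correction of the kinship matrix
#'
#' The covariance of *observed* population allele frequencies adds binomial
#' sampling noise to the drift covariance:
#' `Var(p_hat_i) = p0 (1 - p0) (F_ii + (1 - F_ii) / (ploidy * n_i))`.
#' Scans on sample frequencies should use the corrected matrix; scans on
#' true population frequencies (or very large samples) should not.
#'
#' @param F kinship matrix.
#' @param n_per_pop samples per population, in `F`'s row order (recycled).
#' @param ploidy 1 for haploid drones, 2 for diploids.
#' @return Corrected kinship matrix.
#' @export
kinship_sample_correction <- function(F, n_per_pop, ploidy = 1) {
  F <- as.matrix(F)
  n <- rep_len(n_per_pop, nrow(F))
  F + diag((1 - diag(F)) / (ploidy * n), nrow(F))
}

solve_kinship <- function(F) {
  F <- as.matrix(F)
  out <- tryCatch(solve(F), error = function(e)
    stop("kinship matrix is singular"))
  out
}

#' Spectral decomposition of the kinship matrix
#'
#' Decomposes `F = Q' D Q` with `Q` orthogonal (rows are eigenvectors) and
#' `D` diagonal.  `Q[i, j]` is the loading of population `j` in eigenvector
#' `i`; large absolute loadings pinpoint the population an eigenvector
#' represents.
#'
#' @param F kinship matrix.
#' @return Object of class `eigen_system` with `Q` (rows = eigenvectors),
#'   `D` (eigenvalues) and `populations`.
#' @export
eigen_system <- function(F) {
  F <- as.matrix(F)
  es <- eigen(F, symmetric = TRUE)
  structure(list(Q = t(es$vectors), D = es$values,
                 populations = rownames(F)),
            class = "eigen_system")
}

#' FLK statistic for one site
#'
#' Scaled frequency deviations `pt = (p - p0 1) / sqrt(p0 (1 - p0))` give
#' `T = pt' F^-1 pt`, and through the spectral decomposition
#' `u = D^(-1/2) Q pt` with `T = sum(u^2)`, so each `u[i]` is the
#' contribution of eigenvector `i` to the test.  A site whose estimated
#' ancestral frequency is clipped at the boundary (monomorphic across
#' populations) returns `T = 0`, `u = 0` and `flagged = TRUE`.
#'
#' @param p population allele-frequency vector.
#' @param F kinship matrix.
#' @param eig optional precomputed [eigen_system()] of `F`.
#' @return List with `T`, `u`, `p0` and `flagged`.
#' @export
flk_statistic <- function(p, F, eig = eigen_system(F)) {
  p0 <- estimate_p0(p, F)
  if (p0 <= 1e-6 || p0 >= 1 - 1e-6)
    return(list(T = 0, u = rep(0, length(p)), p0 = p0, flagged = TRUE))
  pt <- (p - p0) / sqrt(p0 * (1 - p0))
  u <- as.vector((eig$Q %*% pt) / sqrt(eig$D))
  list(T = sum(u^2), u = u, p0 = p0, flagged = FALSE)
}

#' Genome-wide FLK scan
#'
#' Vectorized [flk_statistic()] over all sites of a frequency table, with
#' p-values from the chi-squared distribution with `npop - 1` degrees of
#' freedom (one degree absorbed by the estimated ancestral frequency).
#'
#' @param freq npop x nsites frequency matrix (rownames = populations).
#' @param F kinship matrix in the same population order.
#' @param sites optional `data.frame(chrom, pos)` to carry through.
#' @return Object of class `flk_result`: `data.frame(chrom, pos, p0, T,
#'   p_value, flagged)` with the eigenvector contribution matrix in
#'   attribute `u` (nsites x npop) and the [eigen_system()] in attribute
#'   `eigen`.
#' @export
flk_scan <- function(freq, F, sites = NULL) {
  stopifnot(nrow(freq) == nrow(F))
  if (!is.null(rownames(freq)) && !is.null(rownames(F)) &&
      !identical(rownames(freq), rownames(F)))
    freq <- freq[rownames(F), , drop = FALSE]
  npop <- nrow(F)
  eig <- eigen_system(F)
  Finv <- solve_kinship(F)
  w <- as.vector(Finv %*% rep(1, npop))
  p0 <- as.vector(crossprod(freq, w)) / sum(w)
  p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  flagged <- p0 <= 1e-6 | p0 >= 1 - 1e-6
  Pt <- sweep(freq, 2, p0, `-`)
  Pt <- sweep(Pt, 2, sqrt(p0 * (1 - p0)), `/`)
  U <- t((eig$Q %*% Pt) / sqrt(eig$D))         # nsites x npop
  T <- rowSums(U^2)
  T[flagged] <- 0
  U[flagged, ] <- 0
  out <- data.frame(
    chrom = if (is.null(sites)) "1" else sites$chrom,
    pos = if (is.null(sites)) seq_along(T) else sites$pos,
    p0 = p0, T = T,
    p_value = pchisq(T, df = npop - 1, lower.tail = FALSE),
    flagged = flagged, stringsAsFactors = FALSE)
  attr(out, "u") <- U
  attr(out, "eigen") <- eig
  class(out) <- c("flk_result", "data.frame")
  out
}

#' Calibrate p-values from an empirical scaled chi-squared fit
#'
#' Robustly fits `values ~ a * chisq(d)` on the genome-wide distribution:
#' `(a, d)` are chosen so that the theoretical mean and variance of the
#' scaled chi-squared *truncated below the empirical 95th percentile* match
#' the observed trimmed moments (outliers — e.g. swept regions — live in
#' the discarded top tail and do not distort the null fit).  P-values are
#' the upper chi-squared tail of `value / a` at `d` degrees of freedom.
#'
#' @param values non-negative statistic values (e.g. hapFLK).
#' @param trim lower quantile fraction retained for moment matching.
#' @return List with `p_values`, `a`, `d` and the trim cutoff.
#' @export
pvalues_from_chi2 <- function(values, trim = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 1000)
    warning("fewer than 1000 loci: chi-squared calibration is unstable")
  if (var(values) == 0) stop("constant statistic values: cannot calibrate")
  cut <- as.numeric(quantile(values, trim))
  keep <- values[values <= cut]
  m_obs <- mean(keep); v_obs <- var(keep)
  # theoretical trimmed moments of a*chisq(d) truncated at `cut`
  trimmed_moments <- function(a, d) {
    P <- pchisq(cut / a, d)
    if (P <= 0) return(c(NA, NA))
    m1 <- a * d * pchisq(cut / a, d + 2) / P
    m2 <- a^2 * d * (d + 2) * pchisq(cut / a, d + 4) / P
    c(m1, m2 - m1^2)
  }
  obj <- function(par) {
    a <- exp(par[1]); d <- exp(par[2])
    mm <- trimmed_moments(a, d)
    if (anyNA(mm)) return(1e10)
    log(mm[1] / m_obs)^2 + log(mm[2] / v_obs)^2
  }
  d0 <- max(2 * m_obs^2 / max(v_obs, 1e-12), 0.5)
  a0 <- max(v_obs / (2 * m_obs), 1e-6)
  opt <- optim(c(log(a0), log(d0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  a <- exp(opt$par[1]); d <- exp(opt$par[2])
  list(p_values = pchisq(values / a, d, lower.tail = FALSE),
       a = a, d = d, trim_cutoff = cut)
}

#' Call candidate selection regions from a p-value track
#'
#' Significant positions (`p <= alpha`) on the same chromosome are chained
#' while consecutive gaps are at most `chain_bp`; each chain becomes the
#' region `[min - flank_bp, max + flank_bp]` (clipped at 1), and
#' flank-extended regions that overlap are merged.
#'
#' @param track `data.frame(chrom, pos, p_value)`.
#' @param alpha significance threshold.
#' @param chain_bp maximum gap between chained significant positions (bp).
#' @param flank_bp flanking extension (bp).
#' @return `data.frame(chrom, start, end, peak_pos, peak_p, n_sig)`; empty
#'   if nothing is significant.
#' @export
call_regions <- function(track, alpha = 1e-4, chain_bp = 2000,
                         flank_bp = 10000) {
  sig <- track[!is.na(track$p_value) & track$p_value <= alpha, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_pos = integer(),
                      peak_p = numeric(), n_sig = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  out <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(s$pos) > chain_bp)))
    do.call(rbind, lapply(split(s, grp), function(g) {
      data.frame(chrom = g$chrom[1],
                 start = max(1L, min(g$pos) - flank_bp),
                 end = max(g$pos) + flank_bp,
                 peak_pos = g$pos[which.min(g$p_value)],
                 peak_p = min(g$p_value),
                 n_sig = nrow(g), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  merge_overlapping_regions(out)
}

merge_overlapping_regions <- function(reg) {
  if (nrow(reg) < 2) return(reg)
  out <- lapply(split(reg, reg$chrom), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    merged <- r[1, , drop = FALSE]
    for (i in seq_len(nrow(r))[-1]) {
      last <- nrow(merged)
      if (r$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], r$end[i])
        merged$n_sig[last] <- merged$n_sig[last] + r$n_sig[i]
        if (r$peak_p[i] < merged$peak_p[last]) {
          merged$peak_p[last] <- r$peak_p[i]
          merged$peak_pos[last] <- r$peak_pos[i]
        }
      } else merged <- rbind(merged, r[i, , drop = FALSE])
    }
    merged
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assign the population under selection in a region
#'
#' For each eigenvector `i` of the kinship matrix, the measure of selection
#' is the sum over region SNPs of squared contributions `u_i^2` exceeding
#' the genome-wide per-eigenvector 99th percentile, divided by the number
#' of SNPs in the region.  If the largest measure is at least twice the
#' second largest, the region is assigned to the population with the
#' largest absolute loading in that eigenvector; otherwise the assignment
#' is `NA` (or `"ambiguous"` when loadings tie).
#'
#' @param region one row of [call_regions()] output (list or data.frame).
#' @param flk a [flk_scan()] result covering the genome.
#' @param u_quantile percentile threshold for contributing SNPs.
#' @return List with `measures` (per eigenvector), `eigenvector` (index of
#'   the winner or `NA`), `assigned_population`, `n_snps`.
#' @export
assign_population <- function(region, flk, u_quantile = 0.99) {
  U <- attr(flk, "u")
  eig <- attr(flk, "eigen")
  thr <- apply(U^2, 2, quantile, probs = u_quantile, na.rm = TRUE)
  inreg <- flk$chrom == region$chrom & flk$pos >= region$start &
    flk$pos <= region$end
  n_snps <- sum(inreg)
  if (n_snps < 1) stop("region contains no SNPs")
  U2 <- U[inreg, , drop = FALSE]^2
  m <- vapply(seq_len(ncol(U2)), function(i)
    sum(U2[U2[, i] > thr[i], i]) / n_snps, numeric(1))
  o <- order(m, decreasing = TRUE)
  assigned <- NA_character_
  eigv <- NA_integer_
  if (length(m) >= 2 && m[o[1]] > 0 && m[o[1]] >= 2 * m[o[2]]) {
    eigv <- o[1]
    load <- abs(eig$Q[eigv, ])
    best <- which(abs(load - max(load)) < 1e-12)
    assigned <- if (length(best) > 1) "ambiguous"
                else eig$populations[best]
  }
  list(measures = m, eigenvector = eigv,
       assigned_population = assigned, n_snps = n_snps)
}
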