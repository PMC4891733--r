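# Windowed nucleotide diversity, Reynolds distances, kinship construction
# from a rooted population tree, and the depth-vs-callable-fraction curve.

#' Windowed nucleotide diversity (pi)
#'
#' Per-site diversity for haploid samples of one population is the unbiased
#' pairwise heterozygosity `n/(n-1) * 2 p (1-p)` with `n` the number of
#' non-missing haploid calls and `p` the alt-allele frequency at the site.
#' Window pi is the sum over contained sites divided by the window length in
#' bp (the windowed-pi convention of standard VCF tooling), computed in
#' sliding windows; the genome-wide value is the unweighted mean over
#' windows (attribute `genome_pi`).
#'
#' @param gm [genotype_matrix()] (haploid samples).
#' @param population population label to subset; `NULL` uses all samples.
#' @param window window size in bp.
#' @param step step size in bp.
#' @return `data.frame(chrom, win_start, win_end, nsites, pi)` with
#'   attribute `genome_pi`; sites with fewer than 2 calls contribute 0 and
#'   are counted in attribute `n_low`.
#' @export
windowed_pi <- function(gm, population = NULL, window = 5000, step = 1000) {
  stopifnot(window >= step, step >= 1)
  if (!is.null(population))
    gm <- subset_samples(gm, gm$samples$population == population)
  if (any(gm$samples$ploidy != 1L))
    stop("windowed_pi expects haploid samples")
  calls <- gm$calls
  n <- colSums(!is.na(calls))
  p <- ifelse(n > 0, colSums(calls == CALL_ALT, na.rm = TRUE) / n, 0)
  persite <- ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), 0)
  n_low <- sum(n < 2)
  if (n_low > 0) warning(n_low, " site(s) with < 2 calls contribute 0")
  out <- do.call(rbind, lapply(split(seq_len(nrow(gm$sites)),
                                     gm$sites$chrom), function(idx) {
    pos <- gm$sites$pos[idx]
    chrom_end <- max(pos)
    starts <- seq(1L, max(1L, chrom_end), by = step)
    starts <- starts[starts <= chrom_end]
    ends <- starts + window - 1L
    wi <- findInterval(pos, starts)            # per start, using cumulative
    # assign each window its contained sites directly (windows overlap)
    res <- lapply(seq_along(starts), function(w) {
      inw <- pos >= starts[w] & pos <= ends[w]
      data.frame(chrom = gm$sites$chrom[idx[1]],
                 win_start = starts[w], win_end = ends[w],
                 nsites = sum(inw),
                 pi = sum(persite[idx][inw]) / window)
    })
    do.call(rbind, res)
  }))
  rownames(out) <- NULL
  attr(out, "genome_pi") <- mean(out$pi)
  attr(out, "n_low") <- n_low
  out
}

#' Population allele-frequency table from a genotype matrix
#'
#' Alt-allele frequencies per population over non-missing calls (haploid
#' FLK path: het calls in haploids are treated as missing since frequency
#' estimation assumes clean 0/1 haploid calls; diploid calls contribute two
#' copies, het one of each).
#'
#' @param gm [genotype_matrix()].
#' @return npop x nsites matrix of alt frequencies, populations as rownames.
#' @export
pop_freq_table <- function(gm) {
  pops <- unique(gm$samples$population)
  out <- matrix(NA_real_, length(pops), nrow(gm$sites),
                dimnames = list(pops, NULL))
  for (pn in pops) {
    sub <- subset_samples(gm, gm$samples$population == pn)
    calls <- sub$calls
    hap <- sub$samples$ploidy == 1L
    calls[calls == CALL_HET & hap] <- NA_integer_
    ploidy <- sub$samples$ploidy
    obs <- !is.na(calls)
    copies <- colSums(obs * ploidy)
    altc <- (calls == CALL_ALT) * ploidy
    altc[calls == CALL_HET] <- 1
    out[pn, ] <- ifelse(copies > 0,
                        colSums(altc, na.rm = TRUE) / copies, NA_real_)
  }
  out
}

#' Reynolds genetic distance between two populations
#'
#' Multilocus ratio-of-sums estimator:
#' `D = sum_l (p_i - p_j)^2 / sum_l (1 - p_i p_j - (1-p_i)(1-p_j))`.
#' Proportional to divergence time under pure drift.
#'
#' @param freq npop x nsites population frequency matrix (e.g. from
#'   [pop_freq_table()] or [simulate_frequencies()]).
#' @param pop_i,pop_j row names or indices.
#' @return Distance in `[0, 1]`; 0 (with a warning) if the denominator
#'   vanishes (all sites fixed identically).
#' @export
reynolds_distance <- function(freq, pop_i, pop_j) {
  pi_ <- freq[pop_i, ]; pj <- freq[pop_j, ]
  ok <- !is.na(pi_) & !is.na(pj)
  pi_ <- pi_[ok]; pj <- pj[ok]
  num <- sum((pi_ - pj)^2)
  den <- sum(1 - pi_ * pj - (1 - pi_) * (1 - pj))
  if (den <= 0) {
    warning("Reynolds denominator is 0 (no polymorphism); returning 0")
    return(0)
  }
  num / den
}

#' Pairwise Reynolds distance matrix
#'
#' @param freq npop x nsites frequency matrix with population rownames.
#' @return Symmetric npop x npop distance matrix.
#' @export
reynolds_matrix <- function(freq) {
  pops <- rownames(freq)
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops))
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- reynolds_distance(freq, pops[i], pops[j])
    }
  D
}

#' Kinship matrix from pairwise Reynolds distances
#'
#' Builds a neighbor-joining tree on `-log(1 - D)` transformed distances
#' (which keeps branch lengths additive under drift), roots it on the
#' outgroup branch, clamps negative NJ branch lengths to zero, and reads
#' co-ancestry as shared root-to-leaf path length: `F[i, j]` is the path
#' length from the root to the most recent common ancestor of populations
#' `i` and `j`, and `F[i, i]` the full root-to-leaf length.  The outgroup
#' is removed from the result.
#'
#' @param D symmetric distance matrix with population dimnames.
#' @param outgroup outgroup population label (used to root, then dropped).
#' @return List with `F` (kinship matrix), `tree` (rooted `phylo`) and
#'   `populations`.
#' @export
kinship_from_distances <- function(D, outgroup) {
  pops <- rownames(D)
  if (is.null(pops)) stop("distance matrix needs population dimnames")
  if (!outgroup %in% pops) stop("outgroup label absent: ", outgroup)
  if (length(pops) < 3) stop("need >= 3 populations including the outgroup")
  Dt <- -log(1 - D)
  tree <- ape::nj(stats::as.dist(Dt))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ingroup <- setdiff(pops, outgroup)
  depth <- ape::node.depth.edgelength(tree)     # distance from root
  lab <- tree$tip.label
  F <- matrix(0, length(ingroup), length(ingroup),
              dimnames = list(ingroup, ingroup))
  mr <- ape::mrca(tree)
  for (i in ingroup)
    for (j in ingroup) {
      F[i, j] <- if (i == j) depth[match(i, lab)]
                 else depth[mr[match(i, lab), match(j, lab)]]
    }
  list(F = F, tree = tree, populations = ingroup)
}

#' Fit the depth-versus-callable-fraction curve
#'
#' Least-squares fit of the saturating-exponential model
#' `GX = a (1 - exp(-DP / b))` relating mean sequencing depth (DP, in X) to
#' the callable fraction of the genome (GX).  Used to pick an economical
#' sequencing depth for haploid cohorts.
#'
#' @param points `data.frame(DP, GX)` with at least 3 points, GX in (0, 1).
#' @return Object of class `depth_curve` with elements `a` (asymptote),
#'   `b` (rate, in X) and the `nls` fit.
#' @export
fit_depth_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("DP", "GX") %in% names(points)))
  if (nrow(points) < 3) stop("need >= 3 points")
  if (any(points$GX <= 0) || any(points$GX >= 1))
    stop("GX values must lie in (0, 1)")
  if (sd(points$GX) == 0 || sd(points$DP) == 0)
    stop("degenerate points: no variation in DP or GX")
  a0 <- min(max(points$GX) * 1.05, 0.999)
  b0 <- median(points$DP) / max(1e-6, -log(1 - median(points$GX) / a0))
  fit <- tryCatch(
    stats::nls(GX ~ a * (1 - exp(-DP / b)), data = points,
               start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            scaleOffset = 1)),
    error = function(e) stop("depth-curve fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["a"]] <= 0 || cf[["a"]] > 1 || cf[["b"]] <= 0)
    stop("depth-curve fit outside valid range (a in (0,1], b > 0)")
  structure(list(a = unname(cf[["a"]]), b = unname(cf[["b"]]), fit = fit,
                 points = points), class = "depth_curve")
}

#' Invert a depth curve: depth required for a target callable fraction
#'
#' Closed-form inversion `DP = -b log(1 - gx / a)`.
#'
#' @param curve a [fit_depth_curve()] result.
#' @param gx_target target callable fraction; must be below the asymptote.
#' @return Required mean depth (X).
#' @export
invert_depth_curve <- function(curve, gx_target) {
  stopifnot(inherits(curve, "depth_curve"))
  if (gx_target >= curve$a)
    stop("gx_target >= fitted asymptote a = ", signif(curve$a, 4))
  if (gx_target <= 0) stop("gx_target must be positive")
  -curve$b * log(1 - gx_target / curve$a)
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("depth_curve: GX = %.4f * (1 - exp(-DP / %.4f))\n", x$a, x$b))
  invisible(x)
}
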