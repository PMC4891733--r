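# Heterozygous calls in haploid drones are biologically impossible at a
# unique locus; clusters of them with inflated depth flag collapsed
# duplications (candidate CNVs).  This module filters, clusters, merges
# across drones, tests for population bias and annotates the intervals.

#' Depth/chromosome site filter for the hetSNP analysis
#'
#' Keeps sites on the requested chromosomes where every individual's
#' per-genotype depth is at least `dp_min`.
#'
#' @param gm [genotype_matrix()] (het calls retained).
#' @param dp_min minimum per-genotype depth in every individual.
#' @param chroms chromosomes to keep (default the 16 honeybee autosomes,
#'   labelled `"1"`..`"16"`).
#' @return Filtered [genotype_matrix()].
#' @export
site_filter <- function(gm, dp_min = 9, chroms = as.character(1:16)) {
  keep <- gm$sites$chrom %in% as.character(chroms) &
    apply(gm$depth >= dp_min, 2, all)
  subset_sites(gm, which(keep))
}

#' Neighbour filter on one drone's hetSNP positions
#'
#' A hetSNP is retained iff its nearest het neighbour on the same
#' chromosome is at most `max_gap` bp away (isolated het calls are most
#' often artefacts).
#'
#' @param pos sorted or unsorted integer positions of one drone's hetSNPs
#'   on one chromosome.
#' @param max_gap maximum distance to the nearest neighbour (bp).
#' @return Retained positions, sorted.
#' @export
neighbor_filter <- function(pos, max_gap = 2000) {
  pos <- sort(unique(as.integer(pos)))
  if (length(pos) < 2) return(integer(0))
  gap_left <- c(Inf, diff(pos))
  gap_right <- c(diff(pos), Inf)
  pos[pmin(gap_left, gap_right) <= max_gap]
}

#' Call hetSNP clusters for one drone
#'
#' Maximal runs of retained hetSNPs with inter-het gaps at most `max_gap`
#' form candidate clusters; a cluster is kept when it contains at least
#' `min_n` hetSNPs, spans at least `min_span` bp, and its mean depth is at
#' least `dp_factor` times the drone's average depth (computed over all the
#' drone's genotyped sites, before any site filtering).
#'
#' @param pos retained het positions on one chromosome (from
#'   [neighbor_filter()]).
#' @param dp depths at those positions (same order as sorted `pos`).
#' @param drone_mean_dp the drone's genome-wide average depth.
#' @param min_n,min_span,dp_factor,max_gap filter parameters.
#' @return `data.frame(start, end, n_het, mean_dp)` of retained clusters.
#' @export
call_clusters <- function(pos, dp, drone_mean_dp, min_n = 3,
                          min_span = 2000, dp_factor = 3,
                          max_gap = 2000) {
  o <- order(pos)
  pos <- pos[o]; dp <- dp[o]
  empty <- data.frame(start = integer(), end = integer(),
                      n_het = integer(), mean_dp = numeric())
  if (!length(pos)) return(empty)
  grp <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
  out <- do.call(rbind, lapply(split(seq_along(pos), grp), function(i) {
    data.frame(start = pos[i[1]], end = pos[i[length(i)]],
               n_het = length(i), mean_dp = mean(dp[i]))
  }))
  keep <- out$n_het >= min_n & (out$end - out$start) >= min_span &
    out$mean_dp >= dp_factor * drone_mean_dp
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-drone hetSNP cluster detection over a genotype matrix
#'
#' Runs [site_filter()], then per drone and chromosome the
#' [neighbor_filter()] and [call_clusters()] steps.  The drone average
#' depth is computed over all the drone's genotyped sites before the site
#' filter.
#'
#' @param gm [genotype_matrix()] with haploid het calls retained.
#' @param dp_min,chroms see [site_filter()].
#' @param max_gap,min_n,min_span,dp_factor see [call_clusters()].
#' @return `data.frame(drone_id, chrom, start, end, n_het, mean_dp,
#'   drone_mean_dp)`.
#' @export
hetsnp_clusters <- function(gm, dp_min = 9, chroms = as.character(1:16),
                            max_gap = 2000, min_n = 3, min_span = 2000,
                            dp_factor = 3) {
  drone_mean <- rowMeans(gm$depth)
  gmf <- site_filter(gm, dp_min = dp_min, chroms = chroms)
  res <- list()
  for (i in seq_len(nrow(gmf$samples))) {
    het <- which(gmf$calls[i, ] == CALL_HET)
    if (!length(het)) next
    for (ch in unique(gmf$sites$chrom[het])) {
      idx <- het[gmf$sites$chrom[het] == ch]
      keep_pos <- neighbor_filter(gmf$sites$pos[idx], max_gap = max_gap)
      if (!length(keep_pos)) next
      idx <- idx[gmf$sites$pos[idx] %in% keep_pos]
      cl <- call_clusters(gmf$sites$pos[idx], gmf$depth[i, idx],
                          drone_mean_dp = drone_mean[i], min_n = min_n,
                          min_span = min_span, dp_factor = dp_factor,
                          max_gap = max_gap)
      if (nrow(cl)) {
        cl$drone_id <- gmf$samples$sample_id[i]
        cl$chrom <- ch
        cl$drone_mean_dp <- drone_mean[i]
        res[[length(res) + 1L]] <- cl
      }
    }
  }
  if (!length(res))
    return(data.frame(drone_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_het = integer(), mean_dp = numeric(),
                      drone_mean_dp = numeric()))
  out <- do.call(rbind, res)
  out[c("drone_id", "chrom", "start", "end", "n_het", "mean_dp",
        "drone_mean_dp")]
}

#' Merge per-drone clusters into population-level intervals
#'
#' Per-drone clusters overlapping by at least 1 bp on the same chromosome
#' are unioned into intervals; carriers are counted per population, and
#' intervals carried by more than `carrier_threshold` drones are flagged
#' as unlikely artefacts.  The result is independent of drone input order.
#'
#' @param clusters output of [hetsnp_clusters()].
#' @param samples the cohort [sample_table()].
#' @param carrier_threshold flag intervals with more carriers than this
#'   (default 15, mirroring a 60-drone design; scale for other cohorts).
#' @return `data.frame(chrom, start, end, n_carriers, high_frequency,
#'   carriers_<pop>...)` plus a `carrier_ids` list column.
#' @export
merge_across_drones <- function(clusters, samples, carrier_threshold = 15) {
  pops <- unique(samples$population)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_carriers = integer(),
                      high_frequency = logical())
  if (!nrow(clusters)) return(empty)
  out <- lapply(split(clusters, clusters$chrom), function(cl) {
    cl <- cl[order(cl$start, cl$end, cl$drone_id), , drop = FALSE]
    grp <- integer(nrow(cl)); grp[1] <- 1L
    hi <- cl$end[1]
    for (i in seq_len(nrow(cl))[-1]) {
      if (cl$start[i] <= hi) grp[i] <- grp[i - 1L]
      else grp[i] <- grp[i - 1L] + 1L
      hi <- max(hi, cl$end[i])
    }
    do.call(rbind, lapply(split(cl, grp), function(g) {
      ids <- unique(g$drone_id)
      r <- data.frame(chrom = g$chrom[1], start = min(g$start),
                      end = max(g$end), n_carriers = length(ids),
                      stringsAsFactors = FALSE)
      for (pn in pops) {
        members <- samples$sample_id[samples$population == pn]
        r[[paste0("carriers_", pn)]] <- sum(ids %in% members)
      }
      r$carrier_ids <- I(list(ids))
      r
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$high_frequency <- out$n_carriers > carrier_threshold
  out
}

#' Pearson chi-squared test of carrier-frequency bias between populations
#'
#' 2 x 2 Pearson chi-squared without continuity correction on
#' carrier/non-carrier counts in two populations, with the p-value from the
#' upper tail of the 1-df chi-squared distribution.
#'
#' @param carriers length-2 vector of carrier counts.
#' @param n_per_population length-2 vector of population sizes.
#' @return List with `chi2`, `p_value` and the contingency `table`.
#' @export
population_bias_test <- function(carriers, n_per_population) {
  stopifnot(length(carriers) == 2, length(n_per_population) == 2)
  if (any(n_per_population == 0)) stop("a population has size 0")
  if (any(carriers > n_per_population))
    stop("more carriers than individuals")
  tab <- rbind(carriers, n_per_population - carriers)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0)) {
    chi2 <- 0
  } else {
    chi2 <- sum((tab - E)^2 / E)
  }
  list(chi2 = chi2,
       p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
       table = tab)
}

#' Annotate intervals with recombination overlap and nearby genes
#'
#' Flags intervals intersecting (by >= 1 bp) any crossover/gene-conversion
#' interval, and lists genes whose span intersects the interval extended by
#' `gene_margin` bp on each side.
#'
#' @param intervals `data.frame(chrom, start, end)` (1-based inclusive).
#' @param recomb `data.frame(chrom, start, end)` of recombination events
#'   (e.g. from [read_bed()]), or `NULL`.
#' @param genes `data.frame(chrom, start, end, gene_id)` (e.g. from
#'   [read_gff3_genes()]), or `NULL`.
#' @param gene_margin margin in bp for gene proximity.
#' @return `intervals` with added `overlaps_recombination` flag and
#'   `nearby_genes` list column.
#' @export
annotate_intervals <- function(intervals, recomb = NULL, genes = NULL,
                               gene_margin = 2000) {
  n <- nrow(intervals)
  hits <- function(a_chr, a_s, a_e, b) {
    vapply(seq_along(a_chr), function(i) {
      same <- b$chrom == a_chr[i]
      any(same & b$start <= a_e[i] & b$end >= a_s[i])
    }, logical(1))
  }
  intervals$overlaps_recombination <-
    if (is.null(recomb) || !nrow(recomb)) rep(FALSE, n)
    else hits(intervals$chrom, intervals$start, intervals$end, recomb)
  intervals$nearby_genes <- I(lapply(seq_len(n), function(i) {
    if (is.null(genes) || !nrow(genes)) return(character(0))
    s <- intervals$start[i] - gene_margin
    e <- intervals$end[i] + gene_margin
    sel <- genes$chrom == intervals$chrom[i] &
      genes$start <= e & genes$end >= s
    genes$gene_id[sel]
  }))
  intervals
}
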