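# Readers/writers for the standard formats the pipeline touches, and the
# genotype-matrix container shared by all downstream analyses.
#
# Internal coordinate convention: 1-based inclusive everywhere (VCF/GFF3
# convention); BED's half-open 0-based coordinates are converted at the
# boundary on read/write.

CALL_REF <- 0L
CALL_ALT <- 1L
CALL_HET <- 2L

#' Sample table
#'
#' Builds the sample metadata table used throughout the pipeline: one row per
#' sequenced individual with its population label and ploidy (1 for drones,
#' 2 for workers/queens or in-silico diploids).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param population character vector of population labels (e.g. `"HN"`,
#'   `"RJ"`, `"OU"`, `"BE"`, `"SL"`).
#' @param ploidy integer vector of 1s and 2s (recycled if length 1).
#' @return A `data.frame` of class `sample_table` with columns `sample_id`,
#'   `population`, `ploidy`.
#' @export
sample_table <- function(sample_id, population, ploidy = 1L) {
  sample_id <- as.character(sample_id)
  population <- as.character(population)
  ploidy <- as.integer(rep_len(ploidy, length(sample_id)))
  if (anyDuplicated(sample_id))
    stop("sample_ids must be unique")
  if (length(population) != length(sample_id))
    stop("population must have one label per sample")
  if (any(!nzchar(population)) || anyNA(population))
    stop("every population label must be non-empty")
  if (!all(ploidy %in% c(1L, 2L)))
    stop("ploidy must be 1 or 2")
  out <- data.frame(sample_id = sample_id, population = population,
                    ploidy = ploidy, stringsAsFactors = FALSE)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Read a tab-separated sample table
#'
#' Expects columns `sample_id`, `population`, `ploidy` (header required).
#' Gzipped files are accepted.
#'
#' @param path file path.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "ploidy")
  if (!all(need %in% names(df)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  sample_table(df$sample_id, df$population, df$ploidy)
}

#' Genotype matrix
#'
#' The substrate of all population statistics: biallelic sites by samples,
#' with ploidy-aware genotype calls and per-call sequencing depth.
#'
#' Calls are coded `0` (ref), `1` (alt), `2` (het) and `NA` (missing).  For a
#' haploid drone a het call is biologically impossible at a unique locus and
#' is only permitted when `het_mode = TRUE` (the variant-calling mode in which
#' heterozygous calls in haploids are deliberately retained as candidate
#' collapsed-duplication signals; see [hetsnp_clusters()]).
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; must be sorted by (chrom, pos) and unique.
#' @param calls integer matrix, samples x sites.
#' @param depth non-negative integer matrix, samples x sites.
#' @param samples a [sample_table()] with one row per matrix row.
#' @param het_mode logical; permit het calls in haploid samples.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, depth, samples, het_mode = FALSE) {
  calls <- as.matrix(calls); storage.mode(calls) <- "integer"
  depth <- as.matrix(depth); storage.mode(depth) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (nrow(calls) != nrow(samples) || nrow(depth) != nrow(samples))
    stop("calls/depth must have one row per sample")
  if (ncol(calls) != nrow(sites) || ncol(depth) != nrow(sites))
    stop("calls/depth must have one column per site")
  key <- order(sites$chrom, sites$pos)
  if (!identical(key, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("sites must be unique by (chrom, pos)")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be >= 0")
  bad <- !(calls %in% c(CALL_REF, CALL_ALT, CALL_HET) | is.na(calls))
  if (any(bad)) stop("calls must be coded 0/1/2/NA")
  if (!het_mode) {
    hap <- samples$ploidy == 1L
    if (any(calls[hap, , drop = FALSE] == CALL_HET, na.rm = TRUE))
      stop("het calls in haploid samples require het_mode = TRUE")
  }
  rownames(calls) <- rownames(depth) <- samples$sample_id
  colnames(calls) <- colnames(depth) <- NULL
  structure(list(sites = sites, calls = calls, depth = depth,
                 samples = samples, het_mode = het_mode),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d population%s)%s\n",
              nrow(x$samples), nrow(x$sites),
              length(unique(x$samples$population)),
              if (length(unique(x$samples$population)) == 1) "" else "s",
              if (isTRUE(x$het_mode)) " [het calls retained]" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$samples), nrow(x$sites))

#' Read genotypes and depths from a VCF file
#'
#' Reads biallelic SNPs (multi-allelic sites and indels are skipped with a
#' warning) and returns a [genotype_matrix()].  Haploid genotypes `"0"`/`"1"`
#' map to ref/alt; `"0/1"`, `"1/0"` (or phased equivalents) map to het;
#' `"."`/`"./."` to missing.  Per-genotype `DP` is required alongside `GT`.
#'
#' @param path VCF 4.x file (optionally gzipped).
#' @param samples a [sample_table()]; every VCF sample must be listed.
#' @param het_mode permit het calls in haploid samples (see
#'   [genotype_matrix()]).
#' @return A [genotype_matrix()] with samples ordered as in `samples`
#'   restricted to those present in the VCF.
#' @export
read_vcf <- function(path, samples, het_mode = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L || !any(grepl("GT", v@gt[, "FORMAT"])))
    stop("VCF format error: GT field missing")
  vcf_samples <- colnames(v@gt)[-1]
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown))
    stop("VCF samples absent from sample table: ",
         paste(unknown, collapse = ", "))
  ref <- v@fix[, "REF"]; alt <- v@fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  sites <- data.frame(chrom = as.character(v@fix[keep, "CHROM"]),
                      pos = as.integer(v@fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  code1 <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0", "0/0")] <- CALL_REF
    out[g %in% c("1", "1/1")] <- CALL_ALT
    out[g %in% c("0/1", "1/0")] <- CALL_HET
    out
  }
  calls <- apply(gt, 2, code1)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(sites))
  dp[is.na(dp)] <- 0
  st <- samples[match(vcf_samples, samples$sample_id), , drop = FALSE]
  class(st) <- c("sample_table", "data.frame")
  gm <- genotype_matrix(sites, t(calls), t(dp), st, het_mode = het_mode)
  reorder_sites(gm)
}

# sites arrive in VCF order; enforce the internal (chrom, pos) sort
reorder_sites <- function(gm) {
  o <- order(gm$sites$chrom, gm$sites$pos)
  if (identical(o, seq_len(nrow(gm$sites)))) return(gm)
  genotype_matrix(gm$sites[o, , drop = FALSE],
                  gm$calls[, o, drop = FALSE],
                  gm$depth[, o, drop = FALSE],
                  gm$samples, het_mode = gm$het_mode)
}

#' Write a genotype matrix to a VCF file
#'
#' Minimal VCF 4.2 writer (GT:DP per genotype) used for the synthetic-data
#' path and round-trip testing.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples$sample_id),
                     collapse = "\t")), con)
  hap <- gm$samples$ploidy == 1L
  gt_str <- matrix("", nrow(gm$calls), ncol(gm$calls))
  for (i in seq_len(nrow(gm$calls))) {
    g <- gm$calls[i, ]
    s <- if (hap[i]) c("0", "1", "0/1")[g + 1L] else c("0/0", "1/1", "0/1")[g + 1L]
    s[is.na(g)] <- if (hap[i]) "." else "./."
    gt_str[i, ] <- paste0(s, ":", gm$depth[i, ])
  }
  lines <- vapply(seq_len(nrow(gm$sites)), function(j) {
    paste(c(gm$sites$chrom[j], gm$sites$pos[j], ".", gm$sites$ref[j],
            gm$sites$alt[j], ".", "PASS", ".", "GT:DP", gt_str[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Per-site allele frequencies and call rates
#'
#' Alt-allele frequency over non-missing allele copies: a haploid call
#' contributes one copy, a diploid call two, and a het call one copy of each
#' allele.  Call rate is the fraction of non-missing genotype calls.
#'
#' @param gm a [genotype_matrix()].
#' @return `data.frame` with columns `alt_freq`, `maf`, `call_rate`, `n_copies`.
#' @export
site_summary <- function(gm) {
  ploidy <- gm$samples$ploidy
  calls <- gm$calls
  obs <- !is.na(calls)
  copies <- obs * ploidy                       # copies observed per call
  alt <- matrix(0, nrow(calls), ncol(calls))
  alt[which(calls == CALL_ALT)] <- 1
  alt <- alt * ploidy                          # hom alt: all copies alt
  alt[which(calls == CALL_HET)] <- 1           # het: exactly one alt copy
  n_copies <- colSums(copies)
  alt_freq <- ifelse(n_copies > 0, colSums(alt) / n_copies, NA_real_)
  data.frame(alt_freq = alt_freq,
             maf = pmin(alt_freq, 1 - alt_freq),
             call_rate = colMeans(obs),
             n_copies = n_copies)
}

#' Filter sites on MAF, call rate and chromosome
#'
#' Standard genotype quality control: retain sites on the requested
#' chromosomes with minor allele frequency >= `maf_min` (inclusive) and
#' genotyping call rate >= `call_rate_min` (inclusive).  Site order is
#' preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param call_rate_min minimum call rate in `(0, 1]`.
#' @param chroms chromosomes to keep (`NULL` = all).
#' @param drop_missing additionally drop sites with any missing call (stands
#'   in for the external imputation step, which is out of scope).
#' @return Filtered [genotype_matrix()]; warns if no site survives.
#' @export
filter_sites <- function(gm, maf_min = 0.05, call_rate_min = 0.9,
                         chroms = NULL, drop_missing = FALSE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            call_rate_min > 0, call_rate_min <= 1)
  ss <- site_summary(gm)
  keep <- !is.na(ss$maf) & ss$maf >= maf_min & ss$call_rate >= call_rate_min
  if (!is.null(chroms))
    keep <- keep & gm$sites$chrom %in% as.character(chroms)
  if (drop_missing) keep <- keep & ss$call_rate == 1
  if (!any(keep)) warning("no site survives filtering")
  subset_sites(gm, which(keep))
}

#' Subset a genotype matrix by sites or samples
#'
#' @param gm a [genotype_matrix()].
#' @param idx site (or sample) indices or a logical vector.
#' @return The subsetted [genotype_matrix()].
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE],
                  gm$calls[, idx, drop = FALSE],
                  gm$depth[, idx, drop = FALSE],
                  gm$samples, het_mode = gm$het_mode)
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, idx) {
  st <- gm$samples[idx, , drop = FALSE]
  class(st) <- c("sample_table", "data.frame")
  genotype_matrix(gm$sites, gm$calls[idx, , drop = FALSE],
                  gm$depth[idx, , drop = FALSE], st, het_mode = gm$het_mode)
}

#' Build in-silico diploids from haploid drones
#'
#' Combines both alleles of randomly selected pairs of drones within each
#' population into diploid genotypes (the device used to compare haploid
#' drone cohorts against diploid reference panels without systematic
#' homozygosity artefacts).  Depth of a diploid call is the sum of the two
#' haploid depths.  Pairing is without replacement and deterministic for a
#' fixed `pairing_seed`; an odd drone (or a population with fewer than two
#' drones) is dropped with a warning.
#'
#' @param gm haploid [genotype_matrix()].
#' @param pairing_seed integer seed for the random pairing.
#' @return Diploid [genotype_matrix()] with samples named `<a>x<b>`.
#' @export
make_insilico_diploids <- function(gm, pairing_seed) {
  if (any(gm$samples$ploidy != 1L)) stop("all samples must be haploid")
  pops <- split(seq_len(nrow(gm$samples)), gm$samples$population)
  pairs <- list()
  withr_seed(pairing_seed, {
    for (pn in names(pops)) {
      idx <- pops[[pn]]
      if (length(idx) < 2L) {
        warning("population ", pn, " has < 2 drones; skipped")
        next
      }
      if (length(idx) %% 2L == 1L) {
        warning("population ", pn, ": odd drone count, one drone dropped")
      }
      perm <- sample(idx)
      npair <- length(idx) %/% 2L
      for (q in seq_len(npair))
        pairs[[length(pairs) + 1L]] <- perm[c(2L * q - 1L, 2L * q)]
    }
  })
  if (!length(pairs)) stop("no population with >= 2 drones")
  n <- length(pairs)
  calls <- matrix(NA_integer_, n, nrow(gm$sites))
  depth <- matrix(0L, n, nrow(gm$sites))
  ids <- character(n); pop <- character(n)
  for (q in seq_len(n)) {
    a <- pairs[[q]][1]; b <- pairs[[q]][2]
    ga <- gm$calls[a, ]; gb <- gm$calls[b, ]
    g <- ifelse(is.na(ga) | is.na(gb), NA_integer_,
                ifelse(ga == gb, ga, CALL_HET))
    calls[q, ] <- g
    depth[q, ] <- gm$depth[a, ] + gm$depth[b, ]
    ids[q] <- paste0(gm$samples$sample_id[a], "x", gm$samples$sample_id[b])
    pop[q] <- gm$samples$population[a]
  }
  genotype_matrix(gm$sites, calls, depth,
                  sample_table(ids, pop, ploidy = 2L))
}

# run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Read and write BED intervals
#'
#' BED is half-open 0-based on disk; intervals are converted to the internal
#' 1-based inclusive representation on read and back on write.
#'
#' @param path file path.
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `name`.
#' @return `read_bed()`: `data.frame(chrom, start, end, name)` (1-based
#'   inclusive); `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = as.integer(df$start),   # GRanges is 1-based already
                    end = as.integer(df$end),
                    name = if ("name" %in% names(df)) as.character(df$name)
                           else NA_character_,
                    stringsAsFactors = FALSE)
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name
           else paste0("iv", seq_len(nrow(intervals))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Returns gene features (1-based inclusive, as in GFF3) with their `ID`
#' attribute as the gene name.
#'
#' @param path GFF3 file (optionally gzipped).
#' @return `data.frame(chrom, start, end, gene_id)`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  df <- as.data.frame(gr)
  data.frame(chrom = as.character(df$seqnames),
             start = as.integer(df$start),
             end = as.integer(df$end),
             gene_id = if ("ID" %in% names(df)) as.character(df$ID)
                       else NA_character_,
             stringsAsFactors = FALSE)
}
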