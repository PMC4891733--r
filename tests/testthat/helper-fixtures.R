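# Small deterministic fixtures built in code.

toy_samples <- function(n = 3, pop = "HN", ploidy = 1L) {
  sample_table(sprintf("D%02d", seq_len(n)), rep_len(pop, n), ploidy)
}

# 3 haploid samples x 4 sites with hand-set calls and depths
toy_gm <- function(het_mode = FALSE) {
  sites <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                      ref = c("A", "C", "G", "T"),
                      alt = c("T", "G", "A", "C"),
                      stringsAsFactors = FALSE)
  calls <- rbind(c(0L, 1L, 0L, NA),
                 c(1L, 1L, 0L, 0L),
                 c(0L, if (het_mode) 2L else 0L, 1L, 1L))
  depth <- rbind(c(10L, 12L, 9L, 0L),
                 c(8L, 15L, 11L, 7L),
                 c(14L, 12L, 10L, 9L))
  genotype_matrix(sites, calls, depth, toy_samples(3), het_mode = het_mode)
}

# hand-written VCF matching toy_gm(het_mode = TRUE), plus one multi-allelic
# record that readers must skip
write_toy_vcf <- function(path, multiallelic = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "D01", "D02", "D03"), collapse = "\t"))
  rows <- c(
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0:10\t1:8\t0:14",
    "1\t200\t.\tC\tG\t.\tPASS\t.\tGT:DP\t1:12\t1:15\t0/1:12",
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT:DP\t0:9\t0:11\t1:10",
    "1\t400\t.\tT\tC\t.\tPASS\t.\tGT:DP\t.:0\t0:7\t1:9")
  if (multiallelic)
    rows <- c(rows, "1\t500\t.\tA\tT,G\t.\tPASS\t.\tGT:DP\t0:9\t1:9\t0:9")
  writeLines(c(hdr, rows), path)
  path
}

random_psd_kinship <- function(npop, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(npop * npop, sd = 0.1), npop)
    F <- crossprod(A) + diag(0.02, npop)
    F <- F / (2 * max(diag(F)))   # keep diagonal comfortably inside (0, 1)
    dimnames(F) <- list(paste0("P", 1:npop), paste0("P", 1:npop))
    F
  })
}

# fake FLK scan result with prescribed eigenvector contributions, for
# exercising the assignment rule in isolation
fake_flk <- function(U, Q, D, pops, chrom = "1",
                     pos = seq_len(nrow(U)) * 1000L) {
  out <- data.frame(chrom = chrom, pos = pos, p0 = 0.5,
                    T = rowSums(U^2),
                    p_value = 0.5, flagged = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "u") <- U
  attr(out, "eigen") <- structure(list(Q = Q, D = D, populations = pops),
                                  class = "eigen_system")
  class(out) <- c("flk_result", "data.frame")
  out
}
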