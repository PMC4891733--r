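test_that("drift simulation respects the zero-drift limit and its covariance", {
  # F = 0: every population frequency equals the ancestral draw exactly
  fr0 <- simulate_frequencies(drift_model(matrix(0, 3, 3), nsites = 200,
                                          seed = 2))
  expect_equal(max(abs(sweep(fr0$freq, 2, fr0$p0))), 0)

  # F = 0.1 I: standardized deviations have variance 0.1; checked where
  # boundary truncation is negligible (mid-range ancestral frequencies)
  fr <- simulate_frequencies(drift_model(0.1 * diag(3), nsites = 50000,
                                         seed = 5))
  mid <- fr$p0 > 0.35 & fr$p0 < 0.65
  z <- sweep(fr$freq[, mid], 2, fr$p0[mid]) /
    rep(sqrt(fr$p0[mid] * (1 - fr$p0[mid])), each = 3)
  expect_lt(abs(stats::var(as.vector(z)) / 0.1 - 1), 0.05)

  # deterministic per seed; non-PSD kinship rejected
  fr2 <- simulate_frequencies(drift_model(0.1 * diag(3), nsites = 50000,
                                          seed = 5))
  expect_identical(fr$freq, fr2$freq)
  badF <- matrix(c(0.1, 0.3, 0.3, 0.1), 2)
  expect_error(drift_model(badF), "positive semi-definite")
})

test_that("founder-pool haplotypes recover input frequencies and LD limits", {
  F <- default_kinship()[1:2, 1:2]
  fr <- simulate_frequencies(drift_model(F, nsites = 400, seed = 11))
  # block length 1, large founder pool: per-site frequency within a wide
  # two-stage binomial band
  gm <- simulate_haplotypes(fr, nsamples_per_pop = 60, ld_block = 1,
                            n_founders = 500, seed = 12)
  for (pn in rownames(fr$freq)) {
    phat <- colMeans(gm$calls[gm$samples$population == pn, ])
    p <- fr$freq[pn, ]
    tol <- 4 * sqrt(pmax(p * (1 - p), 0.002) * (1 / 500 + 1 / 60))
    expect_true(all(abs(phat - p) <= tol))
  }
  # founder pool of size 1: every haplotype in a population is identical
  gm1 <- simulate_haplotypes(fr, nsamples_per_pop = 10, n_founders = 1,
                             seed = 13)
  for (pn in rownames(fr$freq)) {
    rows <- gm1$calls[gm1$samples$population == pn, ]
    expect_true(all(apply(rows, 2, function(x) length(unique(x)) == 1)))
  }
  # bit-identical under a fixed seed
  expect_identical(gm1$calls,
                   simulate_haplotypes(fr, nsamples_per_pop = 10,
                                       n_founders = 1, seed = 13)$calls)
})

test_that("sweep injection fixes the donor haplotype to the target frequency", {
  fr <- simulate_frequencies(drift_model(nsites = 300, seed = 21))
  gm <- simulate_haplotypes(fr, nsamples_per_pop = 30, seed = 22)
  win <- c(50001, 80000)           # sites every 500 bp
  hapfreq <- function(g, idx, pop) {
    rows <- g$calls[g$samples$population == pop, idx, drop = FALSE]
    max(table(apply(rows, 1, paste, collapse = ""))) / nrow(rows)
  }
  pre <- hapfreq(gm, which(gm$sites$pos >= win[1] & gm$sites$pos <= win[2]),
                 "RJ")

  full <- inject_sweep(gm, sweep_spec("RJ", "1", win[1], win[2], 1.0), 7)
  expect_equal(hapfreq(full$gm, full$window_idx, "RJ"), 1.0)

  part <- inject_sweep(gm, sweep_spec("RJ", "1", win[1], win[2], 0.9), 7)
  post <- hapfreq(part$gm, part$window_idx, "RJ")
  expect_gte(post * 30, 27)        # >= 27 of 30 drones carry the haplotype
  expect_gt(post, pre)             # homozygosity strictly raised
  # other populations untouched
  keep <- part$gm$samples$population != "RJ"
  expect_identical(part$gm$calls[keep, ], gm$calls[keep, ])
  expect_error(inject_sweep(gm, sweep_spec("RJ", "9", 1, 2), 1), "no sites")
})

test_that("collapsed-duplication injection produces shared het PSVs and depth inflation", {
  fr <- simulate_frequencies(drift_model(default_kinship()[2:3, 2:3],
                                         nsites = 500, seed = 31))
  gm <- simulate_haplotypes(fr, nsamples_per_pop = 10, spacing_bp = 100,
                            seed = 32)
  spec0 <- cnv_spec("1", 10001, 20000, paralog_divergence = 0,
                    depth_inflation_factor = 3)
  inj0 <- inject_cnv(gm, spec0, seed = 33)
  ci <- match(inj0$carriers, gm$samples$sample_id)
  expect_gt(length(ci), 0)
  # zero divergence: no het calls, but depth inflated exactly 3x
  expect_false(any(inj0$gm$calls == 2L, na.rm = TRUE))
  expect_equal(inj0$gm$depth[ci, inj0$segment_idx],
               gm$depth[ci, inj0$segment_idx] * 3L)
  # non-carriers untouched
  out <- setdiff(seq_len(10 * 2), ci)
  expect_identical(inj0$gm$calls[out, ], gm$calls[out, ])
  expect_identical(inj0$gm$depth[out, ], gm$depth[out, ])

  # realized PSV count behaves like Binomial(n_segment_sites, divergence)
  nseg <- length(inj0$segment_idx)
  counts <- vapply(1:30, function(s)
    length(inject_cnv(gm, cnv_spec("1", 10001, 20000,
                                   paralog_divergence = 0.1),
                      seed = s)$psv_idx), numeric(1))
  expect_gt(mean(counts), nseg * 0.1 * 0.5)
  expect_lt(mean(counts), nseg * 0.1 * 2.0)
  # the generator asserts a minimum realized PSV count
  expect_gte(min(counts), 3)
})

test_that("mitotype amplicon architecture, reads and qualities follow the spec", {
  # error-free reads are exact substrings of the truth
  sim0 <- simulate_mito(mito_sim_spec(read_error_rate = 0, coverage = 5),
                        seed = 3)
  hits <- vapply(sim0$reads$seq, function(s)
    grepl(s, sim0$truth$raw, fixed = TRUE), logical(1))
  expect_true(all(hits))

  # q_copies 2 vs 1 differ by exactly one Q-element length (same seed)
  s1 <- simulate_mito(mito_sim_spec(q_copies = 1, n_snps = 0), seed = 9)
  s2 <- simulate_mito(mito_sim_spec(q_copies = 2, n_snps = 0), seed = 9)
  expect_equal(nchar(s2$truth$raw) - nchar(s1$truth$raw), 190L)

  # FASTQ mean base quality within 1 Phred unit of the requested profile
  sim <- simulate_mito(mito_sim_spec(mean_quality = 35), seed = 4)
  q <- unlist(lapply(sim$reads$qual,
                     function(x) as.integer(charToRaw(x)) - 33L))
  expect_lt(abs(mean(q) - 35), 1)

  # panel contains the truth plus decoys, all distinct
  expect_true("TRUTH" %in% sim$panel$accession)
  expect_false(anyDuplicated(sim$panel$sequence) > 0)

  # FASTQ round-trip
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$qual, sim$reads$qual)
})

test_that("generators are deterministic and leave the global RNG untouched", {
  set.seed(99); before <- .Random.seed
  a <- simulate_frequencies(drift_model(nsites = 100, seed = 8))
  expect_identical(before, .Random.seed)
  b <- simulate_frequencies(drift_model(nsites = 100, seed = 8))
  expect_identical(a$freq, b$freq)
  m1 <- simulate_mito(seed = 5)
  m2 <- simulate_mito(seed = 5)
  expect_identical(m1$reads, m2$reads)
})
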