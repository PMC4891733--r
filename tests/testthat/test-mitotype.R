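test_that("anchor trimming extracts the inter-anchor region exactly once", {
  expect_equal(trim_to_anchors("AACTTTTATTAAAGGGTTTATTTCCACACC"), "GGGTTT")
  expect_error(trim_to_anchors("AACTTTTATTAAAGGGTTT"), "ATTTCCACA")
  # double-trim guard: anchors are gone after the first trim
  once <- trim_to_anchors("AACTTTTATTAAAGGGTTTATTTCCACACC")
  expect_error(trim_to_anchors(once), "not found")
  # duplicated anchor
  expect_error(
    trim_to_anchors("CTTTTATTAAAGGCTTTTATTAAAGGATTTCCACA"), "duplicated")
  # case-insensitive search
  expect_equal(trim_to_anchors("ctttTATTAAAggGTTTatttccacA"), "ggGTTT")
})

test_that("region read extraction uses 1 bp overlap semantics", {
  reads <- data.frame(id = c("r1", "r2", "r3"),
                      seq = "ACGT", qual = "IIII",
                      start = c(3300, 5000, 4295),
                      end = c(3400, 5100, 4400), stringsAsFactors = FALSE)
  out <- extract_region_reads(reads, c(3355, 4295))
  expect_setequal(out$id, c("r1", "r3"))
  expect_error(extract_region_reads(reads[2, ], c(3355, 4295)),
               "no informative reads")
  # interval-overlap count oracle on random read sets
  for (seed in 1:3) {
    rd <- withr::with_seed(seed, {
      s <- sample.int(10000, 50)
      data.frame(id = paste0("r", 1:50), seq = "A", qual = "I",
                 start = s, end = s + 100, stringsAsFactors = FALSE)
    })
    region <- c(4000, 6000)
    got <- tryCatch(nrow(extract_region_reads(rd, region)),
                    error = function(e) 0L)
    expect_equal(got, sum(rd$start <= 6000 & rd$end >= 4000))
  }
})

test_that("panel scoring applies the e > 0 and q > 0.5 acceptance rules", {
  sim <- simulate_mito(mito_sim_spec(read_error_rate = 0, coverage = 10),
                       seed = 41)
  panel <- mitotype_panel(sim$panel$accession, sim$panel$sequence)
  sc <- score_against_panel(sim$reads, panel)
  # error-free reads against their own source: e = 0, hence NOT accepted
  truth_row <- sc[sc$accession == "TRUTH", ]
  expect_equal(truth_row$e, 0)
  expect_false(truth_row$accepted)

  # all base qualities below Q20: q = 0, rejected everywhere
  low <- sim$reads
  low$qual <- vapply(nchar(low$seq), function(n)
    paste(rep("0", n), collapse = ""), character(1))   # Phred 15
  sc_low <- score_against_panel(low, panel)
  expect_true(all(sc_low$q == 0))
  expect_false(any(sc_low$accepted))
  expect_error(score_against_panel(sim$reads, panel[0, ]), "empty")
})

test_that("best-match selection is deterministic with documented tie-breaks", {
  m <- data.frame(accession = c("A", "B"), e = c(0.001, 0.002),
                  q = 0.9, length = c(500, 500), n_hq = 10,
                  accepted = TRUE, stringsAsFactors = FALSE)
  expect_equal(select_best(m)$accession, "A")

  # identical e: the longer reference wins
  m2 <- data.frame(accession = c("A", "B"), e = c(0.001, 0.001),
                   q = 0.9, length = c(600, 450), n_hq = 10,
                   accepted = TRUE, stringsAsFactors = FALSE)
  expect_equal(select_best(m2)$accession, "A")
  expect_false(select_best(m2)$ambiguous)

  # full tie: lexicographically smallest accession, flagged ambiguous
  m3 <- data.frame(accession = c("B", "A"), e = 0.001, q = 0.9,
                   length = 500, n_hq = 10, accepted = TRUE,
                   stringsAsFactors = FALSE)
  expect_equal(select_best(m3)$accession, "A")
  expect_true(select_best(m3)$ambiguous)
  # permutation invariance
  expect_equal(select_best(m2[2:1, ]), select_best(m2))

  m4 <- m; m4$accepted <- FALSE
  expect_error(select_best(m4), "no acceptable")
})

test_that("consensus carries majority SNPs and falls back to the reference", {
  ref <- withr::with_seed(8, paste(sample(c("A", "C", "G", "T"), 80,
                                          replace = TRUE), collapse = ""))
  # error-free reads tiled over the first 60 bases
  starts <- seq(1, 41, by = 4)
  reads <- data.frame(id = paste0("r", seq_along(starts)),
                      seq = vapply(starts, function(s)
                        substr(ref, s, s + 19), character(1)),
                      qual = strrep("I", 20), stringsAsFactors = FALSE)
  expect_equal(consensus_sequence(reads, ref), ref)

  # an injected SNP covered by every overlapping read appears in the
  # consensus; the uncovered tail keeps reference bases
  mut <- ref
  substr(mut, 10, 10) <- "A"   # C -> A at position 10
  reads_mut <- data.frame(id = paste0("m", seq_along(starts)),
                          seq = vapply(starts, function(s)
                            substr(mut, s, s + 19), character(1)),
                          qual = strrep("I", 20), stringsAsFactors = FALSE)
  cons <- consensus_sequence(reads_mut, ref)
  expect_equal(substr(cons, 10, 10), "A")
  expect_equal(substr(cons, 61, 80), substr(ref, 61, 80))
  expect_equal(nchar(cons), nchar(ref))
})

test_that("network recoding reduces the alphabet in the stated order", {
  expect_equal(recode_for_network("ACGT-A"), "AGGTCA")
  expect_equal(recode_for_network("AGT-TA"), "AGTCTA")
  expect_equal(recode_for_network("AGTTA"), "AGTTA")   # no C, no gap
  # recoded output has C only where gaps were
  x <- recode_for_network(c("AC-T", "A-GT"))
  expect_equal(x, c("AGCT", "ACGT"))
  # idempotent once gaps are gone
  expect_equal(recode_for_network(x), chartr("C", "G", x))
})

test_that("segregating-site counting masks columns above the missing threshold", {
  aln <- c("ACGT", "ACGT", "ACGA", "AC-T", rep("ACGT", 6))
  # column 3 has 1 gap among 10 (10% > 5%): masked even though variable
  out <- segregating_sites(aln)
  expect_equal(out$masked, 3L)
  expect_equal(out$columns, 4L)
  expect_equal(out$count, 1L)
  expect_equal(segregating_sites(rep("AAAA", 5))$count, 0L)

  # column-scan oracle on random alignments
  for (seed in 1:10) {
    aln2 <- withr::with_seed(seed, {
      M <- matrix(sample(c("A", "C", "G", "T", "-"), 8 * 30, TRUE,
                         prob = c(.3, .25, .2, .2, .05)), 8, 30)
      apply(M, 1, paste, collapse = "")
    })
    out2 <- segregating_sites(aln2, missing_mask_fraction = 0.05)
    M <- do.call(rbind, strsplit(aln2, ""))
    oracle <- 0L
    for (j in seq_len(ncol(M))) {
      col <- M[, j]
      if (mean(col == "-") > 0.05) next
      if (length(unique(col[col != "-"])) >= 2) oracle <- oracle + 1L
    }
    expect_equal(out2$count, oracle)
  }
})
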