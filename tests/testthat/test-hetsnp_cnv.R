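test_that("depth/chromosome site filter matches a brute-force oracle", {
  n <- 5
  sites <- data.frame(chrom = c("1", "1", "2", "17", "Scaff3"),
                      pos = c(100L, 200L, 100L, 100L, 100L),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos); sites <- sites[o, ]
  depth <- matrix(12L, n, 5)
  depth[3, 2] <- 8L                       # one sample below DP 9
  gm <- genotype_matrix(sites, matrix(0L, n, 5), depth, toy_samples(n),
                        het_mode = TRUE)
  out <- site_filter(gm)
  oracle <- vapply(seq_len(5), function(j)
    gm$sites$chrom[j] %in% as.character(1:16) && all(gm$depth[, j] >= 9),
    logical(1))
  expect_equal(out$sites$pos, gm$sites$pos[oracle])
  expect_equal(out$sites$chrom, gm$sites$chrom[oracle])

  # random matrices
  for (seed in 1:3) {
    gm2 <- withr::with_seed(seed, {
      sites2 <- data.frame(chrom = rep(c("1", "2", "20"), each = 10),
                           pos = rep(seq_len(10) * 50L, 3),
                           ref = "A", alt = "T", stringsAsFactors = FALSE)
      sites2 <- sites2[order(sites2$chrom, sites2$pos), ]
      genotype_matrix(sites2, matrix(0L, 4, 30),
                      matrix(rpois(4 * 30, 11), 4, 30),
                      toy_samples(4), het_mode = TRUE)
    })
    out2 <- site_filter(gm2)
    oracle2 <- gm2$sites$chrom %in% as.character(1:16) &
      apply(gm2$depth >= 9, 2, all)
    expect_equal(nrow(out2$sites), sum(oracle2))
  }
})

test_that("neighbour filter keeps hets with a close neighbour", {
  expect_equal(neighbor_filter(c(10000, 50000)), integer(0))
  expect_equal(neighbor_filter(c(10000, 11000, 50000)), c(10000, 11000))
  # O(n^2) pairwise oracle on random position sets
  for (seed in 1:5) {
    pos <- withr::with_seed(seed, sort(sample.int(1e5, 40)))
    keep <- neighbor_filter(pos, max_gap = 2000)
    oracle <- pos[vapply(seq_along(pos), function(i)
      any(abs(pos[-i] - pos[i]) <= 2000), logical(1))]
    expect_equal(keep, oracle)
  }
})

test_that("cluster calling applies count, span and depth rules", {
  # hand trace: 4 hets, span 2100, mean DP 26 vs 3 x drone mean 7
  cl <- call_clusters(pos = c(10000, 10800, 11500, 12100),
                      dp = c(25, 22, 30, 27), drone_mean_dp = 7)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 10000)
  expect_equal(cl$end, 12100)
  expect_equal(cl$n_het, 4L)
  expect_equal(cl$mean_dp, 26)

  # too few hets
  expect_equal(nrow(call_clusters(c(10000, 10800), c(30, 30), 7)), 0L)
  # span below 2 kb
  expect_equal(nrow(call_clusters(c(10000, 10500, 11000, 11500),
                                  rep(30, 4), 7)), 0L)
  # depth below 3x the drone average
  expect_equal(nrow(call_clusters(c(10000, 10800, 11500, 12100),
                                  rep(20, 4), 7)), 0L)
})

test_that("merging across drones unions overlaps and ignores input order", {
  clusters <- data.frame(
    drone_id = c("a", "b", "c"), chrom = "1",
    start = c(1000, 2500, 9000), end = c(3000, 4000, 9500),
    n_het = 3L, mean_dp = 30, drone_mean_dp = 9,
    stringsAsFactors = FALSE)
  st <- sample_table(c("a", "b", "c"), c("HN", "RJ", "RJ"))
  iv <- merge_across_drones(clusters, st, carrier_threshold = 1)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start, c(1000, 9000))
  expect_equal(iv$end, c(4000, 9500))
  expect_equal(iv$n_carriers, c(2L, 1L))
  expect_equal(iv$carriers_HN, c(1L, 0L))
  expect_equal(iv$carriers_RJ, c(1L, 1L))
  expect_equal(iv$high_frequency, c(TRUE, FALSE))

  # order independence
  perm <- clusters[c(3, 1, 2), ]
  iv2 <- merge_across_drones(perm, st, carrier_threshold = 1)
  expect_equal(iv2[names(iv2) != "carrier_ids"],
               iv[names(iv) != "carrier_ids"])

  # random cluster sets against a sweep-line union oracle
  for (seed in 1:5) {
    cl <- withr::with_seed(seed, {
      s <- sample.int(5e4, 25)
      data.frame(drone_id = sample(letters[1:5], 25, TRUE), chrom = "1",
                 start = s, end = s + sample.int(3000, 25), n_het = 3L,
                 mean_dp = 30, drone_mean_dp = 9, stringsAsFactors = FALSE)
    })
    st5 <- sample_table(letters[1:5], rep("HN", 5))
    iv3 <- merge_across_drones(cl, st5)
    # oracle: coordinate sweep over event points
    ev <- sort(unique(c(cl$start, cl$end + 1)))
    cov <- vapply(ev, function(x) any(cl$start <= x & cl$end >= x),
                  logical(1))
    n_components <- sum(diff(c(FALSE, cov)) == 1)
    expect_equal(nrow(iv3), n_components)
  }
})

test_that("population bias test reproduces the Pearson chi-squared", {
  r <- population_bias_test(c(23, 9), c(30, 30))
  expect_equal(r$chi2, 13.125, tolerance = 1e-10)
  expect_equal(signif(r$p_value, 2), 2.9e-4)

  r0 <- population_bias_test(c(12, 12), c(30, 30))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)

  # oracle: stats::chisq.test without continuity correction
  for (seed in 1:5) {
    k <- withr::with_seed(seed, c(sample(0:29, 1), sample(0:29, 1)))
    if (sum(k) == 0 || sum(k) == 60) next
    mine <- population_bias_test(k, c(30, 30))
    ref <- suppressWarnings(
      stats::chisq.test(rbind(k, 30 - k), correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(population_bias_test(c(5, 1), c(30, 0)), "size 0")
})

test_that("annotation flags recombination overlap and genes within the margin", {
  iv <- data.frame(chrom = "1", start = 1000, end = 2000)
  genes <- data.frame(chrom = "1", start = c(3500, 4100), end = c(5000, 5000),
                      gene_id = c("g_near", "g_far"),
                      stringsAsFactors = FALSE)
  ann <- annotate_intervals(iv, recomb = NULL, genes = genes,
                            gene_margin = 2000)
  expect_equal(ann$nearby_genes[[1]], "g_near")

  recomb <- data.frame(chrom = "1", start = 1999, end = 2100)
  ann2 <- annotate_intervals(iv, recomb = recomb, genes = NULL)
  expect_true(ann2$overlaps_recombination)

  # quadratic-scan oracle on random interval/gene sets
  for (seed in 1:3) {
    dat <- withr::with_seed(seed, {
      s1 <- sample.int(1e5, 10); s2 <- sample.int(1e5, 15)
      list(iv = data.frame(chrom = "1", start = s1, end = s1 + 2000),
           genes = data.frame(chrom = "1", start = s2, end = s2 + 1500,
                              gene_id = paste0("g", 1:15),
                              stringsAsFactors = FALSE))
    })
    ann3 <- annotate_intervals(dat$iv, genes = dat$genes, gene_margin = 2000)
    for (i in 1:10) {
      oracle <- dat$genes$gene_id[
        dat$genes$start <= dat$iv$end[i] + 2000 &
          dat$genes$end >= dat$iv$start[i] - 2000]
      expect_setequal(ann3$nearby_genes[[i]], oracle)
    }
  }
})
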