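# Seeded generators emulating the statistical structure of haploid drone
# resequencing cohorts: hierarchical drift with a known kinship matrix,
# founder-pool haplotypes with block LD, selective sweeps, collapsed
# duplications (hetSNP clusters with inflated depth), and mitotype amplicons
# with error-bearing reads.

#' Default true kinship matrix for simulated cohorts
#'
#' Co-ancestry matrix for three C-lineage-derived populations: a pure
#' C-lineage reference population, a honey-production population (HN) and a
#' royal-jelly population (RJ).  The two honey-oriented populations are
#' exchangeable mild drifters (self-kinship 0.03, correlation 0.3 between
#' them), while RJ carries five-fold stronger drift (0.15) and little shared
#' history with either (correlation 0.15) — the bottleneck and
#' closed-population management of royal-jelly selection lines.  This
#' structure places the RJ-versus-rest contrast essentially along one
#' eigenvector of `F`, which is what lets a spectral decomposition pinpoint
#' the population under selection; the drift magnitudes also sit in the
#' regime where the Gaussian drift approximation underlying FLK is accurate
#' (boundary truncation of simulated frequencies is rare), so that null
#' calibration is a fair test of the statistic.
#'
#' @param populations population labels; the drift coefficients
#'   (0.03, 0.03, 0.15, 0.18, ...) are recycled in order.
#' @return Symmetric positive-definite matrix with `populations` as dimnames.
#' @export
default_kinship <- function(populations = c("C", "HN", "RJ")) {
  npop <- length(populations)
  corr <- matrix(0.15, npop, npop)
  if (npop >= 2) corr[1, 2] <- corr[2, 1] <- 0.30
  diag(corr) <- 1
  drift <- rep_len(c(0.030, 0.030, 0.150, 0.180), npop)
  F <- corr * outer(sqrt(drift), sqrt(drift))
  dimnames(F) <- list(populations, populations)
  F
}

#' Specification of a pure-drift simulation
#'
#' Describes the hierarchical-drift model from which population allele
#' frequencies are simulated: each site draws an ancestral frequency `p0`
#' and then a population frequency vector from a multivariate normal with
#' mean `p0` and covariance `p0 (1 - p0) F`, truncated to `[0, 1]`.
#'
#' @param kinship true co-ancestry matrix `F` (symmetric PSD, diagonal in
#'   (0, 1)); defaults to [default_kinship()].
#' @param nsites number of simulated sites.
#' @param p0_range range of the uniform ancestral allele-frequency sampler.
#' @param seed integer seed; every draw is deterministic given it.
#' @return Object of class `drift_model`.
#' @export
drift_model <- function(kinship = default_kinship(), nsites = 20000,
                        p0_range = c(0.05, 0.95), seed = 1) {
  kinship <- as.matrix(kinship)
  if (!isSymmetric(unname(kinship), tol = 1e-10))
    stop("kinship must be symmetric")
  ev <- eigen(kinship, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("kinship must be positive semi-definite")
  if (any(diag(kinship) < 0) || any(diag(kinship) >= 1))
    stop("kinship diagonal must lie in [0, 1)")
  if (is.null(rownames(kinship)))
    dimnames(kinship) <- list(paste0("P", seq_len(nrow(kinship))),
                              paste0("P", seq_len(nrow(kinship))))
  structure(list(kinship = kinship, npop = nrow(kinship),
                 nsites = as.integer(nsites),
                 p0_range = p0_range, seed = as.integer(seed)),
            class = "drift_model")
}

#' Simulate population allele frequencies under hierarchical drift
#'
#' For each site, draws the ancestral frequency `p0` uniformly from the
#' model's range, then the population frequency vector from
#' `MVN(p0 * 1, p0 (1 - p0) F)` truncated to `[0, 1]`.  Sites that end up
#' fixed for the same allele in every population are redrawn (up to 10
#' retries) since they carry no information.
#'
#' @param model a [drift_model()].
#' @return List with `freq` (npop x nsites matrix, populations as rownames),
#'   `p0` (length-nsites ancestral frequencies) and `model`.
#' @export
simulate_frequencies <- function(model) {
  stopifnot(inherits(model, "drift_model"))
  F <- model$kinship
  npop <- model$npop
  # PSD but possibly singular F: use eigen square root
  es <- eigen(F, symmetric = TRUE)
  rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), npop) %*% t(es$vectors)
  draw <- function(n) {
    p0 <- runif(n, model$p0_range[1], model$p0_range[2])
    Z <- matrix(rnorm(n * npop), npop, n)
    P <- rep(1, npop) %o% p0 + (rt %*% Z) * rep(sqrt(p0 * (1 - p0)),
                                                each = npop)
    P[P < 0] <- 0
    P[P > 1] <- 1
    list(p0 = p0, P = P)
  }
  withr_seed(model$seed, {
    d <- draw(model$nsites)
    for (retry in seq_len(10)) {
      fixed <- colSums(d$P == 0) == npop | colSums(d$P == 1) == npop
      if (!any(fixed)) break
      rd <- draw(sum(fixed))
      d$P[, fixed] <- rd$P
      d$p0[fixed] <- rd$p0
    }
    rownames(d$P) <- rownames(F)
    list(freq = d$P, p0 = d$p0, model = model)
  })
}

#' Simulate haploid genotypes with block LD from population frequencies
#'
#' Within each LD block a small pool of founder haplotypes is drawn per
#' population (each founder allele Bernoulli at the population frequency),
#' and every sampled drone copies one founder per block; block boundaries
#' act as recombination points.  Pooled allele frequencies therefore match
#' the input frequencies up to two-stage sampling error that shrinks as
#' `n_founders` grows.  Depth is Poisson with a per-site Gamma mappability
#' factor shared across drones (so that site-level depth is correlated
#' between individuals, as in real data).
#'
#' @param freqs result of [simulate_frequencies()], or an npop x nsites
#'   frequency matrix with population rownames.
#' @param nsamples_per_pop drones per population (recycled).
#' @param ld_block block length in sites (`1` = independent sites).
#' @param n_founders founder haplotypes per population per block; the
#'   default (60, about twice the default sample size) emulates a stable
#'   population whose haplotype diversity is not bottlenecked, so that
#'   neutral cross-population differentiation stays consistent with the
#'   drift model; small pools create strong bottleneck LD and
#'   population-private haplotypes.
#' @param seed integer seed.
#' @param chrom chromosome label for all sites.
#' @param spacing_bp distance between adjacent sites in bp.
#' @param mean_depth mean per-drone sequencing depth.
#' @param depth_shape shape of the per-site Gamma(shape, shape) mappability
#'   factor (larger = less overdispersion).
#' @return Haploid [genotype_matrix()].
#' @export
simulate_haplotypes <- function(freqs, nsamples_per_pop = 30, ld_block = 25,
                                n_founders = 60, seed = 1, chrom = "1",
                                spacing_bp = 500, mean_depth = 15,
                                depth_shape = 25) {
  P <- if (is.list(freqs)) freqs$freq else freqs
  stopifnot(ld_block >= 1, n_founders >= 1)
  npop <- nrow(P); nsites <- ncol(P)
  pops <- rownames(P)
  nper <- rep_len(nsamples_per_pop, npop)
  n <- sum(nper)
  blocks <- split(seq_len(nsites), (seq_len(nsites) - 1L) %/% ld_block)
  withr_seed(seed, {
    calls <- matrix(0L, n, nsites)
    row0 <- 0L
    for (ip in seq_len(npop)) {
      for (b in blocks) {
        founders <- matrix(rbinom(n_founders * length(b), 1,
                                  rep(P[ip, b], each = n_founders)),
                           n_founders, length(b))
        pick <- sample.int(n_founders, nper[ip], replace = TRUE)
        calls[row0 + seq_len(nper[ip]), b] <- founders[pick, , drop = FALSE]
      }
      row0 <- row0 + nper[ip]
    }
    site_factor <- rgamma(nsites, shape = depth_shape, rate = depth_shape)
    depth <- matrix(rpois(n * nsites, rep(mean_depth * site_factor,
                                          each = n)), n, nsites)
    alle <- matrix(c("A", "C", "G", "T")[cbind(
      sample.int(4, nsites, TRUE),
      sample.int(3, nsites, TRUE))], nsites, 2)
    # ensure ref != alt
    alle[, 2] <- c("A", "C", "G", "T")[
      (match(alle[, 1], c("A", "C", "G", "T")) +
         sample.int(3, nsites, TRUE) - 1L) %% 4L + 1L]
    st <- sample_table(
      sprintf("%s%02d", rep(pops, nper),
              unlist(lapply(nper, seq_len))),
      rep(pops, nper), ploidy = 1L)
    sites <- data.frame(chrom = chrom,
                        pos = as.integer(seq_len(nsites)) * spacing_bp,
                        ref = alle[, 1], alt = alle[, 2],
                        stringsAsFactors = FALSE)
    genotype_matrix(sites, calls, depth, st)
  })
}

#' Selective-sweep specification
#'
#' @param target_population population label to sweep.
#' @param chrom,start,end swept window (1-based inclusive bp).
#' @param sweep_strength fraction in (0, 1] to which the frequency of one
#'   resident haplotype is raised in the target population.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(target_population, chrom, start, end,
                       sweep_strength = 0.9) {
  stopifnot(sweep_strength > 0, sweep_strength <= 1, end >= start)
  structure(list(target_population = target_population, chrom = chrom,
                 start = start, end = end,
                 sweep_strength = sweep_strength), class = "sweep_spec")
}

#' Inject a selective sweep into a haploid genotype matrix
#'
#' Picks one resident window haplotype of the target population at random
#' and copies it over other randomly chosen drones of that population until
#' its frequency reaches at least `sweep_strength`.  Other populations and
#' all sites outside the window are untouched.
#'
#' @param gm haploid [genotype_matrix()].
#' @param spec a [sweep_spec()].
#' @param seed integer seed.
#' @return List with the modified `gm`, the swept site indices `window_idx`
#'   and the donor haplotype row `donor`.
#' @export
inject_sweep <- function(gm, spec, seed = 1) {
  idx <- which(gm$sites$chrom == spec$chrom &
                 gm$sites$pos >= spec$start & gm$sites$pos <= spec$end)
  if (!length(idx)) stop("sweep window contains no sites")
  tgt <- which(gm$samples$population == spec$target_population)
  if (!length(tgt)) stop("unknown target population: ",
                         spec$target_population)
  withr_seed(seed, {
    donor <- sample(tgt, 1)
    hap <- gm$calls[donor, idx]
    need <- ceiling(spec$sweep_strength * length(tgt))
    is_donor_hap <- function() {
      vapply(tgt, function(i) all(gm$calls[i, idx] == hap), logical(1))
    }
    carriers <- is_donor_hap()
    others <- tgt[!carriers]
    deficit <- need - sum(carriers)
    if (deficit > 0) {
      recip <- sample(others, min(deficit, length(others)))
      gm$calls[recip, idx] <- rep(hap, each = length(recip))
    }
    list(gm = gm, window_idx = idx, donor = donor)
  })
}

#' Collapsed-duplication (CNV) specification
#'
#' A duplicated segment whose copies are collapsed onto one reference locus:
#' carriers show heterozygous calls at paralogous sequence variants inside
#' the segment and proportionally inflated depth.
#'
#' @param chrom,start,end duplicated segment (1-based inclusive bp).
#' @param carrier_fraction per-population carrier probability (named vector,
#'   or a single value recycled over populations).
#' @param paralog_divergence per-site probability that a segment site is a
#'   paralogous variant (hence het in carriers).  Sites in simulated
#'   cohorts stand for ~100 bp callable tracts, so the default 0.2
#'   corresponds to ~2 paralogous variants per kb between collapsed
#'   copies.
#' @param depth_inflation_factor multiplier applied to carrier depth within
#'   the segment (>= 1; a simple collapsed duplication gives 2, higher-copy
#'   families more).
#' @return Object of class `cnv_spec`.
#' @export
cnv_spec <- function(chrom, start, end, carrier_fraction = 0.5,
                     paralog_divergence = 0.2,
                     depth_inflation_factor = 3) {
  stopifnot(end >= start, depth_inflation_factor >= 1,
            all(carrier_fraction >= 0), all(carrier_fraction <= 1),
            paralog_divergence >= 0, paralog_divergence <= 1)
  structure(list(chrom = chrom, start = start, end = end,
                 carrier_fraction = carrier_fraction,
                 paralog_divergence = paralog_divergence,
                 depth_inflation_factor = depth_inflation_factor),
            class = "cnv_spec")
}

#' Inject a collapsed duplication into a haploid genotype matrix
#'
#' Paralogous variant positions are drawn once (shared by all carriers, as
#' for a real segregating duplication): each segment site becomes a PSV with
#' probability `paralog_divergence`.  Carrier drones, drawn per population
#' with the spec's carrier fraction, get het calls at the PSV sites and
#' their depth multiplied by `depth_inflation_factor` across the whole
#' segment.  Non-carriers are untouched.  The generator retries the PSV draw
#' (up to 20 times) until at least `min_psv` variant sites arise, so that
#' downstream cluster detection is well-posed; it fails if the segment
#' cannot support that many.
#'
#' @param gm haploid [genotype_matrix()].
#' @param spec a [cnv_spec()].
#' @param seed integer seed.
#' @param min_psv minimum number of realized PSV sites.
#' @return List with modified `gm` (het calls enabled), `carriers` (sample
#'   ids), `psv_idx` (site indices) and `segment_idx`.
#' @export
inject_cnv <- function(gm, spec, seed = 1, min_psv = 3) {
  seg <- which(gm$sites$chrom == spec$chrom &
                 gm$sites$pos >= spec$start & gm$sites$pos <= spec$end)
  if (length(seg) < min_psv && spec$paralog_divergence > 0)
    stop("segment contains too few sites for min_psv")
  pops <- unique(gm$samples$population)
  cf <- spec$carrier_fraction
  if (is.null(names(cf))) cf <- setNames(rep_len(cf, length(pops)), pops)
  withr_seed(seed, {
    psv <- integer(0)
    if (spec$paralog_divergence > 0) {
      for (retry in seq_len(20)) {
        psv <- seg[runif(length(seg)) < spec$paralog_divergence]
        if (length(psv) >= min_psv) break
      }
      if (length(psv) < min_psv)
        stop("could not realize ", min_psv, " PSV sites; ",
             "increase site density or paralog_divergence")
    }
    carriers <- which(runif(nrow(gm$samples)) <
                        cf[gm$samples$population])
    if (length(carriers)) {
      if (length(psv))
        gm$calls[carriers, psv] <- CALL_HET
      gm$depth[carriers, seg] <-
        as.integer(round(gm$depth[carriers, seg, drop = FALSE] *
                           spec$depth_inflation_factor))
    }
    gm$het_mode <- TRUE
    list(gm = gm, carriers = gm$samples$sample_id[carriers],
         psv_idx = psv, segment_idx = seg)
  })
}

#' Simulate a CNV screening cohort
#'
#' Convenience wrapper composing [simulate_frequencies()],
#' [simulate_haplotypes()] and [inject_cnv()] into the study design used to
#' exercise the hetSNP/CNV pipeline: two managed populations (HN, RJ) of
#' haploid drones, dense sites (one per 100 bp), and optionally one injected
#' collapsed duplication.
#'
#' @param seed integer seed.
#' @param n_per_pop drones per population.
#' @param nsites simulated sites.
#' @param cnv a [cnv_spec()], or `NULL` for a null cohort without CNV.
#' @param mean_depth mean per-drone depth.
#' @return List with `gm` and (when a CNV is injected) `truth` as returned
#'   by [inject_cnv()].
#' @export
simulate_cnv_cohort <- function(seed = 1, n_per_pop = 10, nsites = 3000,
                                cnv = cnv_spec("1", 150001, 160000),
                                mean_depth = 15) {
  F <- default_kinship(c("HN", "RJ"))
  fr <- simulate_frequencies(drift_model(F, nsites = nsites, seed = seed))
  gm <- simulate_haplotypes(fr, nsamples_per_pop = n_per_pop,
                            ld_block = 25, seed = seed + 1,
                            spacing_bp = 100, mean_depth = mean_depth)
  if (is.null(cnv)) {
    gm$het_mode <- TRUE
    return(list(gm = gm, truth = NULL))
  }
  inj <- inject_cnv(gm, cnv, seed = seed + 2)
  list(gm = inj$gm, truth = inj)
}

#' Mitotype simulation specification
#'
#' Architecture of the simulated tRNA-Leu/cox2 intergenic amplicon:
#' `[5' anchor][optional P element][Q element x q_copies][3' anchor]`, with
#' point mutations, plus uniform-error reads drawn from it.
#'
#' @param p_element_present logical; include the P element.
#' @param q_copies number of tandem Q-element copies (1-3 typical).
#' @param n_snps number of random point mutations injected into the
#'   inter-anchor region.
#' @param read_length,coverage,read_error_rate read simulation parameters.
#' @param mean_quality,sd_quality Phred base-quality profile.
#' @return Object of class `mito_sim_spec`.
#' @export
mito_sim_spec <- function(p_element_present = TRUE, q_copies = 2,
                          n_snps = 5, read_length = 100, coverage = 20,
                          read_error_rate = 0.005, mean_quality = 35,
                          sd_quality = 3) {
  stopifnot(q_copies >= 1, read_error_rate >= 0, read_error_rate < 1,
            coverage >= 1)
  structure(list(p_element_present = p_element_present,
                 q_copies = as.integer(q_copies), n_snps = n_snps,
                 read_length = read_length, coverage = coverage,
                 read_error_rate = read_error_rate,
                 mean_quality = mean_quality, sd_quality = sd_quality),
            class = "mito_sim_spec")
}

ANCHOR_5P <- "CTTTTATTAAA"
ANCHOR_3P <- "ATTTCCACA"

rand_seq <- function(n, at_bias = 0.85) {
  p <- c(A = at_bias / 2, T = at_bias / 2,
         C = (1 - at_bias) / 2, G = (1 - at_bias) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_seq <- function(s, nedits) {
  v <- strsplit(s, "")[[1]]
  pos <- sample.int(length(v), nedits)
  for (i in pos) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}

#' Simulate a mitotype amplicon, a reference panel and sequencing reads
#'
#' Assembles the truth mitotype per the spec, builds a panel containing the
#' truth plus decoys differing in P-element presence, Q copy number and/or
#' point edits (every decoy at >= `decoy_edits` edits from the truth), and
#' draws uniform-coverage reads with per-base substitution errors and
#' Normal-profile base qualities.
#'
#' @param spec a [mito_sim_spec()].
#' @param n_decoys decoy panel entries.
#' @param decoy_edits minimum point edits separating each decoy.
#' @param seed integer seed.
#' @return List with `truth` (accession, raw + trimmed sequence, SNP
#'   positions), `panel` (`data.frame(accession, sequence)`, trimmed to the
#'   inter-anchor region), and `reads`
#'   (`data.frame(id, seq, qual, start, end)`; qualities Phred+33).
#' @export
simulate_mito <- function(spec = mito_sim_spec(), n_decoys = 10,
                          decoy_edits = 2, seed = 1) {
  withr_seed(seed, {
    # anchor motifs must stay unique in every constructed sequence
    # (trimming requires it), so rebuild on the rare accidental hit
    anchored_ok <- function(s) {
      su <- toupper(s)
      length(gregexpr(ANCHOR_5P, su, fixed = TRUE)[[1]]) == 1L &&
        gregexpr(ANCHOR_5P, su, fixed = TRUE)[[1]][1] != -1L &&
        length(gregexpr(ANCHOR_3P, su, fixed = TRUE)[[1]]) == 1L &&
        gregexpr(ANCHOR_3P, su, fixed = TRUE)[[1]][1] != -1L
    }
    p_el <- rand_seq(60)
    q_el <- rand_seq(190)
    build <- function(p_present, q_copies, inner_edits = 0) {
      for (try in seq_len(50)) {
        inner <- paste0(if (p_present) p_el else "",
                        paste(rep(q_el, q_copies), collapse = ""))
        if (inner_edits > 0) inner <- mutate_seq(inner, inner_edits)
        s <- paste0(ANCHOR_5P, inner, ANCHOR_3P)
        if (anchored_ok(s)) return(s)
        # persistent collision lives in the elements: redraw them
        p_el <<- rand_seq(60)
        q_el <<- rand_seq(190)
      }
      stop("could not build an anchor-unique mitotype sequence")
    }
    truth_raw <- build(spec$p_element_present, spec$q_copies,
                       inner_edits = spec$n_snps)
    # decoys: same element library, different architecture and/or edits
    archs <- expand.grid(p = c(TRUE, FALSE), q = 1:3)
    archs <- archs[!(archs$p == spec$p_element_present &
                       archs$q == spec$q_copies), ]
    panel_seq <- character(n_decoys)
    for (i in seq_len(n_decoys)) {
      a <- archs[(i - 1) %% nrow(archs) + 1, ]
      panel_seq[i] <- build(a$p, a$q, inner_edits = decoy_edits + (i %/% 3))
    }
    panel <- data.frame(
      accession = c("TRUTH", sprintf("DECOY%02d", seq_len(n_decoys))),
      sequence = vapply(c(truth_raw, panel_seq), trim_to_anchors,
                        character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    # drop accidental duplicates of the truth (short architectures + edits
    # can collide); keep panel entries distinct
    panel <- panel[!duplicated(panel$sequence), , drop = FALSE]

    len <- nchar(truth_raw)
    nreads <- max(1L, ceiling(spec$coverage * len / spec$read_length))
    starts <- sample.int(len - spec$read_length + 1L, nreads, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    tv <- strsplit(truth_raw, "")[[1]]
    seqs <- character(nreads); quals <- character(nreads)
    for (r in seq_len(nreads)) {
      v <- tv[starts[r]:(starts[r] + spec$read_length - 1L)]
      err <- runif(spec$read_length) < spec$read_error_rate
      if (any(err))
        v[err] <- vapply(v[err], function(b) sample(setdiff(bases, b), 1),
                         character(1))
      q <- pmin(pmax(round(rnorm(spec$read_length, spec$mean_quality,
                                 spec$sd_quality)), 2), 41)
      seqs[r] <- paste(v, collapse = "")
      quals[r] <- rawToChar(as.raw(q + 33L))
    }
    reads <- data.frame(id = sprintf("read%04d", seq_len(nreads)),
                        seq = seqs, qual = quals, start = starts,
                        end = starts + spec$read_length - 1L,
                        stringsAsFactors = FALSE)
    list(truth = list(accession = "TRUTH", raw = truth_raw,
                      trimmed = panel$sequence[panel$accession == "TRUTH"]),
         panel = panel, reads = reads, spec = spec)
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads `data.frame(id, seq, qual)` as produced by
#'   [simulate_mito()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file into the reads data frame used by the mitotype path
#'
#' @param path FASTQ file (optionally gzipped).
#' @return `data.frame(id, seq, qual)`.
#' @export
read_fastq <- function(path) {
  # Biostrings notes that mcols are dropped on construction; harmless here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write a truth file for synthetic cohorts
#'
#' Records the generating truth (sweep window, CNV segment and carriers,
#' true mitotype accession, seeds) as JSON for test assertions.
#'
#' @param truth named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
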