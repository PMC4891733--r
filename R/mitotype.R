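# Reconstruction of the mitochondrial tRNA-Leu/cox2 mitotype of a sample
# from whole-genome sequencing reads scored against a reference panel, and
# preparation of aligned sequences for haplotype-network analysis.

#' Trim a mitotype reference to the inter-anchor region
#'
#' References are trimmed to start after the 3' end of the tRNA-Leu anchor
#' motif and end before the 5' end of the cox2 anchor motif.  Both motifs
#' must occur exactly once (case-insensitive); trimming an already trimmed
#' sequence therefore errors rather than silently double-trimming.
#'
#' @param x raw sequence (character scalar).
#' @param anchor5 upstream anchor motif (3' end of tRNA-Leu).
#' @param anchor3 downstream anchor motif (5' end of cox2).
#' @return The subsequence strictly between the anchors.
#' @export
trim_to_anchors <- function(x, anchor5 = ANCHOR_5P, anchor3 = ANCHOR_3P) {
  xs <- toupper(x)
  find1 <- function(motif) {
    hits <- gregexpr(motif, xs, fixed = TRUE)[[1]]
    if (hits[1] == -1L) stop("anchor motif not found: ", motif)
    if (length(hits) > 1L) stop("anchor motif duplicated: ", motif)
    hits[1]
  }
  a5 <- find1(toupper(anchor5))
  a3 <- find1(toupper(anchor3))
  from <- a5 + nchar(anchor5)
  to <- a3 - 1L
  if (to < from) return("")
  substr(x, from, to)
}

#' Build a mitotype reference panel
#'
#' @param accession character vector of unique accessions.
#' @param sequence inter-anchor (trimmed) sequences.
#' @return `data.frame(accession, sequence, length)` of class
#'   `mitotype_panel`.
#' @export
mitotype_panel <- function(accession, sequence) {
  if (anyDuplicated(accession)) stop("accessions must be unique")
  if (any(!nzchar(sequence))) stop("panel sequences must be non-empty")
  out <- data.frame(accession = as.character(accession),
                    sequence = toupper(sequence),
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("mitotype_panel", "data.frame")
  out
}

#' Extract reads overlapping a genomic region
#'
#' Returns the reads whose alignment interval overlaps the region by at
#' least 1 bp (full containment is not required; a single overlapping base
#' is informative for the flanking anchors).
#'
#' @param reads `data.frame(id, seq, qual, start, end)` of positioned reads
#'   (e.g. exported from an alignment as FASTQ plus coordinates).
#' @param region `list(start, end)` or numeric `c(start, end)` (1-based
#'   inclusive).
#' @return The overlapping subset of `reads`; errors if empty.
#' @export
extract_region_reads <- function(reads, region) {
  if (is.numeric(region)) region <- list(start = region[1], end = region[2])
  stopifnot(all(c("start", "end") %in% names(reads)))
  keep <- reads$start <= region$end & reads$end >= region$start
  if (!any(keep)) stop("no informative reads in region")
  reads[keep, , drop = FALSE]
}

mito_align <- function(seqs, subject, gap_open = 4, gap_ext = 1,
                       match = 1, mismatch = -2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_ext)
}

phred_vec <- function(qual) as.integer(charToRaw(qual)) - 33L

#' Score reads against every panel entry
#'
#' Each read is aligned to each reference by deterministic local gapped
#' alignment (match +1, mismatch -2, gap open -4, gap extend -1).
#' High-quality (HQ) alignments are those with score at least
#' `hq_score_min` (default half the read length, the score a mostly intact
#' read achieves).  Per reference:
#' `e` = HQ mismatch rate + HQ indel-event rate (both per HQ aligned base),
#' recorded to 6 decimals, and
#' `q` = fraction of all aligned bases that are HQ-aligned with base
#' quality >= 20.  A match is accepted when `e > 0` and `q > 0.5`: the
#' `e > 0` rule guards against a short reference aligning perfectly while a
#' longer one explains more of the data, and `q > 0.5` discards alignments
#' dominated by poor base qualities.
#'
#' @param reads `data.frame(id, seq, qual)`.
#' @param panel a [mitotype_panel()] (or `data.frame(accession, sequence)`).
#' @param hq_score_min HQ alignment-score threshold; `NULL` = half the
#'   median read length.
#' @return `data.frame(accession, e, q, length, n_hq, accepted)`.
#' @export
score_against_panel <- function(reads, panel, hq_score_min = NULL) {
  if (!nrow(panel)) stop("empty mitotype panel")
  if (!nrow(reads)) stop("no reads to score")
  if (is.null(hq_score_min))
    hq_score_min <- stats::median(nchar(reads$seq)) / 2
  quals <- lapply(reads$qual, phred_vec)
  res <- lapply(seq_len(nrow(panel)), function(i) {
    aln <- mito_align(reads$seq, panel$sequence[i])
    sc <- Biostrings::score(aln)
    nmm <- Biostrings::nmismatch(aln)
    nmt <- Biostrings::nmatch(aln)
    ins <- Biostrings::nindel(aln)
    # indel events = number of gap openings (insertions + deletions);
    # nindel reports the event count in the "Length" column
    nev <- Biostrings::insertion(ins)[, "Length"] +
      Biostrings::deletion(ins)[, "Length"]
    aligned <- nmm + nmt
    hq <- sc >= hq_score_min
    pr <- as.data.frame(Biostrings::pattern(aln)@range)
    q20 <- vapply(seq_len(nrow(reads)), function(r) {
      if (!hq[r] || aligned[r] == 0) return(0L)
      qq <- quals[[r]][pr$start[r]:pr$end[r]]
      sum(qq >= 20L)
    }, integer(1))
    hq_aligned <- sum(aligned[hq])
    e <- if (hq_aligned > 0)
      sum(nmm[hq]) / hq_aligned + sum(nev[hq]) / hq_aligned else NA_real_
    qv <- if (sum(aligned) > 0) sum(q20) / sum(aligned) else 0
    data.frame(accession = panel$accession[i],
               e = if (is.na(e)) NA_real_ else round(e, 6),
               q = qv, length = nchar(panel$sequence[i]),
               n_hq = sum(hq), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$accepted <- !is.na(out$e) & out$e > 0 & out$q > 0.5
  rownames(out) <- NULL
  out
}

#' Select the best mitotype match
#'
#' Among accepted matches: lowest error rate `e` (compared at the recorded
#' 6-decimal precision); ties broken by longest reference; a remaining tie
#' picks the lexicographically smallest accession and flags the result as
#' ambiguous.  Deterministic and invariant to input order.
#'
#' @param matches output of [score_against_panel()].
#' @return The winning row with an added `ambiguous` flag; errors when no
#'   match is accepted.
#' @export
select_best <- function(matches) {
  acc <- matches[matches$accepted, , drop = FALSE]
  if (!nrow(acc)) stop("no acceptable mitotype (e > 0 & q > 0.5 failed)")
  e6 <- round(acc$e, 6)
  acc <- acc[order(e6, -acc$length, acc$accession), , drop = FALSE]
  top <- acc[round(acc$e, 6) == round(acc$e[1], 6) &
               acc$length == acc$length[1], , drop = FALSE]
  best <- acc[1, , drop = FALSE]
  best$ambiguous <- nrow(top) > 1
  rownames(best) <- NULL
  best
}

#' Consensus sequence of reads against a reference
#'
#' Pileup by local alignment: at each reference position covered by at
#' least one read, the majority base replaces the reference base (ties
#' keep the reference base when it is among the tied bases, otherwise take
#' the alphabetically first — deterministic).  Uncovered positions keep the
#' reference base; indels are not applied, so the consensus has exactly the
#' reference length.
#'
#' @param reads `data.frame(id, seq, qual)`.
#' @param reference reference sequence (character scalar).
#' @return Consensus sequence (character scalar of the reference length).
#' @export
consensus_sequence <- function(reads, reference) {
  L <- nchar(reference)
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, 4, L, dimnames = list(bases, NULL))
  if (nrow(reads)) {
    aln <- mito_align(reads$seq, reference)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    s0 <- Biostrings::start(Biostrings::subject(aln))
    for (r in seq_along(pa)) {
      pv <- strsplit(pa[r], "")[[1]]
      sv <- strsplit(sa[r], "")[[1]]
      ref_pos <- s0[r] - 1L
      for (cidx in seq_along(sv)) {
        if (sv[cidx] != "-") {
          ref_pos <- ref_pos + 1L
          b <- pv[cidx]
          if (b %in% bases)
            votes[b, ref_pos] <- votes[b, ref_pos] + 1L
        }
      }
    }
  }
  refv <- strsplit(toupper(reference), "")[[1]]
  out <- refv
  cov <- colSums(votes)
  for (j in which(cov > 0)) {
    mx <- max(votes[, j])
    top <- bases[votes[, j] == mx]
    out[j] <- if (refv[j] %in% top) refv[j] else top[1]
  }
  paste(out, collapse = "")
}

#' Recode an alignment to three nucleotides for network analysis
#'
#' Median-joining network software masks sites with missing data, which
#' silently removes indel-rich diagnostic elements (the P element is absent
#' in C-lineage mitotypes, and Q-element copies are absent in short
#' mitotypes).  Recoding 'C' as 'G' first and then gaps as 'C' keeps those
#' columns in the analysis on a 3-letter alphabet.
#'
#' @param aln character vector of aligned sequences (equal lengths; gaps
#'   as `-`).
#' @return Recoded alignment (same dimensions).
#' @export
recode_for_network <- function(aln) {
  if (length(unique(nchar(aln))) > 1)
    stop("sequences must be aligned (equal lengths)")
  chartr("-", "C", chartr("Cc", "Gg", aln))
}

#' Count segregating sites with missing-data masking
#'
#' Columns whose gap/N fraction exceeds `missing_mask_fraction` are masked
#' (mirroring network software defaults); among the remaining columns,
#' those with at least two distinct observed states are segregating.
#'
#' @param aln character vector of aligned sequences (equal lengths).
#' @param missing_mask_fraction masking threshold (strictly greater than).
#' @return List with `count`, `columns` (segregating column indices) and
#'   `masked` (masked column indices).
#' @export
segregating_sites <- function(aln, missing_mask_fraction = 0.05) {
  if (length(unique(nchar(aln))) > 1)
    stop("sequences must be aligned (equal lengths)")
  M <- do.call(rbind, strsplit(toupper(aln), ""))
  miss <- M == "-" | M == "N"
  mask <- colMeans(miss) > missing_mask_fraction
  seg <- vapply(seq_len(ncol(M)), function(j) {
    if (mask[j]) return(FALSE)
    states <- unique(M[!miss[, j], j])
    length(states) >= 2
  }, logical(1))
  list(count = sum(seg), columns = which(seg), masked = which(mask))
}

#' Write an alignment as FASTA
#'
#' @param aln named character vector of (possibly gapped) sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0(">", names(aln)), aln), con)
  invisible(path)
}

#' End-to-end mitotype reconstruction
#'
#' Scores region reads against the panel, selects the best match and
#' builds the consensus sequence against it.
#'
#' @param reads `data.frame(id, seq, qual)` of region reads.
#' @param panel a [mitotype_panel()].
#' @param hq_score_min see [score_against_panel()].
#' @return List with `matches`, `best` and `consensus`.
#' @export
reconstruct_mitotype <- function(reads, panel, hq_score_min = NULL) {
  matches <- score_against_panel(reads, panel,
                                 hq_score_min = hq_score_min)
  best <- select_best(matches)
  ref <- panel$sequence[panel$accession == best$accession]
  list(matches = matches, best = best,
       consensus = consensus_sequence(reads, ref))
}
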