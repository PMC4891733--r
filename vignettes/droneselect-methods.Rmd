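---
title: "Methods: selection scans, hetSNP CNV screening and mitotype reconstruction in haploid drones"
author: "droneselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, hetSNP CNV screening and mitotype reconstruction in haploid drones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droneselect)
```

`droneselect` implements the population-genomic analyses that exploit the
haploid genome of honeybee drones: a kinship-aware selection scan (FLK and
hapFLK) with spectral-decomposition assignment of the population under
selection, a copy-number screen built on heterozygous calls in haploids,
reconstruction of the mitochondrial tRNA-Leu/cox2 mitotype from sequencing
reads, and the supporting population statistics.  A seeded synthetic-data
generator emulates the statistical structure these methods assume, so the
whole pipeline is testable at desk scale.

## The drift model and the FLK statistic

Under pure drift with no migration, the allele frequency of population $i$
at a site with ancestral frequency $p_0$ has mean $p_0$ and covariance

$$\mathrm{Cov}(p_i, p_j) = p_0 (1 - p_0)\, F_{ij},$$

where $F$ is the co-ancestry (kinship) matrix: $F_{ii}$ is the drift
accumulated by population $i$ since the common ancestor, and $F_{ij}$ the
drift shared through common branches of the population tree.  FLK tests a
single site by estimating $\hat p_0$ by generalised least squares,
standardising the deviations
$\tilde p = (p - \hat p_0 \mathbf 1)/\sqrt{\hat p_0(1-\hat p_0)}$, and
forming the quadratic form $T = \tilde p^\top F^{-1} \tilde p$, which is
asymptotically $\chi^2$ with $n_\mathrm{pop} - 1$ degrees of freedom (one
degree absorbed by $\hat p_0$).

Writing $F = Q^\top D Q$ with orthogonal $Q$ (rows are eigenvectors) and
diagonal $D$, the statistic decomposes as $T = \sum_i u_i^2$ with
$u = D^{-1/2} Q \tilde p$.  Each $u_i$ is the contribution of eigenvector
$i$; because $Q_{ij}$ is the loading of population $j$ on eigenvector $i$,
large $|u_i|$ at a locus points to the populations that drive the signal.
The package asserts the eigen identity $|T - \sum u_i^2| \le 10^{-8}$
site-by-site.

When $F$ describes *drift* but the scan runs on *sample* frequencies, the
observed covariance gains a binomial term:
$\mathrm{Var}(\hat p_i) = p_0(1-p_0)\,(F_{ii} + (1-F_{ii})/n_i)$ for $n_i$
haploids.  `kinship_sample_correction()` applies this to the diagonal and
`hapflk_scan()` does so by default; scans on true population frequencies
(as in the null-calibration tests) use $F$ unmodified.

## hapFLK: the haplotype-cluster extension

Single-SNP differentiation has limited power against soft or recent
sweeps.  hapFLK replaces allele frequencies with *local haplotype-cluster
frequencies* from a fastPHASE-style hidden Markov model: each haplotype
follows a hidden path through $K$ clusters; between adjacent loci it stays
with probability $1-\rho_l$ or jumps to a cluster drawn from weights
$\alpha$; cluster $k$ emits the alternate allele at locus $l$ with
probability $\theta_{lk}$.  The model is fitted by EM with a scaled
forward–backward E-step (compiled code; the log-likelihood trace is
non-decreasing and tested).  At each locus, posterior cluster frequencies
are pooled per population, and hapFLK is the sum over clusters of the FLK
quadratic form applied to that cluster's frequency vector, averaged over
independent EM restarts.

Cluster frequencies do not follow the binomial drift covariance exactly,
so hapFLK p-values are never taken from the analytic $\chi^2$.  Instead a
scaled chi-squared $a\cdot\chi^2_d$ is fitted robustly to the genome-wide
distribution: $(a, d)$ solve the moment equations of the distribution
*truncated below the empirical 95th percentile*, so that swept regions in
the top tail cannot distort the null fit.  The truncated-moment equations
are solved numerically (Nelder–Mead on $\log a, \log d$); on i.i.d.
$\chi^2_4$ draws the fit recovers $(1, 4)$ within sampling error, which is
a test in the suite.

Significant positions ($p \le 10^{-4}$ by default) are chained when
within 2 kb of one another, regions are extended by 10 kb flanks, and
overlapping flank-extended regions are merged (merging prevents
double-counting one signal; the choice matters only at desk scale).

### Assigning the population under selection

For each region and eigenvector $i$, the measure of selection is the sum
of squared contributions $u_i^2$ over region SNPs that exceed the
genome-wide per-eigenvector 99th percentile, divided by the number of
SNPs in the region.  A region is assigned when the largest measure is at
least twice the second largest; the population is then the one with the
largest $|Q_{ij}|$ in the winning eigenvector, with ties reported as
ambiguous rather than silently resolved.  Squared contributions are used
(not signed ones) for consistency with $T = \sum u_i^2$, and the
percentile reference set is genome-wide, which keeps the threshold
independent of the region under test.

A geometric caveat documented here deliberately: the GLS residual of a
single-population frequency shift is a "that population versus the rest"
contrast.  The rule can only name the population if that contrast lies
close to an eigenvector of $F$.  This holds when one population is much
more drifted than the rest (the royal-jelly situation) and fails when two
populations are nearly exchangeable — a sweep in one of two similar
honey-production populations is detected but may not be assignable.  This
is a property of the method, not of the implementation.

## Synthetic cohorts: what they emulate and what they do not

`simulate_frequencies()` draws per-site ancestral frequencies
$p_0 \sim U(0.05, 0.95)$ and population vectors from the truncated
Gaussian $\mathcal N(p_0\mathbf 1,\; p_0(1-p_0)F)$, redrawing sites fixed
in every population.  A truncated Gaussian rather than Balding–Nichols
Beta is used on purpose: it matches the FLK model's own Gaussian
approximation, so null calibration is a fair test of the statistic rather
than of a distributional mismatch.  Truncation at the frequency
boundaries is the one deviation; the default kinship keeps it rare, and
the covariance moment test therefore checks mid-range ancestral
frequencies where clamping is negligible.

The default kinship (`default_kinship()`) describes three C-lineage-derived
populations: two exchangeable, mildly drifted honey-production populations
(self-kinship 0.03, correlation 0.3) and a royal-jelly population with
five-fold stronger drift (0.15, correlation 0.15 to the others), the
signature of a recent closed-population bottleneck.  These magnitudes are
in the range implied by the reported differentiation among C-derived
managed populations, keep Gaussian truncation rare, and give $F$ an
eigenvector aligned with the RJ-versus-rest contrast so the spectral
assignment rule is identifiable.

`simulate_haplotypes()` builds haplotypes from per-population founder
pools within LD blocks (block boundaries act as recombination points).
The founder-pool size controls bottleneck structure: the default of 60
founders per block (about twice the default sample size) emulates
populations whose haplotype diversity is not bottlenecked, so neutral
cross-population differentiation stays consistent with the drift model.
Small pools (say 8) create population-private haplotypes in every block —
a haplotype-level differentiation far beyond $F$ — which swamps the
empirical null of hapFLK; that regime is available through the parameter
but is not the default.  Depth is Poisson with a per-site Gamma
mappability factor shared across drones, so site-level depth is
correlated between individuals as in real data.

What the generator does *not* emulate: genealogical coalescent structure,
recombination hotspots, sequencing-error models beyond uniform per-base
error, mapping artefacts, and real linkage maps.  Passing tests therefore
demonstrate correctness of the statistics under their own model
assumptions and robust behaviour at realistic noise levels — not
performance guarantees on real resequencing data.

Sweeps are injected by copying one resident haplotype over random drones
of the target population until its frequency reaches the requested value;
collapsed duplications by drawing paralogous-variant positions once
(shared by all carriers, as for a real segregating duplication), setting
them heterozygous in carriers and multiplying carrier depth across the
segment.

## The hetSNP copy-number screen

A heterozygous call in a haploid drone is biologically impossible at a
unique locus; clustered het calls with inflated depth flag collapsed
duplications.  The screen applies, in order: sites on chromosomes 1–16
with per-genotype depth $\ge 9$ in *every* individual; per drone, removal
of het calls more than 2 kb from their nearest het neighbour; maximal
runs with inter-het gaps $\le 2$ kb kept when they contain $\ge 3$
hetSNPs, span $\ge 2$ kb and have mean depth $\ge 3\times$ the drone's
genome-wide average (computed before the site filter — the genome-wide
mean is the natural baseline for the inflation test).  Per-drone clusters
overlapping by $\ge 1$ bp are unioned into intervals with per-population
carrier counts; carrier-frequency bias between two populations is tested
by the 2×2 Pearson chi-squared without continuity correction, with raw
(uncorrected) p-values, matching how such screens are reported.

Two desk-scale notes.  First, a cluster necessarily spans from its first
to its last hetSNP, strictly inside the true duplicated segment, so
"recovery" in the tests means an emitted interval overlapping the true
segment — covering it exactly is unattainable by construction.  Second,
with depth inflation exactly $3\times$ and the threshold also $3\times$,
a single carrier passes the depth rule only about half the time
(fluctuations of the site-level mappability mean); detection relies on
several carriers sharing the duplication, which is also how the filters
behave on real cohorts.  The default simulated cohort (two populations
of 10 drones at 15X, 10 kb segment, carrier fraction 0.5, paralogous
variant probability 0.2 per callable site — about two variants per kb
between collapsed copies) keeps the screen comfortably powered while a
null cohort yields no intervals.

## Mitotype reconstruction

The tRNA-Leu/cox2 intergenic region carries the classical mitotype
signal: presence/absence of the P element, tandem copy number of the Q
element and point variants.  References are trimmed to the region between
the anchor motifs `CTTTTATTAAA` (3' end of tRNA-Leu) and `ATTTCCACA`
(5' end of cox2), each required exactly once — trimming an already
trimmed sequence errors rather than silently double-trimming.

Reads overlapping the region by $\ge 1$ bp are scored against every panel
entry by deterministic local gapped alignment (match $+1$, mismatch $-2$,
gap open $-4$, gap extend $-1$; no heuristic tie-breaking).  Alignments
with score at least half the read length count as high-quality (HQ); per
reference, the error rate $e$ is the HQ mismatch rate plus the HQ
indel-event rate (events per aligned base, recorded to 6 decimals), and
the alignment quality $q$ is the fraction of all aligned bases that are
HQ-aligned with base quality $\ge 20$.  A reference is acceptable when
$e > 0$ and $q > 0.5$; the best match minimises $e$, with ties broken by
reference length and then lexicographic accession (flagged ambiguous).
The $e > 0$ rule exists to reject a short reference that aligns perfectly
while a longer one explains more of the data; its corollary — error-free
reads reject even the true reference — is implemented as stated, and the
read simulator's default error rate (0.5%) is non-zero accordingly.

The consensus is a majority-vote pileup against the chosen reference:
covered positions take the majority base (ties keep the reference base
when it is among the tied candidates), uncovered positions keep the
reference, indels are not applied, so the output has exactly the
reference length.  Mitotype identity is carried by the selected panel
entry; indel calling would add failure modes without changing it.

For haplotype networks, `recode_for_network()` recodes C→G and then
gap→C, in that order, collapsing the alphabet to three letters so that
indel-rich diagnostic columns (the P element, missing Q copies) survive
the $>5\%$ missing-data masking of network software;
`segregating_sites()` reproduces that masking rule.

## Numerical choices and tunable parameters

* FLK: $\hat p_0$ clipped to $[10^{-6}, 1-10^{-6}]$; a clipped site
  (monomorphic across populations) is flagged and contributes $T = 0$.
  Missing genotypes are dropped per site from frequency estimation.
* Cluster model: $K = 10$ clusters and 20 independent EM restarts by
  default, matching the published configuration (the published "20 EM
  iterations" is read as the fit count of the underlying software, with
  each fit run to convergence).  Convergence is declared when the change
  in mean log-likelihood per haplotype–locus drops below `em_tol`
  ($10^{-5}$) or after `max_iter` (200) iterations; an absolute
  tolerance on the total log-likelihood would never trigger at these
  problem sizes.  $\theta$ is clamped to $[10^{-6}, 1-10^{-6}]$ for
  numerical safety.  Replicate-heavy tests run `max_iter = 20`, the
  published iteration budget, which converges to the same detections.
* Region calling: `alpha` $10^{-4}$, `chain_bp` 2000, `flank_bp` 10000.
* hetSNP screen: `dp_min` 9, `max_gap` 2000, `min_n` 3, `min_span` 2000,
  `dp_factor` 3, `carrier_threshold` 15 (mirroring a 60-drone design;
  scale for other cohorts).
* Depth curve: the saturating exponential $GX = a(1 - e^{-DP/b})$ is this
  package's choice of regression family (the source regression form is
  unspecified); the closed-form inversion is
  $DP = -b\log(1 - GX/a)$, defined only below the asymptote $a$.
* Mitotype scoring: the HQ score threshold (half the read length) and
  the per-aligned-base indel rate are conventions exposed as
  configuration; selection only requires scores comparable across panel
  entries under one convention.

## Problem sizes used by the test suite

Tests run at desk scale, chosen so the full suite completes in minutes on
one CPU while every statistical property is exercised at meaningful
power: null calibration on 20,000 sites; sweep recovery on 20 replicates
of three populations × 30 drones × 5,000 sites (K = 10, 5 EM fits);
the CNV screen on 20 duplication and 20 null cohorts of 2 × 10 drones ×
3,000 sites; mitotype reconstruction on 40 replicates of truth + 10
decoys at 20× coverage.

## Known limitations

* The spectral assignment rule cannot separate nearly exchangeable
  populations (see above); it reports `NA`/ambiguous rather than guessing.
* hapFLK p-values inherit the quality of the empirical chi-squared fit;
  with fewer than ~1000 loci the calibration is unstable and a warning is
  raised.
* The windowed diversity estimator divides by window length in bp, the
  convention of standard VCF tooling; with sparse sites this understates
  per-accessible-base diversity.
* Genotype imputation is out of scope; the call-rate filter plus
  major-allele imputation (for the cluster model only) stand in.
* The mitotype module consumes positioned reads (FASTQ plus coordinates);
  BAM/CRAM extraction is left to standard tools upstream.
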