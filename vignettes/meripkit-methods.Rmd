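---
title: "meripkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meripkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

meripkit implements a transcript-coordinate analysis stack for m6A
profiling experiments: MeRIP-seq peak calling, metagene and motif
summaries, actinomycin-D mRNA half-life estimation with ERCC spike-in
calibration, and ribosome-profiling translation efficiency, together
with a synthetic-data generator that plants known peaks, half-lives and
TE shifts so every stage can be validated against ground truth. This
vignette explains the statistical models, the tunable parameters and
the choices made where the design was genuinely open.

## The coordinate frame

All windowing happens in transcript coordinates. For each gene the
longest annotated isoform is selected (`select_longest_isoform()`; ties
break on the lexicographically smaller transcript id so the choice is
deterministic), and aligned reads are extended to the library's average
fragment size — 150 bp by default, matching a 100–200 bp fragmentation
protocol — from their 5' end in the read's 3' direction
(`extend_fragment()`). The extended fragment is intersected with the
exon chain and projected to isoform coordinates
(`project_to_transcript()`), which removes intronic interference from
peak calling. Coordinates are 0-based half-open internally; GTF input
(1-based closed) is converted on read and BED is emitted natively,
which keeps all interval arithmetic BED-compatible.

Extension happens in genomic space and is projected afterwards. The
alternative — extending in transcript space — differs only for the
minority of fragments that straddle an exon boundary, and at 100-nt
window resolution the difference is well below one window step.

Each projected fragment contributes a single **midpoint**
(`fragment_midpoint()`, the floor-midpoint of the projected span).
Counting midpoints rather than any-overlap prevents one fragment from
inflating the ~15 windows it touches; a fragment whose genomic midpoint
is intronic is carried by the nearest exonic base automatically,
because the midpoint is taken on the projected (intron-free) span.
Fragments with no exonic overlap are dropped.

## The peak caller

Every transcript is scanned with 100-nt windows advanced in 10-nt steps
(`make_windows()`); a transcript shorter than one window gets a single
full-length window. Per replicate:

1. **Low-count filter.** Windows below 1/20 of the transcript's top
   window in *both* the IP and the input sample are excluded
   (`filter_low_windows()`). This guards against annotation errors and
   the arbitrariness of the longest-isoform convention. "Both" is read
   as a conjunction: a window at or above threshold in either sample
   survives. A transcript with all-zero counts loses all windows.
2. **Gene-median normalization.** Window counts are normalized by the
   median count over the transcript's surviving windows — `b` for IP
   and `d` for input (`gene_median_offsets()`). The median of an
   even-length list is its lower-middle element (keeps offsets
   integral); zero medians become 1 so enrichment stays finite.
3. **Enrichment score.** `(a * d) / (b * c)` with `a`/`c` the IP/input
   window counts (`enrichment_score()`). The printed form
   "(a) × (d)/(b) × (c)" is parenthesized this way because it is the
   IP window-to-median ratio divided by the input window-to-median
   ratio. Zero `a` or `c` get a +1 pseudocount.
4. **Window test.** An exact conditional test (`nb_window_test()`):
   given the window total `n = a + c`, under the null the IP count is
   `Binomial(n, pi0)` with `pi0 = b/(b + d)` for dispersion 0, and
   Beta-Binomial with mean `pi0` and intra-class correlation
   `rho = phi/(1 + phi)` for dispersion `phi > 0`. Normalization enters
   through the offsets rather than by rescaling counts, preserving the
   count distributions. The two-sided p-value is the minimum-likelihood
   sum (total probability of outcomes no likelier than the observed
   one). With a single IP and input library per replicate there is no
   within-group replication to estimate a dispersion from, so `phi` is
   a moment estimate across the two IP replicates
   (`estimate_dispersion()`): per-window
   `max(0, (var − mean)/mean²)` on depth-normalized counts, median over
   windows with mean ≥ 5, floored at 0.01 (default 0.05 with fewer
   than two replicates). The conditional test is exact, dependency-free
   and testable against enumeration; at `phi = 0` it reduces to the
   exact binomial test, which the test suite verifies to 1e-9 for all
   totals up to 50.
5. **FDR and intersection.** Benjamini–Hochberg adjustment is applied
   transcriptome-wide per replicate across all tested windows (the
   per-transcript alternative would leave too few tests for the
   step-up procedure to be meaningful). A window is positive when
   `q < 1%` and `log2(enrichment) ≥ 1` in *every* replicate.
6. **Merging.** Overlapping positive windows (sharing ≥ 1 base;
   half-open touching does not count) merge into peaks; the enrichment
   of the merged span is recomputed from `a, b, c, d` over the whole
   span per replicate, and the reported summary score is their
   geometric mean. Peaks are projected back to genomic blocks and can
   be written as BED12 (`write_peaks_bed12()`, score
   `100 × min(summary, 10)`).

Numerical details worth knowing: pmf ties in the minimum-likelihood sum
are compared with a 1e-9 relative tolerance (exact symmetric nulls
produce mathematically tied outcomes whose floating-point images differ
at the last ulp; without the tolerance a p-value could lose a whole pmf
term to rounding); `n = 0` windows give p = 1; only windows with
enrichment above 1 can become positive anyway because of the log2
threshold.

Replicate QC follows the published practice of correlating replicate
window vectors: Pearson on `log2(count + 1)`
(`replicate_correlation()`), expecting values above 0.85 for usable
replicates.

## Metagene and motif summaries

`region_of()` segments a transcript position into 5'UTR/CDS/3'UTR with
half-open boundaries. `metagene_bin()` maps a position to one of 100
bins — 10 for the 5'UTR, 50 for the CDS, 40 for the 3'UTR — by relative
position within its region; `metagene_profile()` bins each peak once,
at its midpoint (the procedure does not distinguish summit from span,
and the midpoint is the natural single-point reduction), skipping and
tallying peaks on transcripts without an annotated CDS. Motif
occurrence scanning (`scan_motif()`) matches IUPAC patterns — `GGACU`
or the m6A consensus `DRACH` — with U and T treated identically and all
overlapping matches reported. Motif *enrichment* statistics are out of
scope; only occurrence scanning is provided.

## mRNA decay kinetics

Each timepoint sample of a 0/3/6 h actinomycin-D chase is calibrated
against its ERCC spike-ins by least squares of `log2(amount)` on
`log2(count)` over species with nonzero counts (`ercc_calibrate()`);
the slope is fitted rather than fixed at 1 so saturation or library
effects do not bias the mapping, and `r2` is reported as QC. Counts
convert to attomole via `to_abundance()`; a count of zero maps to the
calibration's floor `2^intercept`. Zeros are excluded from the fit
rather than pseudocounted: a +1 pseudocount inside the log bends the
low-abundance end of the line and visibly biases recovered half-lives
even in noise-free data, whereas dropping empty spike-ins leaves the
noise-free calibration exact (the test suite checks recovery to
machine precision, and depth rescaling of any sample cancels exactly).
The absolute unit is only meaningful within one calibrated sample set.

Decay rates come from `log2(At/A0) = −kt`: `k_3h` (3 h vs 0 h) and
`k_6h` (6 h vs 0 h), and the half-life uses their average,
`t_1/2 = 2/(k_3h + k_6h) = 1/mean(k)`. A non-positive rate sum —
an apparently stabilized or increasing transcript — yields a flagged
`NA`, never a capped number. `At = 0` is floored at the smallest
positive abundance observed in that sample.

## Translation efficiency

`rpkm()` implements reads per kilobase per million mapped reads.
TE is RPF density over mRNA-input density (`translation_efficiency()`),
computed on RPKM so depth differences between the paired libraries
cancel exactly; genes with input density below 1 RPKM are flagged
rather than producing unstable ratios. Densities use CDS length
(ribosome footprints derive from the coding region); the length column
is caller-supplied, so full-transcript density is available by passing
a different length. `te_contrast()` reports per-gene signed log2 TE
ratios between conditions per replicate, omitting and tallying flagged
genes. Because RPKM normalizes within each library, TE is a *relative*
quantity: a strong composition change in one library shifts all
contrasts by a shared constant, which is why condition-level summaries
here use across-gene medians.

## Supporting count statistics

The differential-expression filter (`de_filter()`) is the simple
published rule — at least 1.5-fold change and p below 0.01, evaluated
on pseudocounted normalized expression in both directions — with BH
q-values attached. P-values for two digital counts come from the
Audic–Claverie conditional test (`audic_claverie_p()`):
`P(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`, which is
exactly a negative binomial with size `x + 1` and success probability
`N1/(N1+N2)`; the implementation evaluates it in log space and sums the
minimum-likelihood tail, truncating below 1e-12 tail mass. Note that
this test conditions on `x`, so `p(x, y)` and `p(y, x)` are *not*
interchangeable even at equal library sizes — only the kernel
`P(y|x) = P(x|y)` is symmetric. `ddct()` provides the `2^-ddCt`
relative-expression utility.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_transcriptome()` and friends)
emits every input the pipeline consumes — GTF, FASTA, BED6 reads,
count TSVs with `ERCC-` rows, truth JSON — with the statistical
structure the analyses assume. Its defaults are the study conditions
used throughout the tests:

* 300 genes, single isoform (plus shorter decoy isoforms on 10% of
  genes, present only in the GTF, to exercise the longest-isoform
  rule), lengths log-normal with median 1500 nt (sdlog 0.35, floor
  400 nt), regions split 10/50/40%, 30% of genes with one intron,
  spread over 5 chromosomes.
* Expression shares log-normal (sdlog 1); per-gene library totals NB
  with dispersion 0.05 (biological-replicate scale); 1e6 fragments per
  library, two replicates; fragment lengths jittered uniformly over
  100–200 bp to mimic the fragmentation step, reads 50 bp.
* 20 peak genes with one GGACT (DRACH) site planted near the stop
  codon (uniform offset in [−100, +40] nt around the CDS end, which
  puts peak midpoints in metagene bins ~53–62 and mirrors the
  stop-codon enrichment seen in real metagene profiles). IP libraries
  mix the uniform background with a triangular kernel (half-width =
  half the fragment size) centred on the site, weighted so a 100-nt
  window on the site is 8-fold enriched over the gene background.
  The triangular shape is a simple bounded-support stand-in for the
  roughly tent-shaped coverage that fragment-midpoint counting induces
  around a point source.
* Decay: half-lives log-normal, median 4 h (sdlog 0.5), clipped to
  [0.5, 24] h; a 92-species 2-fold spike-in ladder carrying 5% of the
  0 h mass; per-sample depth factors; NB noise at dispersion 0.002.
  The chase samples are aliquots of a single culture harvested at
  three times, so their variability is near-technical, far below the
  between-animal dispersion of the MeRIP totals; 0.002 sits at the
  upper end of the technical range rather than the biological one.
* Ribo: baseline TE log-normal (sdlog 0.3); 10 genes with a planted
  2-fold TE reduction in the knockout only, mirroring a small targeted
  set of translationally affected transcripts, plus one designated
  negative-control housekeeping gene with ratio exactly 1. Each
  (condition, replicate) draws one animal-level abundance vector
  (gamma, dispersion 0.05) shared by its RPF and input library — the
  paired design means biological variation cancels in the TE ratio —
  with library-level NB noise at dispersion 0.002 on top.

One master seed drives deterministic sub-streams per library, so
replicates are exchangeable and every emitted file is byte-identical
across runs with the same seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequence errors and quality strings, mapping
ambiguity, multi-isoform genes with expressed minor isoforms,
transcript-end coverage bias, GC effects, batch structure, or
antibody-specificity artifacts in the IP. The planted-peak recovery
numbers characterize the procedure under its own assumptions, not its
field performance.

## Problem sizes used in validation

The validation suite runs the default MeRIP conditions (300
transcripts, 2 × 2 libraries of 1e6 fragments) once and shares the
result across checks; null calibration uses 20 independent seeds of a
peak-free preset at 100 transcripts and 2e5 fragments per library —
the calibration of an exact conditional test does not depend on depth,
so the smaller preset measures the same property; decay recovery uses
200 genes; coordinate invariants use 1000 randomized toy models. The
binomial-limit check enumerates all window totals up to 50.

## Known limitations

* Peak calling reports presence/absence per condition; differential
  methylation between conditions is by set overlap only, with no
  statistical test, and peaks are not isoform-resolved.
* The dispersion fed to the window test is a single common value; a
  per-window empirical-Bayes treatment would be strictly better with
  more replicates.
* ERCC calibration makes abundances unit-consistent within a sample
  set only; "attomole" is not comparable across experiments without a
  shared spike-in protocol.
* The DE filter deliberately implements the simple fold-change +
  p-value rule rather than a dispersion-aware model; with biological
  replicates a shrinkage-based test is preferable.
* The SAM reader is minimal (no CIGAR interpretation); spliced
  alignments should be supplied as BED of read positions instead.
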