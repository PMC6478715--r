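# meripkit

Transcript-coordinate analysis of m6A (N6-methyladenosine) profiling
experiments in R: MeRIP-seq peak calling, metagene and DRACH motif
summaries, actinomycin-D mRNA half-life estimation with ERCC spike-in
calibration, ribosome-profiling translation efficiency, and supporting
count statistics — plus a synthetic-data generator with planted ground
truth that exercises every stage end to end.

It is written for computational biologists analysing MeRIP-seq (m6A-seq)
experiments with matched IP/input libraries, optionally alongside decay
time courses and ribosome profiling, who want a self-contained,
testable implementation of the classic sliding-window peak-calling
procedure rather than a black box.

## The methods in brief

**Peak calling.** Reads are analysed on the longest isoform of each
gene: alignments are extended to the 150-bp average fragment size and
projected from genome to transcript coordinates, removing introns. Each
transcript is scanned with 100-nt windows in 10-nt steps; windows below
1/20 of the transcript's top window in both IP and input are excluded,
and counts are normalized by the gene-median window counts *b* (IP) and
*d* (input). The enrichment score of a window with IP count *a* and
input count *c* is

    ES = (a * d) / (b * c)

and each window is tested with an exact conditional test: given
n = a + c, the null IP count is Binomial(n, b/(b+d)) — Beta-Binomial
with the same mean when a dispersion phi estimated across the IP
replicates is positive — with a two-sided minimum-likelihood p-value.
Windows with BH FDR < 1% and log2(ES) >= 1 in **both** replicates are
positive; overlapping positive windows merge into peaks whose scores
are recomputed over the merged span.

**Half-lives.** Counts from a 0/3/6 h actinomycin-D chase are calibrated
per sample against ERCC spike-ins (log2 amount ~ log2 count), decay
rates come from log2(At/A0) = -k t for t = 3 and 6 h, and

    t1/2 = 2 / (k3h + k6h)

i.e. the half-life implied by the average rate. Apparently stabilized
genes are flagged, not capped.

**Translation efficiency.** TE = RPF RPKM / input RPKM per gene (CDS
length by default), with low-expression flagging and per-replicate
log2 TE contrasts between conditions.

**Count statistics.** Audic–Claverie p-values for pairs of digital
counts, the >= 1.5-fold & P < 0.01 differential-expression filter with
BH q-values, and the 2^-ddCt qPCR utility.

## Worked example

Simulate the default synthetic study (300 genes, 20 planted 8x peaks at
DRACH sites near stop codons, two replicates of 1e6 fragments per
library), call peaks, and run the downstream modules:

```r
library(meripkit)

cfg   <- sim_config(seed = 42)
sim   <- simulate_transcriptome(cfg)
merip <- simulate_merip(sim)

to_al <- function(bed) data.table::data.table(
  chrom = bed$chrom, strand = bed$strand,
  five_prime_pos = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
  read_len = bed$end - bed$start)

pk <- call_peaks(sim$models, lapply(merip$ip, to_al),
                 lapply(merip$input, to_al))
pk$correlations$ip        # 0.953  — replicate QC (log2 window counts)
pk$dispersion             # 0.0142 — moment estimate across IP replicates
sum(pk$windows$positive)  # 277 positive windows
nrow(pk$peaks)            # 20 peaks
pk$peaks[1:3, .(gene_id, chrom, strand, t_start, t_end, n_windows,
                summary_score)]
#    gene_id  chrom strand t_start t_end n_windows summary_score
# 1:   g0101   chr1      +     490   690        11      3.879755
# 2:   g0211   chr1      +    1140  1370        14      4.062290
# 3:   g0231   chr1      -    1040  1270        14      4.075041
```

All 20 planted peaks are recovered with no false peaks; the metagene
profile of the called peaks peaks at bin 57 of 100 (the CDS ends at
bin 59), reproducing the stop-codon enrichment the procedure is known
for. The peak table carries per-replicate enrichment scores and the
geometric-mean summary; `summary_score` ~ 4 for a merged span is
typical of a planted 8x site once the flanking background is averaged
in.

```r
dk  <- simulate_decay(sim)
fit <- lifetime_pipeline(dk$counts, dk$ercc_amounts)
fit[1:3, .(gene_id, A0 = round(A0, 1), k3h, k6h, t_half)]
#    gene_id    A0   k3h   k6h t_half
# 1:   g0001 156.5 0.153 0.215   5.44
# 2:   g0002 238.8 0.336 0.254   3.39
# 3:   g0003  59.4 0.076 0.094  11.76
```

`A0` is the spike-calibrated abundance (attomole) at 0 h and `t_half`
is in hours; against the generator's truth the median relative
half-life error here is 8%.

```r
rb    <- simulate_ribo(sim)
te_wt <- compute_te(rb$wt[[1]]$rpf, rb$wt[[1]]$input, condition = "wt")
te_ko <- compute_te(rb$ko[[1]]$rpf, rb$ko[[1]]$input, condition = "ko")
ct    <- te_contrast(te_ko, te_wt)
```

The ten genes with a planted 2-fold KO translation-efficiency drop show
a median log2 contrast of -1.1 in this replicate; the null genes'
median is 0.005.

## Command line

A thin CLI over the same functions lives at
`inst/scripts/meripkit-cli.R`:

```sh
Rscript inst/scripts/meripkit-cli.R demo --seed 7 --out demo_out
Rscript inst/scripts/meripkit-cli.R callpeaks --gtf annotation.gtf \
  --ip1 ip_rep1.bed --input1 input_rep1.bed \
  --ip2 ip_rep2.bed --input2 input_rep2.bed --out peaks
```

Subcommands: `simulate`, `callpeaks`, `metagene`, `motif`, `lifetime`,
`te`, `diffexp`, `demo`. Exit status 2 flags a missing input, 3 an
invalid configuration.

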