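# Shared fixtures and independent oracles. Expensive simulations are
# memoised so several test files can share one default-scale run.

.fixtures <- new.env(parent = emptyenv())

# default-condition MeRIP dataset + full peak call (shared)
default_merip_run <- function(seed = 7L) {
  key <- paste0("merip_", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- simulate_transcriptome(sim_config(seed = seed))
    merip <- simulate_merip(sim)
    pk <- call_peaks(sim$models,
                     lapply(merip$ip, bed_to_alignments),
                     lapply(merip$input, bed_to_alignments))
    .fixtures[[key]] <- list(sim = sim, merip = merip, peaks = pk)
  }
  .fixtures[[key]]
}

bed_to_alignments <- function(bed) {
  data.table::data.table(
    chrom = bed$chrom,
    strand = bed$strand,
    five_prime_pos = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
    read_len = bed$end - bed$start)
}

# planted-site recovery given called peaks; a planted peak is the region
# site +/- half a fragment
peak_recovery <- function(peaks, truth, pad = 75L) {
  planted <- truth[truth$is_peak, ]
  hits <- 0L
  for (i in seq_len(nrow(planted))) {
    p <- peaks[peaks$gene_id == planted$gene_id[i], ]
    if (nrow(p) && any(p$t_start - pad <= planted$peak_pos[i] &
                         planted$peak_pos[i] < p$t_end + pad))
      hits <- hits + 1L
  }
  fp <- 0L
  for (j in seq_len(nrow(peaks))) {
    site <- truth$peak_pos[truth$gene_id == peaks$gene_id[j]]
    ok <- length(site) == 1L && !is.na(site) &&
      peaks$t_start[j] - pad <= site && site < peaks$t_end[j] + pad
    if (!ok) fp <- fp + 1L
  }
  list(sensitivity = if (nrow(planted)) hits / nrow(planted) else NA_real_,
       fp_fraction = if (nrow(peaks)) fp / nrow(peaks) else 0)
}

# independent two-sided binomial oracle (minimum-likelihood sum over the
# exact pmf, same tie tolerance as the contract)
binom_minlik_p <- function(a, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[a + 1L] * (1 + 1e-9)])
}

# independent Audic-Claverie oracle: explicit log-gamma formula
ac_oracle_p <- function(x, y, N1, N2, ymax = 1000L) {
  yy <- 0:ymax
  lp <- yy * log(N2 / N1) + lgamma(x + yy + 1) - lgamma(x + 1) -
    lgamma(yy + 1) - (x + yy + 1) * log1p(N2 / N1)
  sum(exp(lp[lp <= lp[y + 1L] + 1e-9]))
}

# regex oracle for IUPAC scanning (overlapping matches via lookahead)
regex_motif_hits <- function(seq, pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[GC]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  pat <- paste0(map[strsplit(toupper(chartr("uU", "tT", pattern)),
                             "")[[1L]]], collapse = "")
  s <- toupper(chartr("uU", "tT", seq))
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# random small transcript model (1-4 exons, either strand)
random_toy_model <- function(i) {
  n_ex <- sample(1:4, 1L)
  widths <- sample(10:80, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1L) sample(5:200, n_ex - 1L, replace = TRUE) else integer(0)
  starts <- cumsum(c(sample(0:50, 1L), head(widths, -1L) + gaps))
  ends <- starts + widths
  len <- sum(widths)
  u5 <- sample.int(max(len %/% 4L, 1L), 1L)
  cds <- sample.int(max(len - u5 - 1L, 1L), 1L)
  transcript_model(paste0("g", i), paste0("t", i), "chrT",
                   sample(c("+", "-"), 1L), starts, ends,
                   utr5_len = u5, cds_len = cds)
}
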