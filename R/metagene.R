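# Metagene summaries over the 5'UTR/CDS/3'UTR model and IUPAC motif
# scanning within transcripts.

#' Transcript region of a position
#'
#' @param pos integer vector of transcript positions.
#' @param model a [transcript_model()].
#' @return Character vector: `"UTR5"`, `"CDS"` or `"UTR3"`.
#' @export
region_of <- function(pos, model) {
  if (any(pos < 0L | pos >= model$length))
    stop("position out of transcript range")
  ifelse(pos < model$utr5_len, "UTR5",
         ifelse(pos < model$utr5_len + model$cds_len, "CDS", "UTR3"))
}

#' Metagene bin of a transcript position
#'
#' The 5'UTR, CDS and 3'UTR are binned into `bins` segments (default
#' 10/50/40) according to their relative lengths; the bin index is the
#' region offset plus `floor(r * bins_of_region)` where `r` is the
#' relative position within the region.
#'
#' @param pos integer vector of transcript positions.
#' @param model a [transcript_model()].
#' @param bins integer triple of segment counts per region.
#' @return Integer bin indices in `[0, sum(bins))`.
#' @export
metagene_bin <- function(pos, model, bins = c(10L, 50L, 40L)) {
  stopifnot(length(bins) == 3L, all(bins > 0L))
  region <- region_of(pos, model)
  rlen <- c(UTR5 = model$utr5_len, CDS = model$cds_len,
            UTR3 = model$utr3_len)
  if (any(rlen[region] == 0L))
    stop("position in a zero-length region")
  roff <- c(UTR5 = 0L, CDS = model$utr5_len,
            UTR3 = model$utr5_len + model$cds_len)
  boff <- c(UTR5 = 0L, CDS = bins[1L], UTR3 = bins[1L] + bins[2L])
  r <- (pos - roff[region]) / rlen[region]
  as.integer(boff[region] + floor(r * bins[c(UTR5 = 1L, CDS = 2L,
                                             UTR3 = 3L)[region]]))
}

#' Metagene profile of a peak set
#'
#' Histogram of peak midpoints over the binned transcript model,
#' normalized to fractions. Peaks on transcripts without an annotated CDS
#' (or with an empty UTR at the midpoint's bin) are skipped and tallied.
#'
#' @param peaks `data.table` with `gene_id`, `t_start`, `t_end`.
#' @param models named list of [transcript_model()] keyed by gene id.
#' @param bins segment counts per region (default 10/50/40).
#' @return List with `bin_fractions` (length `sum(bins)`), `n_peaks`
#'   (peaks used) and `n_skipped`.
#' @export
metagene_profile <- function(peaks, models, bins = c(10L, 50L, 40L)) {
  nb <- sum(bins)
  counts <- integer(nb)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    m <- models[[peaks$gene_id[i]]]
    if (is.null(m) || m$cds_len == 0L) { skipped <- skipped + 1L; next }
    mid <- fragment_midpoint(peaks$t_start[i], peaks$t_end[i])
    reg <- region_of(mid, m)
    rlen <- c(UTR5 = m$utr5_len, CDS = m$cds_len, UTR3 = m$utr3_len)
    if (rlen[reg] == 0L) { skipped <- skipped + 1L; next }
    b <- metagene_bin(mid, m, bins)
    counts[b + 1L] <- counts[b + 1L] + 1L
    used <- used + 1L
  }
  frac <- if (used > 0L) counts / used else numeric(nb)
  list(bin_fractions = frac, n_peaks = used, n_skipped = skipped)
}

#' Write a metagene profile as TSV
#'
#' @param profile output of [metagene_profile()].
#' @param path output file.
#' @param bins segment counts per region used to label bins.
#' @return `path`, invisibly.
#' @export
write_metagene_tsv <- function(profile, path, bins = c(10L, 50L, 40L)) {
  region <- rep(c("UTR5", "CDS", "UTR3"), bins)
  data.table::fwrite(data.table::data.table(
    bin = seq_along(profile$bin_fractions) - 1L,
    region = region,
    fraction = profile$bin_fractions), path, sep = "\t")
  invisible(path)
}

#' Scan a sequence for an IUPAC motif
#'
#' All (possibly overlapping) occurrences of an IUPAC pattern such as
#' `GGACU` or the m6A consensus `DRACH` (D = A/G/U, R = A/G, H = A/C/U).
#' U and T are treated identically in both sequence and pattern.
#'
#' @param seq character sequence over A/C/G/T/U/N.
#' @param pattern IUPAC pattern (default `"GGACU"`).
#' @return `data.table` with `pos` (0-based match start) and `matched`
#'   (the matching subsequence as given, in DNA alphabet).
#' @export
scan_motif <- function(seq, pattern = "GGACU") {
  seq_dna <- chartr("uU", "tT", seq)
  pat_dna <- toupper(chartr("uU", "tT", pattern))
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  pat_chars <- strsplit(pat_dna, "")[[1L]]
  if (length(pat_chars) == 0L || !all(pat_chars %in% valid))
    stop("invalid IUPAC code in pattern: ", pattern)
  if (!all(strsplit(toupper(seq_dna), "")[[1L]] %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over A/C/G/U/T/N")
  subject <- Biostrings::DNAString(seq_dna)
  hits <- Biostrings::matchPattern(pat_dna, subject, fixed = FALSE)
  data.table::data.table(
    pos = BiocGenerics::start(hits) - 1L,
    matched = as.character(hits))
}

#' Scan many transcripts for a motif
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet` of
#'   transcript sequences.
#' @param pattern IUPAC pattern.
#' @return `data.table` with `transcript_id`, `pos`, `matched`.
#' @export
scan_motif_set <- function(seqs, pattern = "GGACU") {
  if (inherits(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  res <- lapply(names(seqs), function(id) {
    h <- scan_motif(seqs[[id]], pattern)
    if (nrow(h)) h$transcript_id <- id
    h
  })
  out <- data.table::rbindlist(res, fill = TRUE)
  if (nrow(out))
    data.table::setcolorder(out, c("transcript_id", "pos", "matched"))
  out
}
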