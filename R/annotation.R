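# Transcript models and genome <-> transcript coordinate projection.
#
# All coordinates are 0-based half-open internally. GTF input (1-based,
# closed) is converted on read; BED is emitted natively.

#' Construct a transcript model
#'
#' A transcript model is the coordinate frame used by the whole pipeline:
#' the exon chain of one isoform together with the 5'UTR/CDS/3'UTR
#' segmentation of its spliced length. Transcript position 0 is the 5' end
#' of the mature transcript, which for minus-strand models corresponds to
#' the exon base with the largest genomic coordinate.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of exon boundaries
#'   (0-based half-open genomic coordinates); exons must not overlap.
#' @param utr5_len,cds_len lengths in nt of the 5'UTR and CDS on the
#'   spliced transcript; the 3'UTR is the remainder. Both default to 0
#'   (non-coding model).
#' @return An object of class `transcript_model` with fields `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`,
#'   `utr5_len`, `cds_len`, `utr3_len` and `length`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exon_starts, exon_ends,
                             utr5_len = 0L, cds_len = 0L) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L,
            strand %in% c("+", "-"))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_starts < 0L) || any(exon_starts >= exon_ends))
    stop("invalid exon coordinates")
  n <- length(exon_starts)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n]))
    stop("exons overlap")
  widths <- exon_ends - exon_starts
  len <- sum(widths)
  utr5_len <- as.integer(utr5_len)
  cds_len <- as.integer(cds_len)
  utr3_len <- len - utr5_len - cds_len
  if (utr5_len < 0L || cds_len < 0L || utr3_len < 0L)
    stop("region lengths inconsistent with transcript length")
  # transcript-coordinate offset of each exon, in genomic exon order
  if (strand == "+") {
    offsets <- c(0L, cumsum(widths))[seq_len(n)]
  } else {
    offsets <- rev(c(0L, cumsum(rev(widths)))[seq_len(n)])
  }
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id,
    chrom = chrom, strand = strand,
    exon_starts = exon_starts, exon_ends = exon_ends,
    exon_offsets = offsets,
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    length = len
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), %d nt [%d/%d/%d]>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exon_starts), x$length,
              x$utr5_len, x$cds_len, x$utr3_len))
  invisible(x)
}

#' Project genomic positions onto a transcript
#'
#' Vectorised point projection. Positions falling in an intron or outside
#' the exon chain map to `NA`.
#'
#' @param model a [transcript_model()].
#' @param gpos integer vector of genomic positions (0-based).
#' @return Integer vector of transcript positions (0-based from the 5' end)
#'   with `NA` where the position is not exonic.
#' @export
genomic_to_transcript_pos <- function(model, gpos) {
  i <- findInterval(gpos, model$exon_starts)
  ok <- i >= 1L & gpos < model$exon_ends[pmax(i, 1L)]
  out <- rep(NA_integer_, length(gpos))
  if (any(ok)) {
    ii <- i[ok]
    if (model$strand == "+") {
      out[ok] <- model$exon_offsets[ii] + (gpos[ok] - model$exon_starts[ii])
    } else {
      out[ok] <- model$exon_offsets[ii] + (model$exon_ends[ii] - 1L - gpos[ok])
    }
  }
  out
}

#' Map transcript positions back to genomic positions
#'
#' Inverse of [genomic_to_transcript_pos()]; every position inside
#' `[0, length)` maps to exactly one exonic base.
#'
#' @param model a [transcript_model()].
#' @param tpos integer vector of transcript positions.
#' @return Integer vector of genomic positions (0-based).
#' @export
transcript_pos_to_genomic <- function(model, tpos) {
  if (any(tpos < 0L | tpos >= model$length))
    stop("transcript position out of range")
  widths <- model$exon_ends - model$exon_starts
  if (model$strand == "+") {
    bounds <- c(0L, cumsum(widths))
    i <- findInterval(tpos, bounds, rightmost.closed = FALSE)
    i[tpos >= bounds[i + 1L]] <- i[tpos >= bounds[i + 1L]] + 1L  # safety
    model$exon_starts[i] + (tpos - bounds[i])
  } else {
    n <- length(widths)
    bounds <- c(0L, cumsum(rev(widths)))
    i <- findInterval(tpos, bounds)
    ei <- n + 1L - i  # genomic exon index, walking 3'->5' genomically
    model$exon_ends[ei] - 1L - (tpos - bounds[i])
  }
}

#' Project a genomic interval onto transcript coordinates
#'
#' Returns the transcript-coordinate span covered by the exonic part of
#' each interval, with introns removed; intervals with no exonic overlap
#' yield `NA`. Chromosome mismatches also yield `NA` (with a warning when
#' `warn = TRUE`).
#'
#' @param model a [transcript_model()].
#' @param start,end integer vectors (0-based half-open genomic interval).
#' @param chrom optional chromosome vector to check against the model.
#' @param warn warn on chromosome mismatch.
#' @return `data.table` with columns `t_start`, `t_end` (half-open,
#'   transcript coordinates), `NA` rows where nothing projects.
#' @export
project_to_transcript <- function(model, start, end, chrom = NULL,
                                  warn = FALSE) {
  n <- length(start)
  lo <- rep(NA_integer_, n)
  hi <- rep(NA_integer_, n)
  use <- rep(TRUE, n)
  if (!is.null(chrom)) {
    use <- chrom == model$chrom
    if (warn && !all(use))
      warning(sprintf("%d interval(s) on a different chromosome than %s",
                      sum(!use), model$transcript_id))
  }
  for (e in seq_along(model$exon_starts)) {
    es <- model$exon_starts[e]; ee <- model$exon_ends[e]
    s <- pmax(start, es); t <- pmin(end, ee)
    ov <- use & s < t
    if (!any(ov)) next
    if (model$strand == "+") {
      plo <- model$exon_offsets[e] + (s[ov] - es)
      phi <- model$exon_offsets[e] + (t[ov] - es)  # exclusive
    } else {
      plo <- model$exon_offsets[e] + (ee - t[ov])
      phi <- model$exon_offsets[e] + (ee - s[ov])  # exclusive
    }
    lo[ov] <- pmin(lo[ov], plo, na.rm = TRUE)
    hi[ov] <- pmax(hi[ov], phi, na.rm = TRUE)
  }
  data.table::data.table(t_start = lo, t_end = hi)
}

#' Extend an aligned read to fragment length
#'
#' Reconstructs the sequenced fragment from a single-end alignment: the
#' interval of width `fragment_len` starting at the read's 5' end and
#' extending in the read's 3' direction (toward larger coordinates on `+`,
#' smaller on `-`), clipped at position 0.
#'
#' @param five_prime_pos integer vector, 5'-end genomic positions (0-based).
#' @param strand character vector of `"+"`/`"-"`.
#' @param fragment_len fragment size in bp (default 150, the library's
#'   average fragment size).
#' @return `data.table` with columns `start`, `end` (0-based half-open).
#' @export
extend_fragment <- function(five_prime_pos, strand, fragment_len = 150L) {
  stopifnot(fragment_len >= 1L, all(strand %in% c("+", "-")))
  plus <- strand == "+"
  start <- ifelse(plus, five_prime_pos,
                  pmax(five_prime_pos - fragment_len + 1L, 0L))
  end <- ifelse(plus, five_prime_pos + fragment_len, five_prime_pos + 1L)
  data.table::data.table(start = as.integer(start), end = as.integer(end))
}

#' Midpoint of a transcript interval
#'
#' The base used to assign a projected fragment to windows: one
#' window-step cohort per fragment rather than every overlapped window.
#'
#' @param t_start,t_end integer vectors, half-open transcript interval.
#' @return Integer vector `floor((t_start + t_end - 1)/2)`, guaranteed to
#'   lie inside the interval.
#' @export
fragment_midpoint <- function(t_start, t_end) {
  as.integer(floor((t_start + t_end - 1L) / 2))
}

#' Select the longest isoform per gene
#'
#' When a gene has multiple annotated isoforms, all downstream analysis is
#' carried out on its longest one; ties are broken by lexicographically
#' smaller `transcript_id` so the choice is deterministic.
#'
#' @param models list of [transcript_model()] objects (any order).
#' @return Named list of models, one per `gene_id` (names are gene ids,
#'   sorted). Genes whose transcripts all lack exons are skipped with a
#'   warning (such models cannot be constructed anyway).
#' @export
select_longest_isoform <- function(models) {
  stopifnot(length(models) > 0L)
  genes <- vapply(models, function(m) m$gene_id, character(1))
  lens <- vapply(models, function(m) m$length, integer(1))
  txs <- vapply(models, function(m) m$transcript_id, character(1))
  keep <- lens > 0L
  if (!all(keep)) {
    dropped <- unique(genes[!keep])
    lost <- setdiff(dropped, genes[keep])
    if (length(lost))
      warning(sprintf("gene(s) without exonic transcripts skipped: %s",
                      paste(lost, collapse = ", ")))
  }
  out <- list()
  for (g in sort(unique(genes[keep]))) {
    idx <- which(genes == g & keep)
    best <- idx[order(-lens[idx], txs[idx])][1L]
    out[[g]] <- models[[best]]
  }
  out
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` and `CDS` features (attributes `gene_id`,
#' `transcript_id`), builds one model per transcript with UTR/CDS
#' segmentation derived from the CDS extent, and applies the
#' longest-isoform rule per gene.
#'
#' @param path GTF file path.
#' @param longest_only collapse to one model per gene (default `TRUE`).
#' @return Named list of [transcript_model()] (by `gene_id` when
#'   `longest_only`, else by `transcript_id`).
#' @export
read_gtf_models <- function(path, longest_only = TRUE) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id)
  )
  ex <- dt[type == "exon"]
  if (nrow(ex) == 0L) stop("no exon features in ", path)
  cds <- dt[type == "CDS"]
  models <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[transcript_id == tx]
    m <- transcript_model(e$gene_id[1L], tx, e$chrom[1L], e$strand[1L],
                          e$start, e$end)
    cd <- cds[transcript_id == tx]
    if (nrow(cd) > 0L) {
      # CDS span in transcript coordinates gives utr5/cds lengths
      pr <- project_to_transcript(m, cd$start, cd$end)
      cds_start <- min(pr$t_start)
      cds_len <- sum(cd$end - cd$start)
      m <- transcript_model(e$gene_id[1L], tx, e$chrom[1L], e$strand[1L],
                            e$start, e$end,
                            utr5_len = cds_start, cds_len = cds_len)
    }
    models[[tx]] <- m
  }
  if (longest_only) select_longest_isoform(models) else models
}

#' Read aligned reads from a BED6 file
#'
#' The name and score fields are ignored; strand is required. Each record
#' becomes a read alignment keyed by its 5'-end position.
#'
#' @param path BED6 file.
#' @return `data.table` with columns `chrom`, `strand`, `five_prime_pos`,
#'   `read_len`.
#' @export
read_bed_alignments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6])
  if (!all(dt$strand %in% c("+", "-")))
    stop("BED6 strand column required (+/-)")
  data.table::data.table(
    chrom = dt$chrom,
    strand = dt$strand,
    five_prime_pos = ifelse(dt$strand == "+", dt$start, dt$end - 1L),
    read_len = dt$end - dt$start
  )
}

#' Read aligned reads from a SAM file (minimal)
#'
#' Convenience reader for plain-text SAM: mapped records become read
#' alignments using the flag's strand bit and the sequence length as the
#' reference span (adequate for ungapped short-read alignments; spliced
#' CIGARs are not interpreted).
#'
#' @param path SAM file.
#' @return `data.table` as in [read_bed_alignments()].
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.table::data.table(chrom = character(), strand = character(),
                                  five_prime_pos = integer(),
                                  read_len = integer()))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = c(2:4, 10))
  flag <- as.integer(f[[1]])
  mapped <- bitwAnd(flag, 4L) == 0L
  rev <- bitwAnd(flag, 16L) != 0L
  pos0 <- as.integer(f[[3]]) - 1L
  len <- nchar(f[[4]])
  data.table::data.table(
    chrom = f[[2]][mapped],
    strand = ifelse(rev[mapped], "-", "+"),
    five_prime_pos = ifelse(rev[mapped], pos0[mapped] + len[mapped] - 1L,
                            pos0[mapped]),
    read_len = len[mapped]
  )
}
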