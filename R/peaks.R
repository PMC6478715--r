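# The m6A peak caller: read assignment, per-window testing across
# replicates, replicate intersection, window merging, and QC.

#' Peak-caller configuration
#'
#' Defaults are the procedure's published operating point: 100-nt windows
#' advanced in 10-nt steps over the longest isoform, reads extended to the
#' 150-bp average fragment size, the 1/20 top-window low-count filter,
#' FDR < 1% and log2(enrichment score) >= 1 required in every replicate.
#'
#' @param window_size,step window geometry in nt.
#' @param fragment_len read extension length in bp.
#' @param low_frac low-count filter fraction of the top window.
#' @param fdr FDR threshold on BH q-values.
#' @param min_log2_es minimum log2 enrichment score.
#' @param dispersion_floor,default_dispersion see [estimate_dispersion()].
#' @return Named list of class `peak_caller_config`.
#' @export
peak_caller_config <- function(window_size = 100L, step = 10L,
                               fragment_len = 150L, low_frac = 1 / 20,
                               fdr = 0.01, min_log2_es = 1,
                               dispersion_floor = 0.01,
                               default_dispersion = 0.05) {
  stopifnot(step > 0L, step <= window_size, low_frac > 0, low_frac < 1,
            fdr > 0, fdr < 1)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 fragment_len = as.integer(fragment_len),
                 low_frac = low_frac, fdr = fdr,
                 min_log2_es = min_log2_es,
                 dispersion_floor = dispersion_floor,
                 default_dispersion = default_dispersion),
            class = "peak_caller_config")
}

#' Assign reads to transcripts as fragment midpoints
#'
#' Reads are extended to fragment length in genomic space, intersected
#' with the exon chains of the models, projected to transcript
#' coordinates (introns removed), and reduced to the midpoint of the
#' projected span. A fragment whose genomic midpoint falls in an intron is
#' thereby carried by the nearest projected exonic base; fragments with no
#' exonic overlap are dropped.
#'
#' @param models named list of [transcript_model()] (one per gene).
#' @param reads `data.table` from [read_bed_alignments()].
#' @param fragment_len extension length in bp.
#' @return Named list (same names as `models`) of integer midpoint
#'   vectors in transcript coordinates.
#' @export
assign_midpoints <- function(models, reads, fragment_len = 150L) {
  frag <- extend_fragment(reads$five_prime_pos, reads$strand, fragment_len)
  fgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(frag$start + 1L, frag$end))
  nex <- vapply(models, function(m) length(m$exon_starts), integer(1))
  exgr <- GenomicRanges::GRanges(
    rep(vapply(models, function(m) m$chrom, character(1)), nex),
    IRanges::IRanges(unlist(lapply(models, function(m) m$exon_starts)) + 1L,
                     unlist(lapply(models, function(m) m$exon_ends))))
  model_of_exon <- rep(seq_along(models), nex)
  hits <- GenomicRanges::findOverlaps(fgr, exgr, ignore.strand = TRUE)
  pairs <- unique(data.table::data.table(
    read = S4Vectors::queryHits(hits),
    model = model_of_exon[S4Vectors::subjectHits(hits)]))
  out <- vector("list", length(models))
  names(out) <- names(models)
  for (i in seq_along(out)) out[[i]] <- integer(0)
  if (nrow(pairs)) {
    grp <- split(pairs$read, pairs$model)
    for (mi in names(grp)) {
      i <- as.integer(mi)
      idx <- grp[[mi]]
      pr <- project_to_transcript(models[[i]], frag$start[idx],
                                  frag$end[idx])
      ok <- !is.na(pr$t_start)
      out[[i]] <- fragment_midpoint(pr$t_start[ok], pr$t_end[ok])
    }
  }
  out
}

#' Window counts for a set of libraries
#'
#' Builds the sliding-window grid of every model and counts assigned
#' fragment midpoints per window for each library.
#'
#' @param models named list of [transcript_model()].
#' @param midpoint_sets named list of libraries; each element is the
#'   output of [assign_midpoints()] for one library.
#' @param window_size,step window geometry.
#' @return `data.table` with `gene_id`, `transcript_id`, `start`, `end`,
#'   `index`, and one count column per library (named after
#'   `midpoint_sets`).
#' @export
merip_window_counts <- function(models, midpoint_sets,
                                window_size = 100L, step = 10L) {
  libs <- names(midpoint_sets)
  stopifnot(!is.null(libs), all(nchar(libs) > 0L))
  res <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    w <- make_windows(m$length, window_size, step)
    dt <- data.table::data.table(gene_id = m$gene_id,
                                 transcript_id = m$transcript_id,
                                 w)
    for (lib in libs) {
      dt[[lib]] <- count_midpoints(midpoint_sets[[lib]][[names(models)[i]]],
                                   w, m$length)
    }
    res[[i]] <- dt
  }
  data.table::rbindlist(res)
}

#' Positive-window call across replicates
#'
#' A window is positive when it survives the low-count filter and shows
#' `q < fdr` and `log2(enrichment) >= min_log2_es` in every replicate
#' (intersection semantics).
#'
#' @param q,es,kept matrices with one column per replicate (q-values,
#'   enrichment scores, filter survival).
#' @param fdr,min_log2_es thresholds.
#' @return Logical vector over windows.
#' @export
call_positive_windows <- function(q, es, kept, fdr = 0.01,
                                  min_log2_es = 1) {
  q <- as.matrix(q); es <- as.matrix(es); kept <- as.matrix(kept)
  if (!all(dim(q) == dim(es)) || !all(dim(q) == dim(kept)))
    stop("replicate result matrices must share the same window grid")
  ok <- kept & !is.na(q) & q < fdr & log2(es) >= min_log2_es
  rowSums(ok) == ncol(q)
}

#' Merge overlapping windows into peak spans
#'
#' Maximal runs of windows sharing at least one base collapse into
#' `[min start, max end)`; adjacent but non-overlapping windows stay
#' separate. Idempotent.
#'
#' @param start,end integer vectors of positive-window coordinates on one
#'   transcript.
#' @return `data.table` with `t_start`, `t_end`, `n_windows`, sorted and
#'   pairwise non-overlapping.
#' @export
merge_windows <- function(start, end) {
  if (length(start) == 0L)
    return(data.table::data.table(t_start = integer(0), t_end = integer(0),
                                  n_windows = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  grp <- cumsum(c(1L, as.integer(start[-1L] >= cummax(end[-length(end)]))))
  data.table::data.table(
    t_start = as.integer(tapply(start, grp, min)),
    t_end = as.integer(tapply(end, grp, max)),
    n_windows = as.integer(tapply(start, grp, length)))
}

#' Replicate-correlation QC
#'
#' Pearson correlation of `log2(count + 1)` window-count vectors between
#' two libraries; the published QC expects biological replicates mostly
#' above 0.85.
#'
#' @param x,y equal-length count vectors (>= 3 windows).
#' @return Correlation in `[-1, 1]`.
#' @export
replicate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  lx <- log2(x + 1); ly <- log2(y + 1)
  if (stats::var(lx) == 0 || stats::var(ly) == 0)
    stop("zero-variance window counts: correlation undefined")
  stats::cor(lx, ly)
}

#' Call m6A peaks from IP/input replicate libraries
#'
#' Full procedure: assign extended-fragment midpoints to the longest
#' isoforms, scan 100/10 windows, apply the 1/20 low-count filter per
#' replicate, normalize by gene-median offsets, test each surviving
#' window with the conditional beta-binomial test (dispersion estimated
#' from the IP replicates), BH-adjust transcriptome-wide per replicate,
#' call windows positive at FDR < `fdr` with log2 enrichment >=
#' `min_log2_es` in both replicates, and merge overlapping positive
#' windows into peaks whose enrichment is recomputed over the merged span.
#'
#' @param models named list of [transcript_model()] (one per gene).
#' @param ip,input lists of read tables (one per replicate, equal length).
#' @param config a [peak_caller_config()].
#' @return List with `windows` (the full window table: counts, offsets,
#'   p/q-values, scores and the positive flag), `peaks` (merged peaks with
#'   per-replicate and geometric-mean scores plus genomic blocks),
#'   `dispersion`, and `correlations` (IP and input replicate QC).
#' @export
call_peaks <- function(models, ip, input, config = peak_caller_config()) {
  stopifnot(length(ip) == length(input), length(ip) >= 1L)
  R <- length(ip)
  mids <- list()
  for (r in seq_len(R)) {
    mids[[paste0("ip", r)]] <- assign_midpoints(models, ip[[r]],
                                                config$fragment_len)
    mids[[paste0("in", r)]] <- assign_midpoints(models, input[[r]],
                                                config$fragment_len)
  }
  win <- merip_window_counts(models, mids, config$window_size, config$step)

  ip_cols <- paste0("ip", seq_len(R))
  in_cols <- paste0("in", seq_len(R))
  phi <- if (R >= 2L) {
    estimate_dispersion(
      normalize_libsize(as.matrix(win[, ip_cols, with = FALSE])),
      config$dispersion_floor, config$default_dispersion)
  } else config$default_dispersion

  for (r in seq_len(R)) {
    ipc <- win[[ip_cols[r]]]
    inc <- win[[in_cols[r]]]
    kept <- rep(FALSE, nrow(win))
    b <- rep(NA_real_, nrow(win)); d <- rep(NA_real_, nrow(win))
    for (tx in split(seq_len(nrow(win)), win$transcript_id)) {
      k <- filter_low_windows(ipc[tx], inc[tx], config$low_frac)
      kept[tx] <- k
      if (any(k)) {
        off <- gene_median_offsets(ipc[tx][k], inc[tx][k])
        b[tx] <- off[["b"]]; d[tx] <- off[["d"]]
      }
    }
    es <- rep(NA_real_, nrow(win))
    es[kept] <- enrichment_score(ipc[kept], b[kept], inc[kept], d[kept])
    p <- rep(NA_real_, nrow(win))
    p[kept] <- nb_window_test_many(ipc[kept], inc[kept], b[kept], d[kept],
                                   phi)
    q <- rep(NA_real_, nrow(win))
    q[kept] <- bh_fdr(p[kept])
    win[[paste0("kept", r)]] <- kept
    win[[paste0("b", r)]] <- b
    win[[paste0("d", r)]] <- d
    win[[paste0("es", r)]] <- es
    win[[paste0("p", r)]] <- p
    win[[paste0("q", r)]] <- q
  }

  win$positive <- call_positive_windows(
    as.matrix(win[, paste0("q", seq_len(R)), with = FALSE]),
    as.matrix(win[, paste0("es", seq_len(R)), with = FALSE]),
    as.matrix(win[, paste0("kept", seq_len(R)), with = FALSE]),
    config$fdr, config$min_log2_es)

  peaks <- .assemble_peaks(models, win, mids, R, config)

  correlations <- list()
  if (R >= 2L) {
    correlations$ip <- replicate_correlation(win$ip1, win$ip2)
    correlations$input <- replicate_correlation(win$in1, win$in2)
  }
  list(windows = win, peaks = peaks, dispersion = phi,
       correlations = correlations)
}

.assemble_peaks <- function(models, win, mids, R, config) {
  pos <- win[positive == TRUE]
  rows <- list()
  for (g in unique(pos$gene_id)) {
    m <- models[[g]]
    pw <- pos[gene_id == g]
    merged <- merge_windows(pw$start, pw$end)
    for (j in seq_len(nrow(merged))) {
      s <- merged$t_start[j]; e <- merged$t_end[j]
      es_r <- numeric(R)
      for (r in seq_len(R)) {
        a <- sum(mids[[paste0("ip", r)]][[g]] >= s &
                   mids[[paste0("ip", r)]][[g]] < e)
        cc <- sum(mids[[paste0("in", r)]][[g]] >= s &
                    mids[[paste0("in", r)]][[g]] < e)
        es_r[r] <- enrichment_score(a, pw[[paste0("b", r)]][1L], cc,
                                    pw[[paste0("d", r)]][1L])
      }
      blocks <- transcript_to_genomic_blocks(m, s, e)
      row <- data.table::data.table(
        gene_id = g, transcript_id = m$transcript_id,
        chrom = m$chrom, strand = m$strand,
        t_start = s, t_end = e, n_windows = merged$n_windows[j],
        g_start = min(blocks$start), g_end = max(blocks$end),
        summary_score = exp(mean(log(es_r))))
      for (r in seq_len(R)) row[[paste0("es", r)]] <- es_r[r]
      row$blocks <- list(blocks)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L)
    return(data.table::data.table(
      gene_id = character(0), transcript_id = character(0),
      chrom = character(0), strand = character(0),
      t_start = integer(0), t_end = integer(0), n_windows = integer(0),
      g_start = integer(0), g_end = integer(0),
      summary_score = numeric(0)))
  out <- data.table::rbindlist(rows, fill = TRUE)
  data.table::setorder(out, chrom, g_start)
  out
}

#' Genomic exon blocks of a transcript interval
#'
#' Inverse projection of a transcript-coordinate span through the exon
#' chain: the list of genomic intervals (one per touched exon) it covers.
#'
#' @param model a [transcript_model()].
#' @param t_start,t_end half-open transcript interval.
#' @return `data.table` of `start`, `end` blocks sorted genomically.
#' @export
transcript_to_genomic_blocks <- function(model, t_start, t_end) {
  stopifnot(t_start >= 0L, t_end > t_start, t_end <= model$length)
  n <- length(model$exon_starts)
  rows <- list()
  for (e in seq_len(n)) {
    w <- model$exon_ends[e] - model$exon_starts[e]
    lo <- model$exon_offsets[e]
    hi <- lo + w
    s <- max(t_start, lo); t <- min(t_end, hi)
    if (s >= t) next
    if (model$strand == "+") {
      gs <- model$exon_starts[e] + (s - lo)
      ge <- model$exon_starts[e] + (t - lo)
    } else {
      gs <- model$exon_ends[e] - (t - lo)
      ge <- model$exon_ends[e] - (s - lo)
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(start = gs, end = ge)
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, start)
  out
}

#' Write peaks as BED12
#'
#' One record per peak: blocks are the exonic pieces of the merged span,
#' the score is `100 * min(summary_score, 10)` and the name is the gene
#' id.
#'
#' @param peaks peak table from [call_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed12 <- function(peaks, path) {
  lines <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    bl <- peaks$blocks[[i]]
    cs <- peaks$g_start[i]
    lines[i] <- paste(
      peaks$chrom[i], cs, peaks$g_end[i], peaks$gene_id[i],
      round(100 * min(peaks$summary_score[i], 10)), peaks$strand[i],
      cs, peaks$g_end[i], "0", nrow(bl),
      paste0(paste(bl$end - bl$start, collapse = ","), ","),
      paste0(paste(bl$start - cs, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the window table as TSV
#'
#' @param windows window table from [call_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  data.table::fwrite(windows, path, sep = "\t")
  invisible(path)
}
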