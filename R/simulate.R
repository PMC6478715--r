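# Synthetic-data generator: produces every input the pipeline consumes
# (GTF, FASTA, BED6 read files, count tables with ERCC rows) with the
# statistical structure the analyses assume, plus serialized ground
# truth for parameter-recovery tests.

# deterministic sub-stream seeds below 2^31 derived from the master seed
.stream_seed <- function(seed, k) {
  as.integer(((seed %% 7919) * 268435399 + k * 104729) %% 2147483629)
}

#' Simulation configuration
#'
#' Defaults are the generator's study conditions: 300 single-isoform
#' genes with log-normal lengths (median 1500 nt) split 10/50/40% into
#' 5'UTR/CDS/3'UTR, 20 peak genes with 8-fold IP enrichment planted at
#' DRACH sites near the stop codon, two replicates of 1e6 fragments per
#' library with NB-overdispersed per-gene totals (dispersion 0.05) and
#' fragment lengths jittered over 100-200 bp, a 0/3/6 h decay time
#' course with log-normal half-lives (median 4 h) calibrated by a 92
#' species spike-in ladder, and paired RPF/input libraries with a 2-fold
#' translation-efficiency reduction planted in 10 genes of the knockout
#' condition.
#'
#' @param n_genes number of genes.
#' @param n_peak_genes genes with one planted m6A peak.
#' @param peak_enrichment planted IP/input window enrichment.
#' @param depth fragments per MeRIP library.
#' @param n_replicates biological replicates per library kind.
#' @param nb_dispersion NB dispersion of per-gene MeRIP totals.
#' @param fragment_len average fragment size (the extension length).
#' @param frag_len_range fragmentation jitter range in bp.
#' @param read_len sequenced read length in bp.
#' @param len_meanlog,len_sdlog,min_len transcript length law (log-normal).
#' @param region_props 5'UTR/CDS/3'UTR proportions (sum to 1).
#' @param expr_sdlog log-normal sd of expression shares.
#' @param two_exon_frac fraction of genes given an intron.
#' @param decoy_frac fraction of genes given a shorter decoy isoform
#'   (exercises the longest-isoform rule; GTF only).
#' @param n_chrom chromosomes genes are spread over.
#' @param half_life_meanlog,half_life_sdlog decay half-life law (hours);
#'   half-lives are clipped to `[0.5, 24]` h.
#' @param decay_depth,decay_dispersion,decay_depth_factors decay-library
#'   depth at 0 h, technical NB dispersion, per-sample depth factors.
#' @param timepoints actinomycin-D chase times in hours.
#' @param n_ercc spike-in species (2-fold ladder of known amounts).
#' @param n_te_genes genes with a planted TE shift in the KO condition.
#' @param te_ratio planted KO/WT TE ratio.
#' @param te_sdlog log-normal sd of baseline TE.
#' @param te_dispersion technical NB dispersion of ribo libraries.
#' @param te_bio_dispersion between-animal dispersion of abundances
#'   (shared by the RPF and input library of one animal, so it cancels
#'   in the TE ratio).
#' @param te_depth fragments per ribo library.
#' @param seed master seed; all sub-streams derive from it.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L, n_peak_genes = 20L,
                       peak_enrichment = 8, depth = 1e6,
                       n_replicates = 2L, nb_dispersion = 0.05,
                       fragment_len = 150L, frag_len_range = c(100L, 200L),
                       read_len = 50L,
                       len_meanlog = log(1500), len_sdlog = 0.35,
                       min_len = 400L,
                       region_props = c(0.1, 0.5, 0.4),
                       expr_sdlog = 1,
                       two_exon_frac = 0.3, decoy_frac = 0.1,
                       n_chrom = 5L,
                       half_life_meanlog = log(4), half_life_sdlog = 0.5,
                       decay_depth = 1e6, decay_dispersion = 0.002,
                       decay_depth_factors = c(1, 1, 1),
                       timepoints = c(0, 3, 6),
                       n_ercc = 92L,
                       n_te_genes = 10L, te_ratio = 0.5, te_sdlog = 0.3,
                       te_dispersion = 0.002, te_bio_dispersion = 0.05,
                       te_depth = 1e6, seed = 7L) {
  if (n_peak_genes > n_genes) stop("more peak genes than genes")
  if (n_te_genes >= n_genes) stop("more TE-shift genes than genes")
  if (n_peak_genes + n_te_genes + 1L > n_genes)
    stop("peak, TE-shift and control genes exceed the gene count")
  stopifnot(abs(sum(region_props) - 1) < 1e-9, peak_enrichment > 0,
            depth > 0, nb_dispersion >= 0, all(frag_len_range > 0),
            te_ratio > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an annotated transcriptome with planted truth
#'
#' Generates gene models (a minority with introns, plus shorter decoy
#' isoforms that exist only in the GTF), random transcript sequences
#' with a DRACH motif (GGACT) planted at each peak gene's site near its
#' stop codon, and the ground truth used by all downstream recovery
#' tests: expression shares, peak positions and enrichments, true
#' half-lives, and true TE factors per condition.
#'
#' @param cfg a [sim_config()].
#' @return List with `config`, `models` (longest isoform per gene),
#'   `decoys` (extra isoforms for the GTF), `sequences` (named by
#'   transcript id) and `truth` (a `data.table`, one row per gene).
#' @export
simulate_transcriptome <- function(cfg = sim_config()) {
  set.seed(.stream_seed(cfg$seed, 1L))
  n <- cfg$n_genes
  lens <- pmax(cfg$min_len,
               as.integer(round(rlnorm(n, cfg$len_meanlog, cfg$len_sdlog))))
  utr5 <- pmax(10L, as.integer(round(cfg$region_props[1L] * lens)))
  cds <- pmax(30L, as.integer(round(cfg$region_props[2L] * lens)))
  utr3 <- lens - utr5 - cds
  gene_ids <- sprintf("g%04d", seq_len(n))
  tx_ids <- sprintf("t%04d.1", seq_len(n))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  chroms <- paste0("chr", (seq_len(n) - 1L) %% cfg$n_chrom + 1L)
  has_intron <- runif(n) < cfg$two_exon_frac
  intron_len <- ifelse(has_intron, sample(200:2000, n, replace = TRUE), 0L)

  cursor <- stats::setNames(rep(1000L, cfg$n_chrom),
                            paste0("chr", seq_len(cfg$n_chrom)))
  models <- vector("list", n)
  names(models) <- gene_ids
  decoys <- list()
  decoy_genes <- sort(sample(n, round(cfg$decoy_frac * n)))
  for (i in seq_len(n)) {
    g0 <- cursor[[chroms[i]]]
    if (has_intron[i]) {
      w1 <- lens[i] %/% 2L
      es <- c(g0, g0 + w1 + intron_len[i])
      ee <- c(g0 + w1, g0 + w1 + intron_len[i] + (lens[i] - w1))
    } else {
      es <- g0
      ee <- g0 + lens[i]
    }
    models[[i]] <- transcript_model(gene_ids[i], tx_ids[i], chroms[i],
                                    strands[i], es, ee,
                                    utr5_len = utr5[i], cds_len = cds[i])
    cursor[[chroms[i]]] <- max(ee) + 1000L
    if (i %in% decoy_genes) {
      # 5'-truncated decoy sharing the gene's last exon region
      dlen <- max(50L, lens[i] %/% 3L)
      if (strands[i] == "+") {
        ds <- max(ee) - dlen
        decoys[[length(decoys) + 1L]] <-
          transcript_model(gene_ids[i], sprintf("t%04d.2", i), chroms[i],
                           strands[i], ds, max(ee))
      } else {
        decoys[[length(decoys) + 1L]] <-
          transcript_model(gene_ids[i], sprintf("t%04d.2", i), chroms[i],
                           strands[i], min(es), min(es) + dlen)
      }
    }
  }

  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- tx_ids

  peak_genes <- sort(sample(n, cfg$n_peak_genes))
  peak_pos <- rep(NA_integer_, n)
  for (i in peak_genes) {
    delta <- sample(-100:40, 1L)
    site <- min(max(utr5[i] + cds[i] - 1L + delta, utr5[i] + 5L),
                lens[i] - 10L)
    substr(seqs[i], site + 1L, site + 5L) <- "GGACT"
    peak_pos[i] <- site
  }

  e <- rlnorm(n, 0, cfg$expr_sdlog)
  expression <- e / sum(e)
  half_life <- pmin(24, pmax(0.5, rlnorm(n, cfg$half_life_meanlog,
                                         cfg$half_life_sdlog)))
  te_base <- rlnorm(n, 0, cfg$te_sdlog)
  non_peak <- setdiff(seq_len(n), peak_genes)
  te_genes <- sort(sample(non_peak, cfg$n_te_genes))
  te_control <- sample(setdiff(non_peak, te_genes), 1L)
  te_ko <- te_base
  te_ko[te_genes] <- te_base[te_genes] * cfg$te_ratio

  truth <- data.table::data.table(
    gene_id = gene_ids, transcript_id = tx_ids,
    chrom = chroms, strand = strands, length = lens,
    utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    expression = expression,
    is_peak = seq_len(n) %in% peak_genes,
    peak_pos = peak_pos,
    peak_enrichment = ifelse(seq_len(n) %in% peak_genes,
                             cfg$peak_enrichment, NA_real_),
    half_life = half_life,
    te_wt = te_base, te_ko = te_ko,
    is_te_target = seq_len(n) %in% te_genes,
    is_te_control = seq_len(n) == te_control)

  list(config = cfg, models = models, decoys = decoys,
       sequences = seqs, truth = truth)
}

# expected enrichment -> mixing weight of the peak component, given the
# triangular kernel mass q inside a window centred on the site
.peak_mix_weight <- function(enrichment, window, transcript_len, half_width) {
  q <- if (window / 2 >= half_width) 1
       else 1 - (1 - (window / 2) / half_width)^2
  b <- (enrichment - 1) * window / transcript_len
  b / (q + b)
}

# one MeRIP library as a BED6 data.table; peak = NULL gives an input
# library
.simulate_library <- function(sim, kind, replicate, stream) {
  cfg <- sim$config
  set.seed(.stream_seed(cfg$seed, stream))
  truth <- sim$truth
  n <- cfg$n_genes
  mu <- cfg$depth * truth$expression
  totals <- if (cfg$nb_dispersion > 0) {
    rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
  } else rpois(n, mu)
  h <- cfg$fragment_len / 2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nf <- totals[i]
    if (nf == 0L) next
    m <- sim$models[[i]]
    L <- truth$length[i]
    fl <- sample(cfg$frag_len_range[1L]:cfg$frag_len_range[2L], nf,
                 replace = TRUE)
    start <- as.integer(floor(runif(nf) * (L - fl + 1L)))
    if (kind == "ip" && truth$is_peak[i]) {
      p <- .peak_mix_weight(cfg$peak_enrichment, 100L, L, h)
      from_peak <- runif(nf) < p
      if (any(from_peak)) {
        mid <- truth$peak_pos[i] +
          as.integer(round((runif(sum(from_peak)) +
                              runif(sum(from_peak)) - 1) * h))
        s <- mid - fl[from_peak] %/% 2L
        start[from_peak] <- pmin(pmax(s, 0L), L - fl[from_peak])
      }
    }
    g5 <- transcript_pos_to_genomic(m, start)
    if (m$strand == "+") {
      bs <- g5; be <- g5 + cfg$read_len
    } else {
      bs <- g5 - cfg$read_len + 1L; be <- g5 + 1L
    }
    out[[i]] <- data.table::data.table(chrom = m$chrom, start = bs,
                                       end = be, name = ".", score = 0L,
                                       strand = m$strand)
  }
  bed <- data.table::rbindlist(out)
  data.table::setattr(bed, "gene_totals",
                      data.table::data.table(gene_id = truth$gene_id,
                                             total = totals,
                                             expected = mu))
  bed
}

#' Simulate MeRIP IP/input replicate libraries
#'
#' Input fragments are placed uniformly along each transcript with
#' abundance-proportional, NB-overdispersed totals; IP fragments mix the
#' same uniform background with a triangular kernel (half-width = half
#' the fragment size) centred on each planted DRACH site, weighted so a
#' 100-nt window on the site is enriched `peak_enrichment`-fold over the
#' gene background. Replicates share the truth and differ by seed
#' stream. Reads are emitted as BED6 genomic alignments (the pipeline
#' re-extends them to fragment length).
#'
#' @param sim output of [simulate_transcriptome()].
#' @param out_dir optional directory; when given, files
#'   `ip_rep<r>.bed` / `input_rep<r>.bed` are written.
#' @return List with `ip` and `input`, each a list of BED `data.table`s
#'   (one per replicate) carrying a `"gene_totals"` attribute.
#' @export
simulate_merip <- function(sim, out_dir = NULL) {
  cfg <- sim$config
  res <- list(ip = list(), input = list())
  for (r in seq_len(cfg$n_replicates)) {
    res$ip[[r]] <- .simulate_library(sim, "ip", r, 100L + r)
    res$input[[r]] <- .simulate_library(sim, "input", r, 200L + r)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(cfg$n_replicates)) {
      data.table::fwrite(res$ip[[r]],
                         file.path(out_dir, sprintf("ip_rep%d.bed", r)),
                         sep = "\t", col.names = FALSE)
      data.table::fwrite(res$input[[r]],
                         file.path(out_dir, sprintf("input_rep%d.bed", r)),
                         sep = "\t", col.names = FALSE)
    }
  }
  res
}

#' Simulate an actinomycin-D decay time course with ERCC rows
#'
#' Expected gene counts at time `t` are proportional to
#' `A0 * 2^(-t / half_life)` times a per-sample depth factor; spike-in
#' expected counts are proportional to their known amounts times the same
#' factor. Optional NB noise at the technical dispersion; with
#' `noise = FALSE` the exact expected counts are emitted.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param noise add NB counting noise (default `TRUE`).
#' @param condition label entering the seed stream, so e.g. WT and KO
#'   time courses are independent draws of the same truth.
#' @param out_dir optional directory; writes `decay_counts_<cond>.tsv`
#'   and `ercc_amounts.tsv`.
#' @return List with `counts` (gene and `ERCC-` rows by timepoint) and
#'   `ercc_amounts`.
#' @export
simulate_decay <- function(sim, noise = TRUE, condition = "wt",
                           out_dir = NULL) {
  cfg <- sim$config
  set.seed(.stream_seed(cfg$seed, 300L + utf8ToInt(substr(condition, 1L, 1L))))
  truth <- sim$truth
  A0 <- truth$expression * 1e5  # attomole pool
  ladder <- 2^seq(-4, 14, length.out = cfg$n_ercc)
  amounts <- 0.05 * sum(A0) * ladder / sum(ladder)
  ercc_ids <- sprintf("ERCC-%04d", seq_len(cfg$n_ercc))
  tp <- cfg$timepoints
  cols <- sprintf("t%gh", tp)
  counts <- data.table::data.table(gene_id = c(truth$gene_id, ercc_ids))
  for (s in seq_along(tp)) {
    At <- A0 * 2^(-tp[s] / truth$half_life)
    kappa <- cfg$decay_depth_factors[s] * cfg$decay_depth / sum(A0)
    mu <- c(At, amounts) * kappa
    counts[[cols[s]]] <- if (noise) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$decay_dispersion)
    } else mu
  }
  ercc_amounts <- data.table::data.table(ercc_id = ercc_ids,
                                         amount = amounts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(counts,
                       file.path(out_dir,
                                 sprintf("decay_counts_%s.tsv", condition)),
                       sep = "\t")
    data.table::fwrite(ercc_amounts,
                       file.path(out_dir, "ercc_amounts.tsv"), sep = "\t")
  }
  list(counts = counts, ercc_amounts = ercc_amounts)
}

#' Simulate paired RPF / mRNA-input libraries per condition
#'
#' Input counts are proportional to abundance; RPF counts to abundance
#' times translation efficiency times the CDS length fraction. Each
#' (condition, replicate) draws one animal-level abundance vector shared
#' by its RPF and input library, so biological variation cancels in the
#' TE ratio; library-level NB noise uses the technical dispersion.
#' Planted TE-shift genes are altered only in the KO condition.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param noise add NB counting noise (default `TRUE`).
#' @param out_dir optional directory; writes
#'   `ribo_<cond>_rep<r>_{rpf,input}.tsv`.
#' @return Nested list `$wt`/`$ko` -> one element per replicate ->
#'   `list(rpf = , input = )` count tables (`gene_id`, `length` = CDS
#'   length, `count`).
#' @export
simulate_ribo <- function(sim, noise = TRUE, out_dir = NULL) {
  cfg <- sim$config
  truth <- sim$truth
  cds_frac <- truth$cds_len / truth$length
  out <- list()
  for (cond in c("wt", "ko")) {
    te <- if (cond == "wt") truth$te_wt else truth$te_ko
    reps <- list()
    for (r in seq_len(cfg$n_replicates)) {
      set.seed(.stream_seed(cfg$seed,
                            400L + 10L * r + (cond == "ko")))
      bio <- if (cfg$te_bio_dispersion > 0) {
        stats::rgamma(cfg$n_genes, shape = 1 / cfg$te_bio_dispersion,
                      scale = cfg$te_bio_dispersion)
      } else rep(1, cfg$n_genes)
      abund <- truth$expression * bio
      mu_in <- cfg$te_depth * abund / sum(abund)
      w <- abund * te * cds_frac
      mu_rpf <- cfg$te_depth * w / sum(w)
      draw <- function(mu) {
        if (noise) rnbinom(length(mu), mu = mu,
                           size = 1 / cfg$te_dispersion) else mu
      }
      reps[[r]] <- list(
        rpf = data.table::data.table(gene_id = truth$gene_id,
                                     length = truth$cds_len,
                                     count = draw(mu_rpf)),
        input = data.table::data.table(gene_id = truth$gene_id,
                                       length = truth$cds_len,
                                       count = draw(mu_in)))
    }
    out[[cond]] <- reps
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in c("wt", "ko")) for (r in seq_len(cfg$n_replicates)) {
      data.table::fwrite(out[[cond]][[r]]$rpf,
                         file.path(out_dir,
                                   sprintf("ribo_%s_rep%d_rpf.tsv", cond, r)),
                         sep = "\t")
      data.table::fwrite(out[[cond]][[r]]$input,
                         file.path(out_dir,
                                   sprintf("ribo_%s_rep%d_input.tsv",
                                           cond, r)),
                         sep = "\t")
    }
  }
  out
}

#' Write the simulated annotation as GTF
#'
#' Emits exon and CDS features (1-based, closed, per the format) for the
#' main models and exon features for decoy isoforms.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param path output GTF file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_gtf <- function(sim, path) {
  lines <- character(0)
  emit <- function(m, with_cds) {
    for (e in seq_along(m$exon_starts)) {
      lines[[length(lines) + 1L]] <<- paste(
        m$chrom, "meripkit", "exon",
        m$exon_starts[e] + 1L, m$exon_ends[e], ".", m$strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";',
                m$gene_id, m$transcript_id), sep = "\t")
    }
    if (with_cds && m$cds_len > 0L) {
      bl <- transcript_to_genomic_blocks(m, m$utr5_len,
                                         m$utr5_len + m$cds_len)
      for (e in seq_len(nrow(bl))) {
        lines[[length(lines) + 1L]] <<- paste(
          m$chrom, "meripkit", "CDS",
          bl$start[e] + 1L, bl$end[e], ".", m$strand, "0",
          sprintf('gene_id "%s"; transcript_id "%s";',
                  m$gene_id, m$transcript_id), sep = "\t")
      }
    }
  }
  for (m in sim$models) emit(m, TRUE)
  for (m in sim$decoys) emit(m, FALSE)
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Write simulated transcript sequences as FASTA
#'
#' @param sim output of [simulate_transcriptome()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(sim, path) {
  ss <- Biostrings::DNAStringSet(sim$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Serialize the ground truth as JSON
#'
#' Self-contained: recovery tests need only the emitted directory.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sim, path) {
  jsonlite::write_json(list(
    seed = sim$config$seed,
    n_genes = sim$config$n_genes,
    truth = sim$truth), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Simulate every pipeline input into a directory
#'
#' Convenience driver: transcriptome (GTF + FASTA + truth JSON), MeRIP
#' BED libraries, decay count tables for both conditions, and ribo count
#' tables.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created).
#' @return The `sim` object, invisibly.
#' @export
simulate_all <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_transcriptome(cfg)
  write_transcriptome_gtf(sim, file.path(out_dir, "annotation.gtf"))
  write_transcriptome_fasta(sim, file.path(out_dir, "transcripts.fa"))
  write_truth_json(sim, file.path(out_dir, "truth.json"))
  simulate_merip(sim, out_dir = out_dir)
  simulate_decay(sim, condition = "wt", out_dir = out_dir)
  simulate_decay(sim, condition = "ko", out_dir = out_dir)
  simulate_ribo(sim, out_dir = out_dir)
  invisible(sim)
}
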