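# Orchestration: merged run configuration, subcommand dispatch, run
# manifests, and the end-to-end demo driver on synthetic data.

#' Merged run configuration
#'
#' Every default mirrors the procedure's printed operating point where
#' one exists: 100/10 window geometry, 150-bp fragment extension, the
#' 1/20 low-count filter, FDR < 1% with log2 enrichment >= 1, the
#' 1.5-fold & P < 0.01 DE filter, 0/3/6 h chase times, 10/50/40 metagene
#' bins and the GGACU motif.
#'
#' @param ... overrides for any field.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    window_size = 100L, step = 10L, fragment_len = 150L,
    low_frac = 1 / 20, fdr = 0.01, min_log2_es = 1,
    dispersion_floor = 0.01, default_dispersion = 0.05,
    fc_min = 1.5, p_max = 0.01,
    times = c(0, 3, 6), bins = c(10L, 50L, 40L),
    motif = "GGACU", min_input_rpkm = 1,
    threads = 1L, seed = 7L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as key = value lines
#'
#' Round-trips unchanged through its file representation.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a [run_config()]; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  base <- run_config()
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad config line: ", ln)
    k <- trimws(kv[1L])
    if (!k %in% names(base)) stop("unknown config field: ", k)
    v <- strsplit(trimws(kv[2L]), ",", fixed = TRUE)[[1L]]
    proto <- base[[k]]
    over[[k]] <- if (is.integer(proto)) as.integer(v)
                 else if (is.numeric(proto)) as.numeric(v)
                 else v
  }
  do.call(run_config, over)
}

#' Write a run manifest
#'
#' Records the seed, configuration, package version and timestamp next
#' to a run's outputs for reproducibility.
#'
#' @param out_dir output directory.
#' @param seed the run's master seed.
#' @param config configuration list.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, seed, config) {
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(list(
    seed = seed,
    config = unclass(config),
    package = "meripkit",
    version = as.character(utils::packageVersion("meripkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end demonstration on fresh synthetic data
#'
#' Simulates a complete dataset, then runs peak calling, the metagene
#' profile, motif scanning over peak sequences, half-life estimation for
#' both conditions, TE contrasts and the DE filter, writing every report
#' to `out_dir`.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param sim_cfg a [sim_config()]; the default is a small preset
#'   (60 genes, 1e5 fragments) sized for a quick demonstration.
#' @param config a [run_config()].
#' @return Invisible list of the in-memory results.
#' @export
run_demo <- function(out_dir, seed = 7L,
                     sim_cfg = sim_config(n_genes = 60L, n_peak_genes = 8L,
                                          depth = 1e5, te_depth = 2e5,
                                          decay_depth = 2e5,
                                          n_te_genes = 5L, seed = seed),
                     config = run_config(seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_all(sim_cfg, out_dir)
  merip <- simulate_merip(sim)
  pk_cfg <- peak_caller_config(
    window_size = config$window_size, step = config$step,
    fragment_len = config$fragment_len, low_frac = config$low_frac,
    fdr = config$fdr, min_log2_es = config$min_log2_es,
    dispersion_floor = config$dispersion_floor,
    default_dispersion = config$default_dispersion)
  reads_ip <- lapply(merip$ip, .bed_dt_to_alignments)
  reads_in <- lapply(merip$input, .bed_dt_to_alignments)
  pk <- call_peaks(sim$models, reads_ip, reads_in, pk_cfg)
  write_peaks_bed12(pk$peaks, file.path(out_dir, "peaks.bed12"))
  write_window_table(pk$windows, file.path(out_dir, "windows.tsv"))

  prof <- metagene_profile(pk$peaks, sim$models, config$bins)
  write_metagene_tsv(prof, file.path(out_dir, "metagene.tsv"), config$bins)
  motif <- scan_motif_set(sim$sequences, config$motif)
  data.table::fwrite(motif, file.path(out_dir, "motif_hits.tsv"),
                     sep = "\t")

  lifetimes <- list()
  for (cond in c("wt", "ko")) {
    dk <- simulate_decay(sim, condition = cond)
    lifetimes[[cond]] <- lifetime_pipeline(dk$counts, dk$ercc_amounts,
                                           config$times)
    data.table::fwrite(lifetimes[[cond]],
                       file.path(out_dir, sprintf("lifetime_%s.tsv", cond)),
                       sep = "\t")
  }
  data.table::fwrite(lifetime_compare(lifetimes$wt, lifetimes$ko),
                     file.path(out_dir, "lifetime_compare.tsv"), sep = "\t")

  ribo <- simulate_ribo(sim)
  contrasts <- list()
  for (r in seq_len(sim$config$n_replicates)) {
    te_wt <- compute_te(ribo$wt[[r]]$rpf, ribo$wt[[r]]$input,
                        config$min_input_rpkm, "wt")
    te_ko <- compute_te(ribo$ko[[r]]$rpf, ribo$ko[[r]]$input,
                        config$min_input_rpkm, "ko")
    contrasts[[r]] <- te_contrast(te_ko, te_wt)
    data.table::fwrite(contrasts[[r]],
                       file.path(out_dir, sprintf("te_contrast_rep%d.tsv", r)),
                       sep = "\t")
  }

  de_in <- contrasts[[1L]]
  write_manifest(out_dir, seed, config)
  invisible(list(sim = sim, peaks = pk, metagene = prof,
                 lifetimes = lifetimes, te_contrasts = contrasts))
}

# BED-shaped data.table (as emitted by simulate_merip) -> read alignments
.bed_dt_to_alignments <- function(bed) {
  data.table::data.table(
    chrom = bed$chrom,
    strand = bed$strand,
    five_prime_pos = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
    read_len = bed$end - bed$start)
}

#' Dispatch a pipeline subcommand
#'
#' Thin programmatic surface behind the command-line script: `simulate`,
#' `callpeaks`, `metagene`, `motif`, `lifetime`, `te`, `diffexp` and
#' `demo`. Each subcommand validates its inputs and writes its declared
#' outputs plus a run manifest.
#'
#' @param name subcommand name.
#' @param args character vector of `--flag value` arguments (see the
#'   script in `inst/scripts/meripkit-cli.R`).
#' @return Integer exit status: 0 success, 2 missing input, 3 invalid
#'   configuration or arguments.
#' @export
run_subcommand <- function(name, args = character()) {
  opts <- .parse_cli_args(args)
  get_opt <- function(k, default = NULL) {
    if (!is.null(opts[[k]])) opts[[k]] else default
  }
  need_file <- function(path) {
    if (is.null(path) || !file.exists(path)) {
      cond <- simpleError(paste0("missing input: ",
                                 if (is.null(path)) "(unset)" else path))
      class(cond) <- c("meripkit_missing_input", class(cond))
      stop(cond)
    }
    path
  }
  status <- tryCatch({
    seed <- as.integer(get_opt("seed", 7L))
    out <- get_opt("out", "meripkit_out")
    switch(name,
      demo = {
        run_demo(out, seed = seed)
      },
      simulate = {
        preset <- get_opt("preset", "default")
        cfg <- switch(preset,
          default = sim_config(seed = seed),
          null = sim_config(n_genes = 100L, n_peak_genes = 0L,
                            depth = 2e5, seed = seed),
          `decay-only` = sim_config(n_genes = 200L, n_peak_genes = 0L,
                                    depth = 1e5, seed = seed),
          stop("invalid preset: ", preset))
        simulate_all(cfg, out)
        write_manifest(out, seed, unclass(cfg))
      },
      callpeaks = {
        models <- read_gtf_models(need_file(get_opt("gtf")))
        cfgfile <- get_opt("config")
        rc <- if (is.null(cfgfile)) run_config()
              else read_run_config(need_file(cfgfile))
        ip <- lapply(c(get_opt("ip1"), get_opt("ip2")),
                     function(p) read_bed_alignments(need_file(p)))
        input <- lapply(c(get_opt("input1"), get_opt("input2")),
                        function(p) read_bed_alignments(need_file(p)))
        if (length(ip) != length(input) || length(ip) == 0L)
          stop("need matched --ip<r>/--input<r> files")
        pc <- peak_caller_config(
          window_size = rc$window_size, step = rc$step,
          fragment_len = rc$fragment_len, low_frac = rc$low_frac,
          fdr = rc$fdr, min_log2_es = rc$min_log2_es)
        pk <- call_peaks(models, ip, input, pc)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_peaks_bed12(pk$peaks, file.path(out, "peaks.bed12"))
        write_window_table(pk$windows, file.path(out, "windows.tsv"))
        write_manifest(out, seed, rc)
      },
      metagene = {
        models <- read_gtf_models(need_file(get_opt("gtf")))
        peaks <- data.table::fread(need_file(get_opt("peaks")))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        prof <- metagene_profile(peaks, models)
        write_metagene_tsv(prof, file.path(out, "metagene.tsv"))
      },
      motif = {
        fa <- Biostrings::readDNAStringSet(need_file(get_opt("fasta")))
        hits <- scan_motif_set(fa, get_opt("pattern", "DRACH"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        data.table::fwrite(hits, file.path(out, "motif_hits.tsv"),
                           sep = "\t")
      },
      lifetime = {
        counts <- data.table::fread(need_file(get_opt("counts")))
        ercc <- data.table::fread(need_file(get_opt("ercc-amounts")))
        times <- as.numeric(strsplit(get_opt("times", "0,3,6"),
                                     ",")[[1L]])
        fit <- lifetime_pipeline(counts, ercc, times)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        data.table::fwrite(fit, file.path(out, "lifetime.tsv"), sep = "\t")
      },
      te = {
        rd <- function(k) data.table::fread(need_file(get_opt(k)))
        te_wt <- compute_te(rd("rpf-wt"), rd("input-wt"), condition = "wt")
        te_ko <- compute_te(rd("rpf-ko"), rd("input-ko"), condition = "ko")
        ct <- te_contrast(te_ko, te_wt)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        data.table::fwrite(ct, file.path(out, "te_contrast.tsv"),
                           sep = "\t")
      },
      diffexp = {
        a <- data.table::fread(need_file(get_opt("wt")))
        b <- data.table::fread(need_file(get_opt("ko")))
        m <- merge(a[, .(gene_id, expr_a = count)],
                   b[, .(gene_id, expr_b = count)], by = "gene_id")
        p <- vapply(seq_len(nrow(m)), function(i)
          audic_claverie_p(m$expr_a[i], m$expr_b[i],
                           sum(m$expr_a), sum(m$expr_b)), numeric(1))
        res <- de_filter(m$expr_a, m$expr_b, p, m$gene_id)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        data.table::fwrite(res, file.path(out, "diffexp.tsv"), sep = "\t")
      },
      stop("unknown subcommand: ", name))
    0L
  },
  meripkit_missing_input = function(e) {
    message(conditionMessage(e)); 2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 3L
  })
  invisible(status)
}

.parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    k <- substring(a, 3L)
    if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      out[[k]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[k]] <- TRUE
      i <- i + 1L
    }
  }
  out
}
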