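test_that("the generator is deterministic given a master seed", {
  cfg <- sim_config(n_genes = 25L, n_peak_genes = 4L, depth = 2e4, seed = 77L)
  s1 <- simulate_transcriptome(cfg)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_merip(s1)
  m2 <- simulate_merip(s2)
  for (r in 1:2) {
    expect_identical(as.data.frame(m1$ip[[r]]), as.data.frame(m2$ip[[r]]))
    expect_identical(as.data.frame(m1$input[[r]]),
                     as.data.frame(m2$input[[r]]))
  }
  d1 <- simulate_decay(s1); d2 <- simulate_decay(s2)
  expect_identical(as.data.frame(d1$counts), as.data.frame(d2$counts))
  r1 <- simulate_ribo(s1); r2 <- simulate_ribo(s2)
  expect_identical(as.data.frame(r1$ko[[2]]$rpf),
                   as.data.frame(r2$ko[[2]]$rpf))
  # written files are byte-identical as well
  dir1 <- tempfile(); dir2 <- tempfile()
  simulate_merip(s1, out_dir = dir1)
  simulate_merip(s2, out_dir = dir2)
  f1 <- file.path(dir1, "ip_rep1.bed"); f2 <- file.path(dir2, "ip_rep1.bed")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted truth is internally consistent with sequences and models", {
  cfg <- sim_config(n_genes = 40L, n_peak_genes = 6L, seed = 19L)
  sim <- simulate_transcriptome(cfg)
  truth <- sim$truth
  expect_identical(sum(truth$is_peak), 6L)
  planted <- truth[truth$is_peak, ]
  for (i in seq_len(nrow(planted))) {
    s <- sim$sequences[[planted$transcript_id[i]]]
    # planted sites sit on a DRACH occurrence
    motif <- substr(s, planted$peak_pos[i] + 1L, planted$peak_pos[i] + 5L)
    expect_identical(motif, "GGACT")
  }
  expect_equal(sum(truth$expression), 1)
  expect_true(all(truth$half_life >= 0.5 & truth$half_life <= 24))
  expect_true(all(truth$utr5_len + truth$cds_len + truth$utr3_len ==
                    truth$length))
  # TE targets are shifted only in the KO condition
  expect_equal(truth$te_ko[truth$is_te_target] /
                 truth$te_wt[truth$is_te_target],
               rep(cfg$te_ratio, cfg$n_te_genes))
  expect_identical(truth$te_ko[!truth$is_te_target],
                   truth$te_wt[!truth$is_te_target])
  expect_error(sim_config(n_genes = 5L, n_peak_genes = 6L), "peak genes")
})

test_that("emitted GTF/FASTA/BED/truth round-trip through the readers", {
  cfg <- sim_config(n_genes = 30L, n_peak_genes = 5L, depth = 2e4,
                    seed = 11L)
  sim <- simulate_transcriptome(cfg)
  dir <- tempfile()
  simulate_all(cfg, dir)
  models2 <- read_gtf_models(file.path(dir, "annotation.gtf"))
  expect_identical(names(models2), names(sim$models))
  for (g in names(sim$models)) {
    a <- sim$models[[g]]; b <- models2[[g]]
    expect_identical(b$transcript_id, a$transcript_id)
    expect_identical(b$exon_starts, a$exon_starts)
    expect_identical(b$exon_ends, a$exon_ends)
    expect_identical(b$utr5_len, a$utr5_len)
    expect_identical(b$cds_len, a$cds_len)
    expect_identical(b$strand, a$strand)
  }
  fa <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  expect_identical(as.character(fa), sim$sequences)
  al <- read_bed_alignments(file.path(dir, "ip_rep1.bed"))
  expect_gt(nrow(al), 0)
  expect_true(all(al$read_len == cfg$read_len))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$n_genes, 30L)
  expect_identical(nrow(truth$truth), 30L)
})

test_that("decoy isoforms are shorter and lose to the longest-isoform rule", {
  cfg <- sim_config(n_genes = 50L, decoy_frac = 0.3, seed = 23L)
  sim <- simulate_transcriptome(cfg)
  expect_gt(length(sim$decoys), 0)
  for (d in sim$decoys) {
    expect_lt(d$length, sim$models[[d$gene_id]]$length)
  }
  # reading the GTF (which contains the decoys) still returns the majors
  dir <- tempfile(); dir.create(dir)
  write_transcriptome_gtf(sim, file.path(dir, "a.gtf"))
  models <- read_gtf_models(file.path(dir, "a.gtf"))
  for (g in names(models)) {
    expect_identical(models[[g]]$transcript_id,
                     sim$models[[g]]$transcript_id)
  }
})

test_that("simulated per-gene totals match the configured NB dispersion", {
  cfg <- sim_config(n_genes = 2000L, n_peak_genes = 0L, depth = 2e5,
                    min_len = 300L, seed = 101L)
  sim <- simulate_transcriptome(cfg)
  lib <- meripkit:::.simulate_library(sim, "input", 1L, 201L)
  tot <- attr(lib, "gene_totals")
  x <- tot$total; mu <- tot$expected
  keep <- mu > 5
  phi_hat <- mean(((x[keep] - mu[keep])^2 - mu[keep]) / mu[keep]^2)
  expect_lt(abs(phi_hat / cfg$nb_dispersion - 1), 0.2)
})

test_that("IP libraries are enriched over input at planted sites", {
  cfg <- sim_config(n_genes = 40L, n_peak_genes = 8L, depth = 2e5,
                    seed = 31L)
  sim <- simulate_transcriptome(cfg)
  merip <- simulate_merip(sim)
  mids_ip <- assign_midpoints(sim$models, bed_to_alignments(merip$ip[[1]]))
  mids_in <- assign_midpoints(sim$models, bed_to_alignments(merip$input[[1]]))
  planted <- sim$truth[sim$truth$is_peak, ]
  ratios <- numeric(0)
  for (i in seq_len(nrow(planted))) {
    g <- planted$gene_id[i]; site <- planted$peak_pos[i]
    L <- planted$length[i]
    w <- c(max(site - 50L, 0L), min(site + 50L, L))
    a <- sum(mids_ip[[g]] >= w[1] & mids_ip[[g]] < w[2])
    cc <- sum(mids_in[[g]] >= w[1] & mids_in[[g]] < w[2])
    # background rate per base from totals outside the peak
    bg_ip <- (length(mids_ip[[g]]) - a) / (L - diff(w))
    bg_in <- (length(mids_in[[g]]) - cc) / (L - diff(w))
    ratios <- c(ratios, (a / diff(w)) / bg_ip)
    # input shows no enrichment
    expect_lt((cc / diff(w)) / bg_in, 2.5)
  }
  expect_gt(median(ratios), 4)
})
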