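test_that("positive calls require FDR and enrichment in every replicate", {
  q <- rbind(c(0.001, 0.002), c(0.001, 0.02), c(0.001, 0.001))
  es <- rbind(c(2^2.1, 2^1.5), c(2^2.1, 2^1.5), c(2^0.9, 2^3.0))
  kept <- matrix(TRUE, 3, 2)
  expect_identical(call_positive_windows(q, es, kept),
                   c(TRUE, FALSE, FALSE))
  # a filtered window can never be positive
  kept[1, 2] <- FALSE
  expect_false(call_positive_windows(q, es, kept)[1])
  expect_error(call_positive_windows(q[, 1, drop = FALSE], es, kept),
               "grid")
})

test_that("window merging unions overlapping runs and is idempotent", {
  mw <- merge_windows(c(0L, 10L, 200L), c(100L, 110L, 300L))
  expect_identical(mw$t_start, c(0L, 200L))
  expect_identical(mw$t_end, c(110L, 300L))
  expect_identical(mw$n_windows, c(2L, 1L))

  one <- merge_windows(40L, 140L)
  expect_identical(one$t_start, 40L)
  expect_identical(one$t_end, 140L)

  # touching half-open windows do not merge
  two <- merge_windows(c(0L, 100L), c(100L, 200L))
  expect_identical(nrow(two), 2L)

  again <- merge_windows(mw$t_start, mw$t_end)
  expect_identical(again$t_start, mw$t_start)
  expect_identical(again$t_end, mw$t_end)
  # output is sorted and pairwise non-overlapping
  set.seed(3)
  s <- sample.int(500L, 40L, replace = TRUE)
  m <- merge_windows(s, s + sample(10:120, 40L, replace = TRUE))
  expect_true(all(diff(m$t_start) > 0))
  expect_true(all(utils::head(m$t_end, -1) <= utils::tail(m$t_start, -1)))
})

test_that("replicate correlation is computed on log2(count + 1)", {
  x <- c(3L, 10L, 200L, 4L, 0L)
  expect_identical(replicate_correlation(x, x), 1)
  # value frozen from the definition itself: cor of the log2 vectors
  expect_equal(replicate_correlation(c(0L, 1L, 2L), c(2L, 1L, 0L)),
               cor(log2(c(1, 2, 3)), log2(c(3, 2, 1))))
  expect_lt(replicate_correlation(c(0L, 1L, 2L), c(2L, 1L, 0L)), -0.9)
  expect_error(replicate_correlation(c(5L, 5L, 5L), x[1:3]), "variance")
})

test_that("genomic blocks of a transcript span invert the projection", {
  m <- transcript_model("g", "t", "chr1", "+", c(100, 300), c(200, 400))
  bl <- transcript_to_genomic_blocks(m, 50L, 150L)
  expect_identical(bl$start, c(150L, 300L))
  expect_identical(bl$end, c(200L, 350L))
  expect_identical(sum(bl$end - bl$start), 100L)

  mm <- transcript_model("g", "t", "chr1", "-", c(100, 300), c(200, 400))
  bl2 <- transcript_to_genomic_blocks(mm, 0L, 120L)
  # first 100 transcript bases are the downstream exon read backwards
  expect_identical(sum(bl2$end - bl2$start), 120L)
  expect_identical(bl2$start, c(180L, 300L))
  expect_identical(bl2$end, c(200L, 400L))
})

test_that("midpoint assignment drops intron-only fragments and projects spans", {
  m <- transcript_model("gX", "tX", "chr1", "+", c(100, 300), c(200, 400))
  models <- list(gX = m)
  reads <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "+", "+"),
    five_prime_pos = c(120L, 250L, 190L, 120L),
    read_len = 50L)
  mids <- assign_midpoints(models, reads, fragment_len = 50L)
  # read 1: [120,170) -> transcript [20,70) -> midpoint 44
  # read 2: intron-only [250,300)... no overlap -> dropped
  # read 3: [190,250) -> exonic [190,200) -> transcript [90,100) -> 94
  # read 4: wrong chromosome -> dropped
  expect_identical(sort(mids$gX), c(44L, 94L))
})

test_that("an end-to-end call on a constructed enrichment recovers the peak", {
  # one long transcript, strong planted IP enrichment at [300, 400)
  len <- 1000L
  m <- transcript_model("gE", "tE", "chr1", "+", 0, len, utr5_len = 100L,
                        cds_len = 500L)
  models <- list(gE = m)
  set.seed(99)
  mk_reads <- function(n_bg, n_peak) {
    pos <- c(sample.int(len - 150L, n_bg, replace = TRUE) - 1L,
             300L + sample.int(60L, n_peak, replace = TRUE))
    data.table::data.table(chrom = "chr1", strand = "+",
                           five_prime_pos = pos, read_len = 50L)
  }
  ip <- list(mk_reads(2000L, 1500L), mk_reads(2000L, 1500L))
  input <- list(mk_reads(2000L, 0L), mk_reads(2000L, 0L))
  pk <- call_peaks(models, ip, input)
  expect_gt(nrow(pk$peaks), 0)
  expect_true(any(pk$peaks$t_start < 450 & pk$peaks$t_end > 350))
  expect_gt(max(pk$peaks$summary_score), 2)
  # window table carries counts, offsets and q-values for both replicates
  expect_true(all(c("ip1", "in2", "b1", "d2", "q1", "q2", "es1",
                    "positive") %in% names(pk$windows)))
  # peaks do not overlap each other
  if (nrow(pk$peaks) > 1) {
    o <- order(pk$peaks$t_start)
    expect_true(all(utils::head(pk$peaks$t_end[o], -1) <=
                      utils::tail(pk$peaks$t_start[o], -1)))
  }
})

test_that("BED12 output round-trips peak block structure", {
  m <- transcript_model("gB", "tB", "chr1", "-", c(100, 300), c(200, 400))
  blocks <- transcript_to_genomic_blocks(m, 50L, 150L)
  peaks <- data.table::data.table(
    gene_id = "gB", transcript_id = "tB", chrom = "chr1", strand = "-",
    t_start = 50L, t_end = 150L, n_windows = 3L,
    g_start = min(blocks$start), g_end = max(blocks$end),
    summary_score = 4.2)
  peaks$blocks <- list(blocks)
  f <- tempfile(fileext = ".bed")
  write_peaks_bed12(peaks, f)
  fields <- strsplit(readLines(f), "\t")[[1L]]
  expect_identical(fields[1], "chr1")
  expect_identical(as.integer(fields[2]), min(blocks$start))
  expect_identical(as.integer(fields[3]), max(blocks$end))
  expect_identical(fields[4], "gB")
  expect_identical(as.integer(fields[10]), nrow(blocks))
  sizes <- as.integer(strsplit(fields[11], ",")[[1L]])
  starts <- as.integer(strsplit(fields[12], ",")[[1L]])
  expect_identical(sizes, blocks$end - blocks$start)
  expect_identical(starts, blocks$start - min(blocks$start))
})
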