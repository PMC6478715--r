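test_that("longest isoform is selected per gene, ties broken lexicographically", {
  m900 <- transcript_model("g1", "tA", "chr1", "+", 0, 900)
  m1200 <- transcript_model("g1", "tB", "chr1", "+", 2000, 3200)
  sel <- select_longest_isoform(list(m900, m1200))
  expect_identical(sel$g1$transcript_id, "tB")
  expect_identical(sel$g1$length, 1200L)

  single <- transcript_model("g2", "tS", "chr1", "-", 0, 500)
  expect_identical(select_longest_isoform(list(single))$g2, single)

  tie1 <- transcript_model("g3", "tZ", "chr1", "+", 0, 1000)
  tie2 <- transcript_model("g3", "tA", "chr1", "+", 5000, 6000)
  expect_identical(select_longest_isoform(list(tie1, tie2))$g3$transcript_id,
                   "tA")
})

test_that("fragment extension is strand-aware from the 5' end and clips at 0", {
  e <- extend_fragment(c(1000L, 1000L, 50L), c("+", "-", "-"), 150L)
  expect_identical(e$start, c(1000L, 851L, 0L))
  expect_identical(e$end, c(1150L, 1001L, 51L))
})

test_that("point projection removes introns and flips on the minus strand", {
  m <- transcript_model("g", "t", "chr1", "+", c(100, 300), c(200, 400))
  expect_identical(genomic_to_transcript_pos(m, 150L), 50L)
  expect_identical(genomic_to_transcript_pos(m, 350L), 150L)
  expect_true(is.na(genomic_to_transcript_pos(m, 250L)))

  mm <- transcript_model("g", "t", "chr1", "-", 100, 200)
  expect_identical(genomic_to_transcript_pos(mm, 199L), 0L)
  expect_identical(genomic_to_transcript_pos(mm, 100L), 99L)
})

test_that("interval projection returns the exonic span and NA off-exon", {
  m <- transcript_model("g", "t", "chr1", "+", c(100, 300), c(200, 400))
  pr <- project_to_transcript(m, c(150L, 250L, 150L), c(360L, 260L, 160L))
  expect_identical(pr$t_start, c(50L, NA_integer_, 50L))
  expect_identical(pr$t_end, c(160L, NA_integer_, 60L))
  # chromosome mismatch yields nothing
  pr2 <- project_to_transcript(m, 150L, 160L, chrom = "chr9")
  expect_true(is.na(pr2$t_start))
})

test_that("fragment midpoints follow the floor rule and stay inside", {
  expect_identical(fragment_midpoint(0L, 150L), 74L)
  expect_identical(fragment_midpoint(10L, 11L), 10L)
  expect_identical(fragment_midpoint(0L, 2L), 0L)
})

test_that("exon projection round-trips [0, length) on both strands", {
  set.seed(41)
  for (i in 1:50) {
    m <- random_toy_model(i)
    pieces <- lapply(seq_along(m$exon_starts), function(e) {
      pr <- project_to_transcript(m, m$exon_starts[e], m$exon_ends[e])
      seq.int(pr$t_start, pr$t_end - 1L)
    })
    expect_identical(sort(unlist(pieces)), seq.int(0L, m$length - 1L))
    # inverse mapping agrees base by base
    tp <- seq.int(0L, m$length - 1L)
    expect_identical(genomic_to_transcript_pos(m, transcript_pos_to_genomic(m, tp)),
                     tp)
  }
})

test_that("projected span length equals the exonic overlap length", {
  set.seed(42)
  for (i in 1:50) {
    m <- random_toy_model(i)
    gmin <- min(m$exon_starts); gmax <- max(m$exon_ends)
    s <- sample(gmin:(gmax - 1L), 5L, replace = TRUE)
    e <- s + sample(1:120, 5L, replace = TRUE)
    pr <- project_to_transcript(m, s, e)
    for (j in 1:5) {
      ov <- sum(pmax(0L, pmin(e[j], m$exon_ends) - pmax(s[j], m$exon_starts)))
      if (ov == 0L) {
        expect_true(is.na(pr$t_start[j]))
      } else {
        # a contiguous genomic interval cannot skip a middle exon, so the
        # projected span length always equals the exonic overlap
        expect_identical(pr$t_end[j] - pr$t_start[j], ov)
      }
    }
  }
})

test_that("single-exon projection preserves order on + and reverses on -", {
  mp <- transcript_model("g", "t", "chrT", "+", 100, 120)
  mn <- transcript_model("g", "t", "chrT", "-", 100, 120)
  g <- 100:119
  expect_identical(genomic_to_transcript_pos(mp, g), 0:19)
  expect_identical(genomic_to_transcript_pos(mn, g), 19:0)
})

test_that("BED6 and SAM readers produce 5'-anchored alignments", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t150\tr1\t0\t+",
               "chr1\t200\t260\tr2\t0\t-"), bed)
  al <- read_bed_alignments(bed)
  expect_identical(al$five_prime_pos, c(100L, 259L))
  expect_identical(al$read_len, c(50L, 60L))

  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste("r1", 0, "chr1", 101, 60, "10M", "*", 0, 0,
                     "ACGTACGTAC", "*", sep = "\t"),
               paste("r2", 16, "chr1", 201, 60, "10M", "*", 0, 0,
                     "ACGTACGTAC", "*", sep = "\t"),
               paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
                     "ACGT", "*", sep = "\t")), sam)
  als <- read_sam_alignments(sam)
  expect_identical(nrow(als), 2L)
  expect_identical(als$five_prime_pos, c(100L, 209L))
  expect_identical(als$strand, c("+", "-"))
})

test_that("model invariants are enforced", {
  expect_error(transcript_model("g", "t", "chr1", "+", c(0, 50), c(100, 150)),
               "overlap")
  expect_error(transcript_model("g", "t", "chr1", "+", 10, 10))
  m <- transcript_model("g", "t", "chr1", "+", 0, 100, utr5_len = 10,
                        cds_len = 60)
  expect_identical(m$utr5_len + m$cds_len + m$utr3_len, m$length)
  expect_error(transcript_model("g", "t", "chr1", "+", 0, 100,
                                utr5_len = 60, cds_len = 60))
})
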