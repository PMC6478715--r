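test_that("spike-in calibration recovers a noise-free proportionality exactly", {
  cal <- ercc_calibrate(c(1, 10, 100), c(20, 200, 2000))
  expect_equal(cal$slope, 1, tolerance = 1e-6)
  expect_equal(to_abundance(200, cal), 10, tolerance = 1e-6)
  expect_equal(to_abundance(20, cal), 1, tolerance = 1e-6)
  expect_equal(cal$r2, 1, tolerance = 1e-9)
  expect_error(ercc_calibrate(c(1, 10, 100), c(50, 50, 50)), "variance")
  expect_error(ercc_calibrate(c(1, 10, 100), c(0, 0, 5)), "3 spike-ins")
})

test_that("noisy calibration reports imperfect fit without error", {
  set.seed(21)
  amounts <- 2^seq(-4, 14, length.out = 92)
  counts <- rnbinom(92, mu = amounts * 8, size = 20)
  cal <- ercc_calibrate(amounts, counts)
  expect_lt(cal$r2, 1)
  expect_gt(cal$r2, 0.8)
  expect_true(is.finite(cal$slope) && is.finite(cal$intercept))
})

test_that("count-to-abundance conversion is monotone with a zero floor", {
  cal <- ercc_calibrate(c(1, 10, 100), c(20, 200, 2000))
  expect_equal(to_abundance(0, cal), 2^cal$intercept)
  a <- to_abundance(c(1, 5, 10, 100, 1e4), cal)
  expect_true(all(diff(a) > 0))
  # doubling the count with slope 1 doubles the abundance
  expect_equal(to_abundance(400, cal) / to_abundance(200, cal), 2,
               tolerance = 1e-6)
})

test_that("decay rates and half-lives follow the log2 kinetics", {
  expect_equal(decay_rate(0.5, 1, 3), 1 / 3)
  expect_identical(decay_rate(1, 1, 3), 0)
  expect_equal(decay_rate(0.25, 1, 6), 1 / 3)
  hl <- half_life(c(0.5, 1 / 3, -0.1, 0.2), c(0.5, 1 / 3, 0.05, -0.2))
  expect_equal(hl$t_half[1:2], c(2, 3))
  expect_true(all(is.na(hl$t_half[3:4])))
  expect_identical(hl$flag[3:4], c("unstable", "unstable"))
  # half_life(k, k) = 1/k exactly
  for (k in c(0.05, 0.31, 2)) expect_equal(half_life(k, k)$t_half, 1 / k)
})

test_that("noise-free simulated time courses are recovered to machine precision", {
  sim <- simulate_transcriptome(sim_config(n_genes = 80L, seed = 5L))
  dk <- simulate_decay(sim, noise = FALSE)
  fit <- lifetime_pipeline(dk$counts, dk$ercc_amounts)
  m <- merge(fit, sim$truth[, c("gene_id", "half_life")], by = "gene_id")
  expect_identical(nrow(m), 80L)
  expect_lt(max(abs(m$t_half / m$half_life - 1)), 1e-9)
  expect_true(all(m$flag == ""))
})

test_that("per-sample depth changes are absorbed by the calibration", {
  cfg <- sim_config(n_genes = 50L, decay_depth_factors = c(1, 0.5, 2),
                    seed = 5L)
  sim <- simulate_transcriptome(cfg)
  dk <- simulate_decay(sim, noise = FALSE)
  fit <- lifetime_pipeline(dk$counts, dk$ercc_amounts)
  m <- merge(fit, sim$truth[, c("gene_id", "half_life")], by = "gene_id")
  expect_lt(max(abs(m$t_half / m$half_life - 1)), 1e-9)
  # explicit rescale of one sample leaves half-lives unchanged
  sim2 <- simulate_transcriptome(sim_config(n_genes = 50L, seed = 6L))
  dk2 <- simulate_decay(sim2, noise = FALSE)
  base <- lifetime_pipeline(dk2$counts, dk2$ercc_amounts)
  scaled <- data.table::copy(dk2$counts)
  scaled$t3h <- scaled$t3h * 7
  refit <- lifetime_pipeline(scaled, dk2$ercc_amounts)
  expect_equal(refit$t_half, base$t_half, tolerance = 1e-9)
})

test_that("the WT/KO comparison pairs genes and flags unstable fits", {
  sim <- simulate_transcriptome(sim_config(n_genes = 40L, seed = 8L))
  wt <- lifetime_pipeline(simulate_decay(sim, noise = FALSE)$counts,
                          simulate_decay(sim, noise = FALSE)$ercc_amounts)
  ko <- lifetime_pipeline(simulate_decay(sim, noise = FALSE,
                                         condition = "ko")$counts,
                          simulate_decay(sim, noise = FALSE)$ercc_amounts)
  cmp <- lifetime_compare(wt, ko)
  expect_identical(nrow(cmp), 40L)
  # same truth, no noise: no lifetime difference between conditions
  expect_lt(max(abs(cmp$log2_ratio)), 1e-9)
})

test_that("malformed count tables are rejected", {
  sim <- simulate_transcriptome(sim_config(n_genes = 20L, n_peak_genes = 3L,
                                           n_te_genes = 4L, seed = 3L))
  dk <- simulate_decay(sim, noise = FALSE)
  no_spikes <- dk$counts[!startsWith(dk$counts$gene_id, "ERCC-")]
  expect_error(lifetime_pipeline(no_spikes, dk$ercc_amounts), "ERCC")
  missing_tp <- dk$counts[, c("gene_id", "t0h", "t3h"), with = FALSE]
  expect_error(lifetime_pipeline(missing_tp, dk$ercc_amounts), "timepoint")
})
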