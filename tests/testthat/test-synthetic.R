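test_that("generators are byte-deterministic given a seed", {
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  simulate_annotation(10, c(chrS1 = 3e6), seed = 7, gtf_path = f1)
  simulate_annotation(10, c(chrS1 = 3e6), seed = 7, gtf_path = f2)
  expect_identical(readLines(f1), readLines(f2))

  ann <- simulate_annotation(2, c(chrS1 = 2e6), seed = 3)
  m <- select_representative(ann$models[[1L]])
  dens <- occupancy_density(m, occupancy_params(), genome = ann$genome)
  s1 <- simulate_reads(dens, 500, ann$genome, seed = 5)
  s2 <- simulate_reads(dens, 500, ann$genome, seed = 5)
  expect_identical(s1$sam, s2$sam)

  t1 <- simulate_lfq_table(lfq_sim_params(n_background = 50, n_spiked = 5,
                                          seed = 9))
  t2 <- simulate_lfq_table(lfq_sim_params(n_background = 50, n_spiked = 5,
                                          seed = 9))
  expect_identical(t1, t2)
})

test_that("annotation layout respects isolation and gene count", {
  ann <- simulate_annotation(50, c(chrS1 = 8e6, chrS2 = 8e6), seed = 13,
                             isolation_bp = 60000)
  expect_length(ann$models, 50L)
  # no 50 kb downstream window may reach another gene's body
  reps <- lapply(ann$models, select_representative)
  bodies <- data.frame(chrom = vapply(reps, `[[`, character(1), "chrom"),
                       start = vapply(reps, function(m) m$exon_starts[1], 1),
                       end = vapply(reps, function(m) max(m$exon_ends), 1))
  for (i in seq_along(reps)) {
    dn <- derive_regions(reps[[i]], "downstream", genome = ann$genome,
                         length = 50000)
    others <- bodies[-i, , drop = FALSE]
    others <- others[others$chrom == dn$chrom, , drop = FALSE]
    expect_false(any(others$start < dn$end & others$end > dn$start))
  }
  expect_error(simulate_annotation(100, c(chrS1 = 1e6), seed = 1),
               "layout too small")
})

test_that("occupancy density honors weights, tail mass and mirror symmetry", {
  g <- c(c1 = 2e6)
  m <- transcript_model("G", "T", "c1", "+", 500000, 520000)
  # degenerate: body only -> exactly uniform over the gene body
  p_body <- occupancy_params(tss_peak_weight = 0, body_weight = 1,
                             tes_peak_weight = 0, readthrough_weight = 0)
  d <- occupancy_density(m, p_body, genome = g)
  org <- attr(d, "origin")
  body_idx <- (500000 - org + 1):(520000 - org)
  expect_true(all(abs(d[body_idx] - 1 / 20000) < 1e-12))
  expect_true(all(d[-body_idx] == 0))
  expect_equal(sum(d), 1)

  # tail mass fraction equals the readthrough weight (tes peak off)
  p_rt <- occupancy_params(tss_peak_weight = 0.25, body_weight = 0.25,
                           tes_peak_weight = 0, readthrough_weight = 0.5,
                           readthrough_decay = 5000)
  d2 <- occupancy_density(m, p_rt, genome = g)
  tes <- transcript_tes(m)
  beyond <- sum(d2[(tes - attr(d2, "origin") + 2):length(d2)])
  expect_lt(abs(beyond - 0.5), 0.01)

  # minus-strand gene mirrored in the chromosome gives the reversed vector
  L <- 2e6
  mm <- transcript_model("G", "T", "c1", "-", L - 520000, L - 500000)
  dm <- occupancy_density(mm, p_rt, genome = g)
  expect_equal(as.numeric(dm), rev(as.numeric(d2)), tolerance = 1e-12)

  expect_error(occupancy_density(m, p_rt, horizon = 1000), "tail support")
  expect_error(occupancy_params(body_weight = 0.5), "sum to 1")
})

test_that("read counts, modes and the truth table stay consistent", {
  ann <- simulate_annotation(2, c(chrS1 = 2e6), seed = 3)
  m <- select_representative(ann$models[[1L]])
  dens <- occupancy_density(m, occupancy_params(), genome = ann$genome)
  ss <- simulate_reads(dens, 1000, ann$genome, mode = "single", seed = 8)
  sp <- simulate_reads(dens, 1000, ann$genome, mode = "paired", seed = 8)
  expect_equal(nrow(ss$truth), 1000L)
  expect_length(ss$sam, 2 + 1000L)           # header + one record per read
  expect_length(sp$sam, 2 + 2000L)           # header + two mates per pair
  # same seed, same fragments: paired truth equals single truth
  expect_identical(ss$truth, sp$truth)
  # fragment lengths within the insert size range (away from chrom edges)
  expect_true(all(ss$truth$length >= 20 & ss$truth$length <= 90))
  expect_error(simulate_reads(numeric(0), 10, ann$genome), "empty density")
})

test_that("empirical 3'-end distribution converges to the input density", {
  ann <- simulate_annotation(2, c(chrS1 = 2e6), seed = 3)
  m <- select_representative(ann$models[[1L]])
  dens <- occupancy_density(m, occupancy_params(), genome = ann$genome)
  tr <- simulate_reads(dens, 100000, ann$genome, seed = 17)$truth
  # total-variation distance on 50 bp bins
  org <- attr(dens, "origin")
  brk <- seq(org, org + length(dens) + 50, by = 50)
  emp <- hist(tr$pos3, breaks = brk - 0.5, plot = FALSE)$counts
  emp <- emp / sum(emp)
  ref <- vapply(seq_along(emp), function(i) {
    lo <- brk[i] - org + 1; hi <- min(length(dens), brk[i + 1] - org)
    if (lo > length(dens)) 0 else sum(dens[lo:hi])
  }, numeric(1))
  expect_lt(0.5 * sum(abs(emp - ref)), 0.05)
})

test_that("LFQ tables carry the designed structure and missingness", {
  p <- lfq_sim_params(n_background = 800, n_spiked = 40, log2_effect = 3,
                      missing_rate = 0.3, seed = 4)
  tab <- simulate_lfq_table(p)
  expect_equal(nrow(tab), 840L)
  lfq <- as.matrix(tab[, grep("^LFQ", names(tab))])
  expect_equal(ncol(lfq), 12L)
  expect_lt(abs(mean(lfq == 0) - 0.3), 0.02)
  expect_equal(sum(tab$truth_spiked), 40L)

  # zero effect: spiked and background intensity means agree in expectation
  p0 <- lfq_sim_params(n_background = 2000, n_spiked = 2000, log2_effect = 0,
                       missing_rate = 0, seed = 5)
  t0 <- simulate_lfq_table(p0)
  l0 <- log2(as.matrix(t0[, grep("^LFQ", names(t0))]))
  expect_lt(abs(mean(l0[t0$truth_spiked, ]) - mean(l0[!t0$truth_spiked, ])),
            0.2)
  expect_error(simulate_lfq_table(p, groups = "IP"), "at least 2")
})
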