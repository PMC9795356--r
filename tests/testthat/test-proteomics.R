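test_that("protein-group loading maps columns, drops flagged rows, round-trips", {
  tab <- simulate_lfq_table(lfq_sim_params(n_background = 40, n_spiked = 10,
                                           seed = 2))
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  pq <- load_protein_groups(f)
  expect_equal(length(pq$protein_id), 50L)
  expect_equal(unname(pq$intensities[3, 4]),
               tab[[pq$design$column[4]]][3])
  expect_equal(nrow(pq$design), 12L)

  # contaminant- and reverse-flagged rows are excluded
  tab2 <- tab
  tab2$Potential.contaminant[5] <- "+"
  tab2$Reverse[7] <- "+"
  pq2 <- load_protein_groups(tab2)
  expect_equal(length(pq2$protein_id), 48L)
  expect_false(tab$Protein.IDs[5] %in% pq2$protein_id)

  tab3 <- tab[, setdiff(names(tab), "Peptides.r1")]
  expect_error(load_protein_groups(tab3, default_column_map(names(tab))),
               "Peptides.r1")
})

test_that("the combined peptide-count filter is strict and monotone", {
  tab <- simulate_lfq_table(lfq_sim_params(n_background = 30, n_spiked = 0,
                                           seed = 3))
  pq <- load_protein_groups(tab)
  pq$peptide_counts[1, ] <- c(1L, 2L)  # combined exactly 3 -> excluded
  pq$peptide_counts[2, ] <- c(2L, 2L)  # combined 4 -> retained
  kept <- filter_min_peptides(pq, 3)
  expect_false(pq$protein_id[1] %in% kept$protein_id)
  expect_true(pq$protein_id[2] %in% kept$protein_id)

  # all-zero counts: empty output
  pq0 <- pq; pq0$peptide_counts[] <- 0L
  expect_length(filter_min_peptides(pq0, 3)$protein_id, 0L)

  # monotone: lowering the threshold never removes a retained protein
  for (thr in c(10, 5, 3, 1, 0)) {
    hi <- filter_min_peptides(pq, thr + 1)$protein_id
    lo <- filter_min_peptides(pq, thr)$protein_id
    expect_true(all(hi %in% lo))
  }
})

test_that("imputation is a pure log2 transform when nothing is missing", {
  pq <- tiny_protein_quant(c(10, 12, 11), c(5, 6, 7))
  a <- impute_log_intensities(pq, seed = 1)
  b <- impute_log_intensities(pq, seed = 999)
  expect_identical(a$log2, b$log2)
  expect_equal(unname(a$log2[1, ]), c(10, 12, 11, 5, 6, 7))
  expect_false(any(a$imputed))
})

test_that("imputed values follow the down-shifted column distribution", {
  p <- lfq_sim_params(n_background = 1000, n_spiked = 0, missing_rate = 0.3,
                      seed = 21)
  pq <- load_protein_groups(simulate_lfq_table(p))
  pq <- impute_log_intensities(pq, shift = 1.8, width = 0.3, seed = 5)
  for (j in sample(ncol(pq$log2), 3)) {
    obs <- !pq$imputed[, j]
    m <- mean(pq$log2[obs, j]); s <- sd(pq$log2[obs, j])
    imp <- pq$log2[pq$imputed[, j], j]
    expect_lt(abs(mean(imp) - (m - 1.8 * s)), 0.05 * s + 3 * 0.3 * s / sqrt(length(imp)))
  }
  # same seed, same matrix
  again <- impute_log_intensities(
    load_protein_groups(simulate_lfq_table(p)), shift = 1.8, width = 0.3,
    seed = 5)
  expect_identical(pq$log2, again$log2)
  # a column with no observed value cannot be imputed
  broken <- load_protein_groups(simulate_lfq_table(
    lfq_sim_params(n_background = 5, n_spiked = 0, missing_rate = 0, seed = 1)))
  broken$intensities[, 2] <- 0
  expect_error(impute_log_intensities(broken), "no observed values")
})

test_that("the volcano t-test matches the closed-form Student result", {
  pq <- tiny_protein_quant(c(10, 12, 11), c(5, 6, 7))
  pq <- impute_log_intensities(pq, seed = 1)
  res <- enrichment_test(pq, "IP", "control")
  expect_equal(res$log2_diff, 5)
  ref <- t.test(c(10, 12, 11), c(5, 6, 7), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(res$neg_log2_p, -log2(ref$p.value), tolerance = 1e-12)

  # identical groups: zero difference, p = 1
  pq0 <- impute_log_intensities(tiny_protein_quant(c(8, 9, 10), c(8, 9, 10)),
                                seed = 1)
  res0 <- enrichment_test(pq0, "IP", "control")
  expect_equal(res0$log2_diff, 0)
  expect_equal(res0$p_value, 1)

  # permuting injections changes nothing
  pqp <- impute_log_intensities(tiny_protein_quant(c(11, 10, 12), c(6, 7, 5)),
                                seed = 1)
  resp <- enrichment_test(pqp, "IP", "control")
  expect_equal(resp$p_value, res$p_value)
  expect_equal(resp$log2_diff, res$log2_diff)

  # volcano symmetry: swapping sides negates the difference, keeps p
  sw <- enrichment_test(pq, "control", "IP")
  expect_equal(sw$log2_diff, -res$log2_diff)
  expect_equal(sw$p_value, res$p_value)

  # degenerate: zero pooled variance with unequal means is floored and flagged
  pqd <- impute_log_intensities(tiny_protein_quant(c(9, 9, 9), c(5, 5, 5)),
                                seed = 1)
  resd <- enrichment_test(pqd, "IP", "control")
  expect_true(resd$degenerate)
  expect_equal(resd$p_value, .Machine$double.xmin)
})

test_that("enrichment thresholds are strict inequalities on both axes", {
  res <- data.frame(protein_id = c("a", "b", "c", "d"),
                    log2_diff = c(5, 2, 2.1, 5),
                    neg_log2_p = c(3, 3, 2, 2))
  cl <- classify_enriched(res)
  expect_equal(cl$enriched, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("spiked proteins are recovered and the null rate stays nominal", {
  tab <- simulate_lfq_table(lfq_sim_params(n_background = 1000,
                                           n_spiked = 50, log2_effect = 4,
                                           missing_rate = 0.3, seed = 42))
  pq <- impute_log_intensities(filter_min_peptides(load_protein_groups(tab)),
                               seed = 42)
  res <- classify_enriched(enrichment_test(pq, "IP", "control"))
  spiked <- pq$extra$truth_spiked
  expect_gte(mean(res$enriched[spiked]), 0.90)
  expect_lte(mean(res$enriched[!spiked]), 0.05)

  # effect-free null table: joint call rate stays below 5%
  null_tab <- simulate_lfq_table(lfq_sim_params(n_background = 1000,
                                                n_spiked = 0,
                                                missing_rate = 0.3,
                                                seed = 43))
  pqn <- impute_log_intensities(filter_min_peptides(
    load_protein_groups(null_tab)), seed = 43)
  resn <- classify_enriched(enrichment_test(pqn, "IP", "control"))
  expect_lte(mean(resn$enriched), 0.05)
})

test_that("reference comparison keeps every reference-enriched protein", {
  ref <- data.frame(protein_id = c("a", "b", "c"),
                    log2_diff = c(5, 3, 1), neg_log2_p = c(4, 3, 5))
  dbl <- data.frame(protein_id = c("b", "x"),
                    log2_diff = c(2.5, 9), neg_log2_p = c(4, 9))
  cmp <- compare_to_reference(dbl, ref)
  expect_setequal(cmp$protein_id, c("a", "b"))   # "c" fails the fc threshold
  expect_true(is.na(cmp$log2_diff_double[cmp$protein_id == "a"]))
  expect_false(cmp$in_double[cmp$protein_id == "a"])
  expect_equal(cmp$log2_diff_double[cmp$protein_id == "b"], 2.5)

  none <- data.frame(protein_id = "z", log2_diff = 0, neg_log2_p = 0)
  expect_error(compare_to_reference(dbl, none), "no enriched")

  # join equals brute-force intersection + lookup on random tables
  set.seed(31)
  ids <- sprintf("Q%03d", 1:200)
  rref <- data.frame(protein_id = sample(ids, 120),
                     log2_diff = rnorm(120, 2, 2),
                     neg_log2_p = rexp(120, 0.3))
  rdbl <- data.frame(protein_id = sample(ids, 100),
                     log2_diff = rnorm(100, 2, 2),
                     neg_log2_p = rexp(100, 0.3))
  cmp2 <- compare_to_reference(rdbl, rref)
  ref_enr <- rref$protein_id[rref$log2_diff > 2 & rref$neg_log2_p > 2]
  expect_setequal(cmp2$protein_id, ref_enr)
  for (id in intersect(ref_enr, rdbl$protein_id)) {
    expect_equal(cmp2$log2_diff_double[cmp2$protein_id == id],
                 rdbl$log2_diff[rdbl$protein_id == id])
  }
})
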