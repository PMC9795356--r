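test_that("GTF coordinates convert to 0-based half-open and group by gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "tA1"; gene_biotype "protein_coding";'),
    paste0("chr2\tsrc\texon\t11\t50\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "tB1"; gene_biotype "protein_coding";'),
    paste0("chr2\tsrc\texon\t11\t90\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "tB2"; gene_biotype "protein_coding";')
  ), gtf)
  models <- parse_gene_models(gtf)
  expect_named(models, c("gA", "gB"))
  expect_length(models$gB, 2L)
  m <- models$gA[[1L]]
  expect_equal(m$exon_starts, 100)
  expect_equal(m$exon_ends, 200)
  expect_equal(m$strand, "+")
})

test_that("non-requested biotypes and off-whitelist chromosomes are dropped", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "tA"; gene_biotype "lincRNA";'),
    paste0("chrM\tsrc\texon\t1\t100\t.\t+\t.\t",
           'gene_id "gM"; transcript_id "tM"; gene_biotype "protein_coding";'),
    paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\t",
           'gene_id "gC"; transcript_id "tC"; gene_biotype "protein_coding";')
  ), gtf)
  models <- parse_gene_models(gtf, chromosomes = "chr1")
  expect_named(models, "gC")
})

test_that("synthetic annotation round-trips through the GTF writer", {
  ann <- simulate_annotation(50, c(chrS1 = 6e6, chrS2 = 6e6), seed = 21)
  f <- tempfile(fileext = ".gtf")
  write_gene_models(ann$models, f)
  back <- parse_gene_models(f)
  expect_length(back, 50L)
  expect_setequal(names(back), names(ann$models))
  for (g in names(ann$models)) {
    orig <- ann$models[[g]]
    names(orig) <- vapply(orig, `[[`, character(1), "transcript_id")
    rec <- back[[g]]
    names(rec) <- vapply(rec, `[[`, character(1), "transcript_id")
    for (tx in names(orig)) expect_equal(rec[[tx]], orig[[tx]])
  }
})

test_that("representative selection follows support, then width, then id", {
  t1 <- tiny_model(support = 1L, tx = "T1")
  t2 <- tiny_model(support = 2L, tx = "T2")
  expect_equal(select_representative(list(t1, t2))$transcript_id, "T1")

  # equal support: widest wins
  narrow <- tiny_model(support = 1L, tx = "T1", start = 100000, end = 105000)
  wide <- tiny_model(support = 1L, tx = "T2", start = 100000, end = 108000)
  expect_equal(select_representative(list(narrow, wide))$transcript_id, "T2")

  # missing support ranks worst, after level 5
  t5 <- tiny_model(support = 5L, tx = "T5")
  tn <- tiny_model(support = NA, tx = "T0", start = 100000, end = 150000)
  expect_equal(select_representative(list(tn, t5))$transcript_id, "T5")

  expect_error(select_representative(list()), "no transcripts")
})

test_that("representative choice equals the brute-force comparator on random genes", {
  set.seed(404)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    sup <- sample(c(1:5, NA), k, replace = TRUE)
    w <- sample(seq(6000, 14000, by = 1000), k, replace = TRUE)
    txs <- lapply(seq_len(k), function(j) {
      tiny_model(support = sup[j], tx = sprintf("T%02d", sample(100, 1)),
                 start = 100000, end = 100000 + w[j])
    })
    sup_eff <- ifelse(is.na(sup), 6L, sup)
    ids <- vapply(txs, `[[`, character(1), "transcript_id")
    brute <- ids[order(sup_eff, -w, ids, method = "radix")[1L]]
    expect_equal(select_representative(txs)$transcript_id, brute)
    # pure function: permuting the input never changes the result
    perm <- sample(k)
    expect_equal(select_representative(txs[perm])$transcript_id, brute)
  }
})

test_that("derived regions are strand-aware and clamped at chromosome bounds", {
  g <- c(c1 = 30000)
  plus <- transcript_model("G", "T", "c1", "+", 2000, 10000)
  dn <- derive_regions(plus, "downstream", genome = g, length = 50000)
  expect_equal(c(dn$start, dn$end), c(10000, 30000))  # clamped at 30 kb
  expect_true(dn$clamped)

  minus <- transcript_model("G", "T", "c1", "-", 10000, 20000)
  dnm <- derive_regions(minus, "downstream", genome = g, length = 50000)
  expect_equal(c(dnm$start, dnm$end), c(0, 10000))    # clamped at 0
  expect_true(dnm$clamped)

  tw <- derive_regions(plus, "tes_window", genome = g, flank = 5000)
  expect_equal(c(tw$start, tw$end), c(9999 - 5000, 9999 + 5000))

  le <- derive_regions(minus, "last_exon")
  expect_equal(c(le$start, le$end), c(10000, 20000))

  expect_error(derive_regions(plus, "no_such_scheme"), "unknown region")
  edge <- transcript_model("G", "T", "c1", "+", 29000, 30000)
  expect_error(derive_regions(edge, "downstream", genome = g, length = 50000),
               "off-chromosome")
})

test_that("downstream and last-exon regions never overlap the body upstream of the TES", {
  ann <- simulate_annotation(20, c(chrS1 = 4e6), seed = 9)
  for (g in ann$models) {
    m <- select_representative(g)
    dn <- derive_regions(m, "downstream", genome = ann$genome, length = 50000)
    tes <- transcript_tes(m)
    if (m$strand == "+") expect_gte(dn$start, tes + 1)
    else expect_lte(dn$end, tes)
  }
})

test_that("mirror-reflecting a transcript mirrors every derived region", {
  L <- 1e6; g <- c(c1 = L)
  m <- transcript_model("G", "T", "c1", "+",
                        c(200000, 214000), c(205000, 216000))
  mm <- transcript_model("G", "T", "c1", "-",
                         L - rev(c(205000, 216000)), L - rev(c(200000, 214000)))
  for (scheme in c("last_exon", "body", "downstream", "tes_window")) {
    r <- derive_regions(m, scheme, genome = g)
    r2 <- derive_regions(mm, scheme, genome = g)
    expect_equal(c(r2$start, r2$end), c(L - r$end, L - r$start),
                 info = scheme)
  }
})
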