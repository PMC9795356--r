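# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

tiny_genome <- function() c(c1 = 1e6, c2 = 1e6)

# a transcript with two exons on the requested strand
tiny_model <- function(strand = "+", gene = "G1", tx = "G1.T1",
                       chrom = "c1", start = 100000, end = 120000,
                       support = 1L) {
  transcript_model(gene, tx, chrom, strand,
                   exon_starts = c(start, end - 2000),
                   exon_ends = c(start + 3000, end),
                   support_level = support)
}

# SNR events -> strand pair of tracks, directly
events_df <- function(chrom, pos, strand, weight = 1L) {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             strand = rep_len(strand, length(pos)),
             weight = rep_len(weight, length(pos)),
             stringsAsFactors = FALSE)
}

# simulate one gene set and return its pooled truth-level SNR events
simulate_gene_set_events <- function(models, genome, readthrough_weight,
                                     n_reads_per_gene, seed0) {
  evs <- lapply(seq_along(models), function(i) {
    m <- select_representative(models[[i]])
    p <- occupancy_params(tss_peak_weight = 0.25, body_weight = 0.35,
                          tes_peak_weight = 0.4 - readthrough_weight,
                          readthrough_weight = readthrough_weight)
    dens <- occupancy_density(m, p, genome = genome)
    tr <- simulate_reads(dens, n_reads_per_gene, genome, mode = "single",
                         seed = seed0 + i)$truth
    events_df(tr$chrom, tr$pos3, tr$strand)
  })
  do.call(rbind, evs)
}

# independent exhaustive two-sided rank-sum p-value (small n, midranks)
enum_ranksum_p <- function(a, b) {
  v <- c(a, b); n1 <- length(a); r <- rank(v)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(length(v), n1)
  Ws <- apply(cmb, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# minimal protein_quant built in code (3 injections x 1 replicate per side)
tiny_protein_quant <- function(test_log2, control_log2, id = "P1") {
  cols <- sprintf("LFQ.intensity.%s_r1_i%d",
                  rep(c("IP", "control"), each = 3), rep(1:3, 2))
  structure(list(
    protein_id = id, gene_name = NULL,
    peptide_counts = matrix(c(5L, 5L), 1, dimnames = list(NULL,
      c("Peptides.r1", "Peptides.r2"))),
    intensities = matrix(2^c(test_log2, control_log2), 1,
                         dimnames = list(NULL, cols)),
    design = data.frame(column = cols,
                        condition = rep(c("IP", "control"), each = 3),
                        replicate = 1L, injection = rep(1:3, 2),
                        stringsAsFactors = FALSE),
    extra = NULL
  ), class = "protein_quant")
}
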