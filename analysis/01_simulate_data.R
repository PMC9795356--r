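#!/usr/bin/env Rscript
# Step 1: build the synthetic study inputs.
#
# Generates a gene annotation with isolated genes (so 50 kb downstream
# windows never touch a neighbor), one single-end nascent-transcription
# sample with realistic nuisance (duplicates, multimappers), a paired-end
# counterpart of the same fragments, and a label-free IP-MS protein-group
# table with spiked RNAPII interactors. Everything is seed-fixed; truth
# tables accompany each file.

suppressPackageStartupMessages(library(netprof))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

seed <- 2024

ann <- simulate_annotation(
  n_genes = 12, chrom_lengths = c(chrS1 = 4e6, chrS2 = 4e6), seed = seed,
  gtf_path = "results/data/annotation.gtf",
  sizes_path = "results/data/chrom.sizes"
)
message("placed ", length(ann$models), " genes on ",
        length(ann$genome), " chromosomes")

# one occupancy density per gene: pausing at the TSS, uniform body, TES
# peak, exponential readthrough tail
sims <- lapply(seq_along(ann$models), function(i) {
  m <- select_representative(ann$models[[i]])
  dens <- occupancy_density(m, occupancy_params(), genome = ann$genome)
  simulate_reads(dens, 2000, ann$genome, mode = "single",
                 duplicate_rate = 0.15, multimapper_rate = 0.08,
                 seed = seed + i)
})
hdr <- sims[[1]]$sam[seq_len(1 + length(ann$genome))]
body <- unlist(lapply(sims, function(s) s$sam[-seq_len(1 + length(ann$genome))]))
f <- vapply(strsplit(body, "\t"), function(x) c(x[3], x[4]), character(2))
ord <- order(f[1, ], as.integer(f[2, ]))
writeLines(c(hdr, body[ord]), "results/data/sample_single.sam")
truth <- do.call(rbind, lapply(seq_along(sims), function(i) {
  cbind(gene = names(ann$models)[i], sims[[i]]$truth)
}))
write.table(truth, "results/data/sample_single.truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", length(body), " SAM records (", nrow(truth), " fragments)")

lfq <- simulate_lfq_table(
  lfq_sim_params(n_background = 1000, n_spiked = 50, log2_effect = 4,
                 missing_rate = 0.3, seed = seed),
  path = "results/data/protein_groups.tsv"
)
message("wrote LFQ table: ", nrow(lfq), " protein groups, ",
        sum(lfq$truth_spiked), " spiked")
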