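#!/usr/bin/env Rscript
# Step 3: density-scaled profiles.
#
# Metagene (5 kb flanks / 100 bp bins / body scaled to 15 kb => 250 bins)
# and TES-anchored (+/- 5 kb, 100 bp bins => 100 bins) profiles of the
# SNR tracks built in step 2, each density-scaled so the area under the
# curve is 1.

suppressPackageStartupMessages(library(netprof))

genome <- read_chrom_sizes("results/data/chrom.sizes")
pair <- list(
  "+" = read_track("results/data/snr_fwd.bedgraph", genome, "+", "snr"),
  "-" = read_track("results/data/snr_rev.bedgraph", genome, "-", "snr")
)
models <- parse_gene_models("results/data/annotation.gtf")
reps <- lapply(models, select_representative)

meta <- profile_matrix(pair, reps, bin_scheme("scale_regions", 5000, 100,
                                              15000), "synthetic_IP")
meta_prof <- density_scale(aggregate_matrix(meta))
write.table(data.frame(bin = seq_along(meta_prof),
                       density = as.numeric(meta_prof)),
            "results/metagene_density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

anchors <- data.frame(
  chrom = vapply(reps, `[[`, character(1), "chrom"),
  pos = vapply(reps, transcript_tes, numeric(1)),
  strand = vapply(reps, `[[`, character(1), "strand"),
  id = names(reps)
)
tes <- profile_matrix(pair, anchors, bin_scheme("point_window", 5000, 100),
                      "synthetic_IP")
tes_prof <- density_scale(aggregate_matrix(tes))
write.table(data.frame(bin = seq_along(tes_prof),
                       density = as.numeric(tes_prof)),
            "results/tes_density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("metagene: ", length(meta_prof), " bins, peak at bin ",
        which.max(meta_prof), "; TES window: ", length(tes_prof),
        " bins, peak at bin ", which.max(tes_prof))
message("both profiles sum to ",
        format(sum(meta_prof)), " / ", format(sum(tes_prof)))
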