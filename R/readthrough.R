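# Per-gene readthrough quantification: RPK in the 50 kb downstream of the
# most distal TES relative to RPK in the last exon, and rank-based
# comparison of ratio distributions.

#' Reads per kilobase of an interval on a strand pair of SNR tracks
#'
#' Counts the sense-strand event mass inside the interval (both strands
#' for strand `"."`) and divides by the interval length in kb. Linear in
#' the track, so global depth scaling cancels in any ratio of RPKs.
#'
#' @param track_pair Named list of `cov_track` (`"+"`, `"-"`).
#' @param region A `genomic_interval`.
#' @return Reads per kilobase (numeric).
#' @export
region_rpk <- function(track_pair, region) {
  len <- interval_width(region)
  if (len <= 0) stop("zero-length region")
  tr <- sense_track(track_pair, region$strand)
  v <- window_values(tr, region$chrom, region$start, region$end)
  sum(v) / (len / 1000)
}

most_distal_tes <- function(transcripts) {
  strand <- transcripts[[1L]]$strand
  if (strand == "+") max(vapply(transcripts, function(m) tx_end(m) - 1,
                                numeric(1L)))
  else min(vapply(transcripts, tx_start, numeric(1L)))
}

#' Readthrough ratio of one gene
#'
#' Ratio of SNR read density (RPK) in the window downstream of the most
#' distal TES to the density in the representative transcript's last
#' exon. Genes with last-exon density 0 cannot form a finite ratio: with
#' downstream signal present the result is flagged `infinite_dropped`,
#' with none `empty_dropped`; both are excluded from downstream
#' statistics.
#'
#' @param track_pair Named list of SNR `cov_track`.
#' @param model Representative `transcript_model` of the gene.
#' @param genome Named chromosome lengths.
#' @param downstream_bp Downstream window length, bp (default 50000).
#' @param distal_tes Optional 0-based most distal TES base (from all of
#'   the gene's transcripts); default: the model's own TES.
#' @return One-row data.frame: gene_id, rpk_downstream, rpk_last_exon,
#'   ratio, status.
#' @export
readthrough_ratio <- function(track_pair, model, genome,
                              downstream_bp = 50000, distal_tes = NULL) {
  dn <- derive_regions(model, "downstream", genome = genome,
                       length = downstream_bp, tes = distal_tes)
  le <- derive_regions(model, "last_exon", genome = genome)
  rpk_dn <- region_rpk(track_pair, dn)
  rpk_le <- region_rpk(track_pair, le)
  if (rpk_le > 0) {
    status <- "ok"; ratio <- rpk_dn / rpk_le
  } else if (rpk_dn > 0) {
    status <- "infinite_dropped"; ratio <- NA_real_
  } else {
    status <- "empty_dropped"; ratio <- NA_real_
  }
  data.frame(gene_id = model$gene_id, rpk_downstream = rpk_dn,
             rpk_last_exon = rpk_le, ratio = ratio, status = status,
             stringsAsFactors = FALSE)
}

#' Readthrough ratios for a gene-model collection
#'
#' Selects the representative transcript per gene, anchors the downstream
#' window at the gene's most distal TES, and flags genes whose downstream
#' window overlaps another gene's body (kept by default; such signal may
#' belong to the neighbor rather than to readthrough).
#'
#' @param track_pair Named list of SNR `cov_track`.
#' @param models Gene-grouped models, as from [parse_gene_models()].
#' @param genome Named chromosome lengths.
#' @param downstream_bp Downstream window length, bp.
#' @param gene_ids Optional restriction to a gene-id subset.
#' @param exclude_overlapping Drop neighbor-overlap-flagged genes.
#' @return data.frame with one row per gene (columns as in
#'   [readthrough_ratio()] plus `neighbor_overlap`).
#' @export
readthrough_table <- function(track_pair, models, genome,
                              downstream_bp = 50000, gene_ids = NULL,
                              exclude_overlapping = FALSE) {
  if (!is.null(gene_ids)) models <- models[names(models) %in% gene_ids]
  reps <- lapply(models, select_representative)
  bodies <- data.frame(
    chrom = vapply(reps, `[[`, character(1L), "chrom"),
    start = vapply(reps, tx_start, numeric(1L)),
    end = vapply(reps, tx_end, numeric(1L)),
    gene = names(models), stringsAsFactors = FALSE
  )
  rows <- lapply(seq_along(models), function(i) {
    m <- reps[[i]]
    r <- readthrough_ratio(track_pair, m, genome, downstream_bp,
                           distal_tes = most_distal_tes(models[[i]]))
    dn <- derive_regions(m, "downstream", genome = genome,
                         length = downstream_bp,
                         tes = most_distal_tes(models[[i]]))
    other <- bodies[bodies$gene != m$gene_id & bodies$chrom == dn$chrom, ,
                    drop = FALSE]
    r$neighbor_overlap <- any(other$start < dn$end & other$end > dn$start)
    r
  })
  out <- do.call(rbind, rows)
  if (exclude_overlapping) out <- out[!out$neighbor_overlap, , drop = FALSE]
  out
}

#' Compare two groups of readthrough ratios
#'
#' Two-sided Wilcoxon test: rank-sum (Mann-Whitney) for independent
#' groups, signed-rank for gene-matched pairs. Ties are midranked; the
#' exact distribution is used at small n without ties, the normal
#' approximation with continuity correction otherwise (stats::wilcox.test
#' defaults).
#'
#' @param ratios_a,ratios_b Numeric ratio vectors (NA dropped).
#' @param paired Use the signed-rank test on matched vectors.
#' @return List: statistic, p_value, method, n_a, n_b.
#' @export
compare_groups <- function(ratios_a, ratios_b, paired = FALSE) {
  if (paired) {
    if (length(ratios_a) != length(ratios_b)) {
      stop("paired comparison needs equal-length, gene-matched vectors")
    }
    ok <- !is.na(ratios_a) & !is.na(ratios_b)
    ratios_a <- ratios_a[ok]; ratios_b <- ratios_b[ok]
  } else {
    ratios_a <- ratios_a[!is.na(ratios_a)]
    ratios_b <- ratios_b[!is.na(ratios_b)]
  }
  if (length(ratios_a) < 3L || length(ratios_b) < 3L) {
    stop("need at least 3 usable ratios per group")
  }
  n1 <- length(ratios_a); n2 <- length(ratios_b)
  if (!paired && n1 + n2 <= 12L) {
    # exact two-sided rank-sum by full enumeration of the group
    # assignments, on midranks, so ties are handled exactly at small n
    r <- rank(c(ratios_a, ratios_b))
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    Ws <- apply(utils::combn(n1 + n2, n1), 2L,
                function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
    return(list(statistic = W, p_value = p,
                method = "Exact Wilcoxon rank sum test (enumeration)",
                n_a = n1, n_b = n2))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(ratios_a, ratios_b, paired = paired,
                       alternative = "two.sided")
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method, n_a = n1, n_b = n2)
}
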