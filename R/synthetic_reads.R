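# Seed-deterministic generators for annotation and aligned nascent-RNA
# reads, with truth tables sufficient to score every downstream stage.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Polymerase occupancy-shape parameters
#'
#' Mixture weights and scales describing where nascent-RNA 3' ends (i.e.
#' RNAPII positions) fall along a gene: a Gaussian pause peak just
#' downstream of the TSS, a uniform gene-body component, a Gaussian peak at
#' the TES, an exponential readthrough tail beyond the TES, and an optional
#' Gaussian bump at an intronic polyA site. Weights must be non-negative
#' and sum to 1.
#'
#' @param tss_peak_weight,body_weight,tes_peak_weight,readthrough_weight,intronic_pa_weight
#'   Mixture fractions (sum to 1).
#' @param tss_peak_sd,tes_peak_sd,intronic_pa_sd Gaussian widths in bp.
#' @param tss_peak_offset Pause-peak center, bp downstream of the TSS.
#' @param readthrough_decay Mean of the exponential tail beyond the TES, bp.
#' @param intronic_pa_position Optional bp offset of an intronic polyA site
#'   from the TSS (transcription direction), or `NULL`.
#' @return A list of class `occupancy_params`.
#' @export
occupancy_params <- function(tss_peak_weight = 0.25, tss_peak_sd = 150,
                             tss_peak_offset = 50,
                             body_weight = 0.30,
                             tes_peak_weight = 0.20, tes_peak_sd = 150,
                             readthrough_weight = 0.25,
                             readthrough_decay = 5000,
                             intronic_pa_position = NULL,
                             intronic_pa_weight = 0, intronic_pa_sd = 200) {
  w <- c(tss_peak_weight, body_weight, tes_peak_weight, readthrough_weight,
         intronic_pa_weight)
  if (any(w < 0)) stop("occupancy weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("occupancy weights must sum to 1, got ", sum(w))
  if (readthrough_decay <= 0) stop("readthrough_decay must be > 0")
  if (tss_peak_sd <= 0 || tes_peak_sd <= 0 || intronic_pa_sd <= 0) {
    stop("Gaussian sds must be > 0")
  }
  structure(list(
    tss_peak_weight = tss_peak_weight, tss_peak_sd = tss_peak_sd,
    tss_peak_offset = tss_peak_offset, body_weight = body_weight,
    tes_peak_weight = tes_peak_weight, tes_peak_sd = tes_peak_sd,
    readthrough_weight = readthrough_weight,
    readthrough_decay = readthrough_decay,
    intronic_pa_position = intronic_pa_position,
    intronic_pa_weight = intronic_pa_weight, intronic_pa_sd = intronic_pa_sd
  ), class = "occupancy_params")
}

#' Per-bp occupancy density for one gene
#'
#' Builds the per-base probability vector of nascent 3'-end positions over
#' the window from `upstream` bp before the TSS to `horizon` bp beyond the
#' TES. Each mixture component is discretely normalized to its weight over
#' its support, so the vector sums to exactly 1 and the mass fraction
#' beyond the TES carried by the tail equals `readthrough_weight`.
#' The vector is stored in genomic coordinate order with attributes
#' `chrom`, `origin` (0-based position of element 1) and `strand`; for a
#' minus-strand gene the shape is the mirror image of the plus-strand case.
#'
#' @param model A `transcript_model`.
#' @param params An `occupancy_params`.
#' @param upstream Window extent upstream of the TSS, bp.
#' @param horizon Window extent beyond the TES, bp; must cover at least
#'   three tail decay lengths when the tail has weight.
#' @param genome Optional named chromosome lengths (window is clamped).
#' @return Numeric density vector with attributes; sums to 1.
#' @export
occupancy_density <- function(model, params, upstream = 5000,
                              horizon = 5 * params$readthrough_decay,
                              genome = NULL) {
  if (params$readthrough_weight > 0 && horizon < 3 * params$readthrough_decay) {
    stop("horizon (", horizon, " bp) shorter than tail support (3 decay lengths)")
  }
  L <- transcript_width(model)
  n <- upstream + L + horizon
  # transcription coordinates: u = 0 at the TSS base, increasing 5'->3'
  u <- seq_len(n) - 1 - upstream
  comp <- function(d, w) if (w > 0 && sum(d) > 0) w * d / sum(d) else numeric(n) * 0

  dens <- comp(stats::dnorm(u, mean = params$tss_peak_offset,
                            sd = params$tss_peak_sd), params$tss_peak_weight)
  dens <- dens + comp(as.numeric(u >= 0 & u < L), params$body_weight)
  dens <- dens + comp(stats::dnorm(u, mean = L - 1, sd = params$tes_peak_sd),
                      params$tes_peak_weight)
  tail_pdf <- ifelse(u > L - 1, exp(-(u - (L - 1)) / params$readthrough_decay), 0)
  dens <- dens + comp(tail_pdf, params$readthrough_weight)
  if (!is.null(params$intronic_pa_position) && params$intronic_pa_weight > 0) {
    dens <- dens + comp(stats::dnorm(u, mean = params$intronic_pa_position,
                                     sd = params$intronic_pa_sd),
                        params$intronic_pa_weight)
  }
  dens <- dens / sum(dens)

  if (model$strand == "+") {
    origin <- transcript_tss(model) - upstream
  } else {
    dens <- rev(dens)
    origin <- transcript_tes(model) - horizon
  }
  if (origin < 0) {
    dens <- dens[(1 - origin):n]; dens <- dens / sum(dens); origin <- 0
  }
  if (!is.null(genome)) {
    cl <- unname(genome[[model$chrom]])
    if (origin + length(dens) > cl) {
      dens <- dens[seq_len(cl - origin)]; dens <- dens / sum(dens)
    }
  }
  attr(dens, "chrom") <- model$chrom
  attr(dens, "origin") <- origin
  attr(dens, "strand") <- model$strand
  dens
}

#' Simulate a gene annotation and matching chromosome-sizes table
#'
#' Places genes sequentially along the supplied chromosomes, on random
#' strands, each with 1-3 transcripts of varying support level. With
#' `isolation_bp` set, consecutive genes are separated by at least that
#' many bp so downstream readthrough windows never reach a neighboring
#' gene body. Deterministic given `seed`.
#'
#' @param n_genes Number of genes to place.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param seed Integer seed.
#' @param gene_length_range Min/max gene span, bp.
#' @param isolation_bp Minimum intergenic gap, bp (also the start/end
#'   margin). Use at least the downstream window plus flanks when derived
#'   regions must not collide.
#' @param gtf_path,sizes_path Optional output paths; when given, the GTF
#'   and chromosome-sizes files are written.
#' @return List with `models` (as from [parse_gene_models()]) and `genome`.
#' @export
simulate_annotation <- function(n_genes, chrom_lengths, seed = 1,
                                gene_length_range = c(8000, 30000),
                                isolation_bp = 60000,
                                gtf_path = NULL, sizes_path = NULL) {
  stopifnot(n_genes >= 1, length(chrom_lengths) >= 1)
  models <- with_seed(seed, {
    out <- list()
    g <- 0L
    for (ci in seq_along(chrom_lengths)) {
      chrom <- names(chrom_lengths)[ci]
      cl <- chrom_lengths[[ci]]
      cursor <- isolation_bp
      repeat {
        if (g >= n_genes) break
        glen <- round(runif(1, gene_length_range[1], gene_length_range[2]))
        if (cursor + glen + isolation_bp > cl) break
        g <- g + 1L
        gid <- sprintf("G%04d", g)
        strand <- sample(c("+", "-"), 1L)
        gstart <- cursor
        gend <- gstart + glen
        n_tx <- sample(1:3, 1L)
        sup <- sample(1:5, n_tx, replace = TRUE)
        if (n_tx > 1 && runif(1) < 0.3) sup[n_tx] <- NA_integer_
        txs <- vector("list", n_tx)
        for (t in seq_len(n_tx)) {
          # transcript 1 spans the gene; later ones are nested truncations
          if (t == 1L) { ts <- gstart; te <- gend } else {
            shrink <- round(runif(2, 0, 0.2 * glen))
            ts <- gstart + shrink[1]; te <- gend - shrink[2]
          }
          n_ex <- sample(1:3, 1L)
          if (n_ex == 1L) { es <- ts; ee <- te } else {
            # interior exon boundaries; last exon kept >= 1 kb where possible
            cuts <- sort(round(runif(2 * (n_ex - 1), ts + 200, te - 1200)))
            es <- c(ts, cuts[seq(2, length(cuts), by = 2)])
            ee <- c(cuts[seq(1, length(cuts), by = 2)], te)
            if (any(es >= ee) || any(es[-1] <= ee[-n_ex])) { es <- ts; ee <- te }
          }
          txs[[t]] <- transcript_model(
            gene_id = gid, transcript_id = sprintf("%s.T%d", gid, t),
            chrom = chrom, strand = strand,
            exon_starts = es, exon_ends = ee,
            support_level = sup[t]
          )
        }
        out[[gid]] <- txs
        cursor <- gend + isolation_bp
      }
      if (g >= n_genes) break
    }
    if (g < n_genes) {
      stop("chromosome layout too small: placed ", g, " of ", n_genes, " genes")
    }
    out
  })
  genome <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  if (!is.null(gtf_path)) write_gene_models(models, gtf_path)
  if (!is.null(sizes_path)) write_chrom_sizes(genome, sizes_path)
  list(models = models, genome = genome)
}

sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome)))
}

#' Simulate aligned nascent-RNA reads from an occupancy density
#'
#' Samples fragment 3' ends from the density, draws fragment lengths
#' uniformly from `fragment_length_range`, and emits coordinate-sorted SAM
#' text plus a plain-TSV truth table. In `single` mode one record per
#' fragment is written on the nascent-RNA strand. In `paired` mode an
#' FR pair is written: mate 1 on the nascent strand covering the fragment,
#' mate 2 on the opposite strand with its 5' end at the fragment 3' end.
#' Duplicates are exact coordinate copies of earlier fragments;
#' multimappers carry an `NH` tag > 1 (and MAPQ 0) on their single primary
#' record. Fragment sampling is independent of `mode`, so the truth table
#' for a given seed is identical across modes.
#'
#' @param density Density vector from [occupancy_density()].
#' @param n_reads Number of fragments.
#' @param genome Named chromosome lengths (for the SAM header).
#' @param mode `"single"` or `"paired"`.
#' @param duplicate_rate,multimapper_rate,improper_rate Nuisance fractions.
#' @param fragment_length_range Fragment length bounds, bp (default 20-90).
#' @param seed Integer seed.
#' @param sam_path,truth_path Optional output paths.
#' @return Invisible list with `sam` (character lines) and `truth`
#'   (data.frame: fragment_id, chrom, pos3, strand, start, end, length,
#'   is_duplicate, source_id, nh, proper).
#' @export
simulate_reads <- function(density, n_reads, genome,
                           mode = c("single", "paired"),
                           duplicate_rate = 0, multimapper_rate = 0,
                           improper_rate = 0,
                           fragment_length_range = c(20, 90), seed = 1,
                           sam_path = NULL, truth_path = NULL) {
  mode <- match.arg(mode)
  if (length(density) == 0L || sum(density) == 0) stop("empty density")
  chrom <- attr(density, "chrom"); origin <- attr(density, "origin")
  strand <- attr(density, "strand")
  cl <- unname(genome[[chrom]])

  truth <- with_seed(seed, {
    pos3 <- origin + sample.int(length(density), n_reads, replace = TRUE,
                                prob = density) - 1
    len <- round(runif(n_reads, fragment_length_range[1], fragment_length_range[2]))
    dup <- runif(n_reads) < duplicate_rate
    dup[1L] <- FALSE
    src <- rep(NA_integer_, n_reads)
    for (i in which(dup)) {
      j <- sample.int(i - 1L, 1L)
      src[i] <- j; pos3[i] <- pos3[j]; len[i] <- len[j]
    }
    nh <- ifelse(runif(n_reads) < multimapper_rate,
                 sample(2:5, n_reads, replace = TRUE), 1L)
    proper <- runif(n_reads) >= improper_rate
    if (strand == "+") {
      start <- pmax(0, pos3 - len + 1); end <- pos3 + 1
    } else {
      start <- pos3; end <- pmin(cl, pos3 + len)
    }
    data.frame(
      fragment_id = sprintf("f%06d", seq_len(n_reads)),
      chrom = chrom, pos3 = pos3, strand = strand,
      start = start, end = end, length = end - start,
      is_duplicate = dup, source_id = src, nh = nh, proper = proper,
      stringsAsFactors = FALSE
    )
  })

  nh_tag <- sprintf("NH:i:%d", truth$nh)
  mapq <- ifelse(truth$nh > 1L, 0L, 60L)
  cig <- sprintf("%dM", truth$length)
  if (mode == "single") {
    flag <- ifelse(truth$strand == "+", 0L, 16L)
    rec <- data.frame(
      qname = truth$fragment_id, flag = flag, pos = truth$start + 1L,
      mapq = mapq, cigar = cig, rnext = "*", pnext = 0L, tlen = 0L,
      tag = nh_tag, stringsAsFactors = FALSE
    )
  } else {
    proper_bit <- ifelse(truth$proper, 2L, 0L)
    plus <- truth$strand == "+"
    # FR pair: mate1 on the nascent strand, mate2 reversed at the 3' end
    f1 <- ifelse(plus, 1L + 32L + 64L, 1L + 16L + 64L) + proper_bit
    f2 <- ifelse(plus, 1L + 16L + 128L, 1L + 32L + 128L) + proper_bit
    r1 <- data.frame(qname = truth$fragment_id, flag = f1,
                     pos = truth$start + 1L, mapq = mapq, cigar = cig,
                     rnext = "=", pnext = truth$start + 1L,
                     tlen = ifelse(plus, truth$length, -truth$length),
                     tag = nh_tag, stringsAsFactors = FALSE)
    r2 <- data.frame(qname = truth$fragment_id, flag = f2,
                     pos = truth$start + 1L, mapq = mapq, cigar = cig,
                     rnext = "=", pnext = truth$start + 1L,
                     tlen = ifelse(plus, -truth$length, truth$length),
                     tag = nh_tag, stringsAsFactors = FALSE)
    rec <- rbind(r1, r2)
  }
  rec <- rec[order(rec$pos, rec$qname, rec$flag), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*\t%s",
                  rec$qname, rec$flag, chrom, rec$pos, rec$mapq, rec$cigar,
                  rec$rnext, rec$pnext, rec$tlen, rec$tag)
  sam <- c(sam_header(genome), body)
  if (!is.null(sam_path)) writeLines(sam, sam_path)
  if (!is.null(truth_path)) {
    write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(sam = sam, truth = truth))
}
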