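#' @importFrom stats approx rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# All internal coordinates are 0-based half-open ([start, end)), the BED
# convention; GTF input/output converts at the boundary (1-based inclusive).

#' Genomic interval
#'
#' A minimal validated interval: chromosome, 0-based half-open coordinates,
#' and strand. Used for all derived analysis regions (last exons, TES
#' windows, downstream readthrough regions, anchored point windows).
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param clamped Logical; whether the interval was truncated at a
#'   chromosome boundary during derivation.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".", clamped = FALSE) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be one of '+', '-', '.', got: ", strand)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end)) {
    stop(sprintf("invalid interval [%s, %s): need 0 <= start < end", start, end))
  }
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         strand = strand, clamped = isTRUE(clamped)),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d, %d) %s%s\n", x$chrom, x$start, x$end,
              x$strand, if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Transcript model
#'
#' One transcript of one gene: an ordered set of exons on a single
#' chromosome and strand, plus the annotation support level used for
#' representative-transcript selection. TSS and TES are strand-aware
#' (TSS is the 5'-most transcribed base).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Parallel numeric vectors, 0-based half-open,
#'   sorted in genomic order and non-overlapping.
#' @param support_level Integer rank (lower = better supported), or `NA`.
#' @param biotype Category label, e.g. `"protein_coding"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exon_starts, exon_ends,
                             support_level = NA_integer_,
                             biotype = "protein_coding") {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1L)
  if (!strand %in% c("+", "-")) stop("transcript strand must be '+' or '-'")
  o <- order(exon_starts)
  exon_starts <- as.numeric(exon_starts[o]); exon_ends <- as.numeric(exon_ends[o])
  if (any(exon_starts >= exon_ends)) stop("exon with start >= end in ", transcript_id)
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(
    list(gene_id = as.character(gene_id),
         transcript_id = as.character(transcript_id),
         chrom = as.character(chrom), strand = strand,
         exon_starts = exon_starts, exon_ends = exon_ends,
         support_level = if (is.na(support_level)) NA_integer_ else as.integer(support_level),
         biotype = as.character(biotype)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript> %s (%s) %s:%d-%d %s, %d exon(s), TSL %s\n",
              x$transcript_id, x$gene_id, x$chrom, tx_start(x), tx_end(x),
              x$strand, length(x$exon_starts),
              ifelse(is.na(x$support_level), "NA", x$support_level)))
  invisible(x)
}

tx_start <- function(model) model$exon_starts[1L]
tx_end   <- function(model) model$exon_ends[length(model$exon_ends)]

#' Transcription start / end site of a transcript model
#'
#' Strand-aware: for a minus-strand transcript the TSS is the genomic
#' rightmost transcribed base. Both are returned as the 0-based coordinate
#' of the base itself.
#'
#' @param model A `transcript_model`.
#' @return 0-based coordinate of the site base.
#' @export
transcript_tss <- function(model) {
  if (model$strand == "+") tx_start(model) else tx_end(model) - 1
}

#' @rdname transcript_tss
#' @export
transcript_tes <- function(model) {
  if (model$strand == "+") tx_end(model) - 1 else tx_start(model)
}

#' Genomic width (TSS-to-TES span) of a transcript
#' @param model A `transcript_model`.
#' @return Span in bp.
#' @export
transcript_width <- function(model) tx_end(model) - tx_start(model)

#' Parse gene models from a GTF file
#'
#' Reads exon features and assembles one `transcript_model` per transcript,
#' grouped by gene. GTF 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention. Attribute keys follow the Ensembl
#' dialect (`gene_id`, `transcript_id`, `gene_biotype`,
#' `transcript_support_level`).
#'
#' @param path GTF file.
#' @param biotypes Biotypes to retain; `NULL` keeps all. Default
#'   `"protein_coding"`.
#' @param chromosomes Optional chromosome whitelist; transcripts on other
#'   chromosomes are dropped.
#' @return Named list (by `gene_id`) of lists of `transcript_model`.
#' @export
parse_gene_models <- function(path, biotypes = "protein_coding",
                              chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    bad <- if (is.null(gr$transcript_id)) 1L else which(is.na(gr$transcript_id))[1L]
    stop("exon feature without transcript_id attribute (exon record ", bad, ")")
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("exon feature without gene_id attribute")
  }
  biot <- if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
          else rep(NA_character_, length(gr))
  tsl <- if (!is.null(gr$transcript_support_level)) {
    suppressWarnings(as.integer(as.character(gr$transcript_support_level)))
  } else rep(NA_integer_, length(gr))

  keep <- rep(TRUE, length(gr))
  if (!is.null(biotypes)) keep <- keep & (!is.na(biot) & biot %in% biotypes)
  if (!is.null(chromosomes)) {
    keep <- keep & (as.character(GenomicRanges::seqnames(gr)) %in% chromosomes)
  }
  gr <- gr[keep]; biot <- biot[keep]; tsl <- tsl[keep]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,    # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    biotype = biot, tsl = tsl,
    stringsAsFactors = FALSE
  )
  by_tx <- split(df, df$transcript_id)
  models <- lapply(by_tx, function(d) {
    transcript_model(
      gene_id = d$gene_id[1L], transcript_id = d$transcript_id[1L],
      chrom = d$chrom[1L], strand = d$strand[1L],
      exon_starts = d$start, exon_ends = d$end,
      support_level = d$tsl[1L],
      biotype = if (is.na(d$biotype[1L])) "protein_coding" else d$biotype[1L]
    )
  })
  genes <- vapply(models, `[[`, character(1L), "gene_id")
  out <- split(models, genes)
  lapply(out, unname)
}

#' Write gene models back to GTF
#'
#' Inverse of [parse_gene_models()]: emits one `exon` feature per exon with
#' `gene_id`, `transcript_id`, `gene_biotype` and (when present)
#' `transcript_support_level` attributes, converting back to 1-based
#' inclusive coordinates.
#'
#' @param models Output shape of [parse_gene_models()] (list of gene groups).
#' @param path Output GTF path.
#' @export
write_gene_models <- function(models, path) {
  flat <- unlist(models, recursive = FALSE, use.names = FALSE)
  lines <- character(0)
  for (m in flat) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     m$gene_id, m$transcript_id, m$biotype)
    if (!is.na(m$support_level)) {
      attrs <- paste0(attrs, sprintf(' transcript_support_level "%d";',
                                     m$support_level))
    }
    lines <- c(lines, sprintf("%s\tnetprof\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, m$exon_starts + 1, m$exon_ends,
                              m$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Select the representative transcript of a gene
#'
#' One transcript per gene is chosen for all region derivation: strongest
#' (numerically smallest) support level first, ties broken by the widest
#' TSS-to-TES genomic span, remaining ties by lexicographically smallest
#' transcript id so the choice is deterministic. Transcripts with no
#' support level rank after level 5 (never preferred over an evidenced
#' model).
#'
#' @param transcripts Non-empty list of `transcript_model`, all of one gene.
#' @return The selected `transcript_model`.
#' @export
select_representative <- function(transcripts) {
  if (length(transcripts) == 0L) stop("no transcripts supplied")
  gid <- unique(vapply(transcripts, `[[`, character(1L), "gene_id"))
  if (length(gid) != 1L) stop("transcripts belong to multiple genes: ",
                              paste(gid, collapse = ", "))
  sup <- vapply(transcripts, function(m)
    ifelse(is.na(m$support_level), 6L, m$support_level), integer(1L))
  wid <- vapply(transcripts, transcript_width, numeric(1L))
  tid <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  o <- order(sup, -wid, tid, method = "radix")
  transcripts[[o[1L]]]
}

#' Derive an analysis region from a transcript model
#'
#' All regions are strand-aware: "downstream" of a minus-strand gene
#' extends toward lower coordinates. Windows running off a chromosome end
#' are clamped (and flagged `clamped`), never dropped; a window falling
#' entirely off-chromosome is an error.
#'
#' @param model A `transcript_model` (the representative transcript).
#' @param scheme One of `"last_exon"`, `"tes_window"`, `"downstream"`,
#'   `"body"`, `"point_window"`.
#' @param genome Named numeric vector of chromosome lengths (for clamping).
#' @param flank Flank size in bp (`tes_window`, `point_window`).
#' @param length Region length in bp (`downstream`; default 50000).
#' @param anchor 0-based anchor base (`point_window`).
#' @param tes Optional 0-based TES base overriding the model's own TES
#'   (e.g. the most distal TES across a gene's transcripts).
#' @return A `genomic_interval`.
#' @export
derive_regions <- function(model, scheme, genome = NULL,
                           flank = 5000, length = 50000, anchor = NULL,
                           tes = NULL) {
  chrom_len <- if (!is.null(genome)) {
    if (!model$chrom %in% names(genome)) {
      stop("chromosome ", model$chrom, " absent from genome sizes")
    }
    unname(genome[[model$chrom]])
  } else Inf
  tes_pos <- if (is.null(tes)) transcript_tes(model) else tes
  plus <- model$strand == "+"

  raw <- switch(scheme,
    last_exon = {
      i <- if (plus) length(model$exon_starts) else 1L
      c(model$exon_starts[i], model$exon_ends[i])
    },
    # point windows put the anchor base in the first downstream bin in
    # TRANSCRIPTION direction: on the minus strand the window shifts one
    # base right so the two strands are exact mirror images
    tes_window = if (plus) c(tes_pos - flank, tes_pos + flank)
                 else      c(tes_pos - flank + 1, tes_pos + flank + 1),
    downstream = if (plus) c(tes_pos + 1, tes_pos + 1 + length)
                 else      c(tes_pos - length, tes_pos),
    body = c(tx_start(model), tx_end(model)),
    point_window = {
      if (is.null(anchor)) stop("point_window requires an anchor position")
      if (plus) c(anchor - flank, anchor + flank)
      else      c(anchor - flank + 1, anchor + flank + 1)
    },
    stop("unknown region scheme: ", scheme)
  )
  s <- max(0, raw[1L]); e <- min(chrom_len, raw[2L])
  if (s >= e) stop(sprintf("region '%s' for %s falls entirely off-chromosome",
                           scheme, model$transcript_id))
  genomic_interval(model$chrom, s, e, model$strand,
                   clamped = (s != raw[1L] || e != raw[2L]))
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with columns name, length (no header).
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("chrom", "len"),
                  stringsAsFactors = FALSE)
  setNames(as.numeric(d$len), d$chrom)
}

#' @rdname read_chrom_sizes
#' @param genome Named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(sprintf("%s\t%d", names(genome), as.integer(genome)), path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param regions List of `genomic_interval`.
#' @param path Output path.
#' @param names Feature names (default region index).
#' @param scores Score column (default 0).
#' @export
write_bed6 <- function(regions, path, names = NULL, scores = NULL) {
  n <- length(regions)
  if (is.null(names)) names <- as.character(seq_len(n))
  if (is.null(scores)) scores <- rep(0, n)
  lines <- vapply(seq_len(n), function(i) {
    r <- regions[[i]]
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", r$chrom, r$start, r$end,
            names[i], format(scores[i]), r$strand)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
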