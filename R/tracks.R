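# Per-base coverage tracks as run-length vectors per chromosome,
# serialized to bedGraph/bigWig at single-bp resolution.

#' Coverage track
#'
#' A per-strand, per-bp non-negative signal over a genome, held as one
#' run-length-encoded vector per chromosome (IRanges machinery).
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param strand_label `"+"`, `"-"` or `"both"`.
#' @param level `"read"` or `"snr"`.
#' @param values Optional named `RleList`-like list; default all-zero.
#' @return Object of class `cov_track`.
#' @export
cov_track <- function(genome, strand_label = "both", level = "snr",
                      values = NULL) {
  if (is.null(values)) {
    values <- lapply(genome, function(L) S4Vectors::Rle(0, L))
  }
  structure(list(genome = genome, values = values,
                 strand_label = strand_label, level = level),
            class = "cov_track")
}

#' @export
print.cov_track <- function(x, ...) {
  cat(sprintf("<cov_track> %d chromosome(s), strand %s, level %s, mass %g\n",
              length(x$genome), x$strand_label, x$level, track_mass(x)))
  invisible(x)
}

#' Total signal mass of a track
#' @param track A `cov_track`.
#' @return Sum of all per-bp values.
#' @export
track_mass <- function(track) {
  sum(vapply(track$values, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)),
             numeric(1L)))
}

coverage_one <- function(starts, widths, weights, len) {
  if (length(starts) == 0L) return(S4Vectors::Rle(0, len))
  ir <- IRanges::IRanges(start = starts + 1L, width = widths)
  IRanges::coverage(ir, width = len, weight = as.numeric(weights))
}

#' Accumulate SNR events into a strand pair of tracks
#'
#' Each event adds its weight at exactly one base of the track matching
#' its strand; total mass of the pair equals the summed event weights.
#'
#' @param events Event data.frame (chrom, pos, strand, weight).
#' @param genome Named chromosome lengths.
#' @return Named list of `cov_track`: `"+"` and `"-"`.
#' @export
accumulate_snr_track <- function(events, genome) {
  bad <- !(events$chrom %in% names(genome)) |
    events$pos < 0 | events$pos >= genome[events$chrom]
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("event off-chromosome: %s:%d (%s)", events$chrom[i],
                 events$pos[i], events$strand[i]))
  }
  out <- lapply(c("+", "-"), function(s) {
    e <- events[events$strand == s, , drop = FALSE]
    vals <- lapply(names(genome), function(ch) {
      ee <- e[e$chrom == ch, , drop = FALSE]
      coverage_one(ee$pos, rep(1L, nrow(ee)), ee$weight, genome[[ch]])
    })
    cov_track(genome, strand_label = s, level = "snr",
              values = setNames(vals, names(genome)))
  })
  setNames(out, c("+", "-"))
}

#' Accumulate read-level coverage into a strand pair of tracks
#'
#' Single-end: each record adds 1 over its aligned span on its alignment
#' strand. Paired: one span per fragment (taken from the first-in-pair
#' record, FR orientation), on the first-in-pair strand.
#'
#' @param records Filtered alignment data.frame.
#' @param genome Named chromosome lengths.
#' @param mode `"single"` or `"paired"`.
#' @return Named list of `cov_track`: `"+"` and `"-"`.
#' @export
accumulate_read_track <- function(records, genome,
                                  mode = c("single", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    r1 <- records[records$is_first, , drop = FALSE]
    spans <- data.frame(chrom = r1$chrom,
                        start = pmin(r1$start, r1$mate_start),
                        strand = r1$strand,
                        width = abs(r1$tlen), stringsAsFactors = FALSE)
  } else {
    spans <- data.frame(chrom = records$chrom, start = records$start,
                        strand = records$strand,
                        width = records$end - records$start,
                        stringsAsFactors = FALSE)
  }
  bad <- !(spans$chrom %in% names(genome)) | spans$start < 0 |
    spans$start + spans$width > genome[spans$chrom]
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("aligned span off-chromosome: %s:%d-%d", spans$chrom[i],
                 spans$start[i], spans$start[i] + spans$width[i]))
  }
  out <- lapply(c("+", "-"), function(s) {
    sp <- spans[spans$strand == s, , drop = FALSE]
    vals <- lapply(names(genome), function(ch) {
      x <- sp[sp$chrom == ch, , drop = FALSE]
      coverage_one(x$start, x$width, rep(1, nrow(x)), genome[[ch]])
    })
    cov_track(genome, strand_label = s, level = "read",
              values = setNames(vals, names(genome)))
  })
  setNames(out, c("+", "-"))
}

#' Merge replicate tracks by positionwise summation
#'
#' Raw counts are summed before any normalization (density scaling happens
#' at the profile level), matching replicate merging done to increase
#' coverage depth.
#'
#' @param tracks List of `cov_track` with identical genome and strand.
#' @return A single `cov_track`.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  g <- tracks[[1L]]$genome; sl <- tracks[[1L]]$strand_label
  for (t in tracks[-1L]) {
    if (!identical(t$genome, g)) stop("genome mismatch between tracks")
    if (!identical(t$strand_label, sl)) stop("strand mismatch between tracks")
  }
  vals <- setNames(lapply(names(g), function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]]))
  }), names(g))
  cov_track(g, strand_label = sl, level = tracks[[1L]]$level, values = vals)
}

#' Collapse a strand pair into an unstranded track
#' @param pair Named list of `cov_track` (`"+"`, `"-"`).
#' @return Unstranded `cov_track` (positionwise sum).
#' @export
combine_strands <- function(pair) {
  g <- pair[["+"]]$genome
  vals <- setNames(lapply(names(g), function(ch) {
    pair[["+"]]$values[[ch]] + pair[["-"]]$values[[ch]]
  }), names(g))
  cov_track(g, strand_label = "both", level = pair[["+"]]$level, values = vals)
}

track_to_granges <- function(track) {
  grs <- lapply(names(track$genome), function(ch) {
    r <- track$values[[ch]]
    rl <- S4Vectors::runLength(r); rv <- S4Vectors::runValue(r)
    ends <- cumsum(rl); starts <- ends - rl + 1L
    keep <- rv != 0
    GenomicRanges::GRanges(rep(ch, sum(keep)),
                           IRanges::IRanges(starts[keep], ends[keep]),
                           score = rv[keep])
  })
  gr <- suppressWarnings(do.call(c, grs))
  GenomeInfoDb::seqlevels(gr) <- names(track$genome)
  GenomeInfoDb::seqlengths(gr) <- as.integer(track$genome)
  gr
}

#' Serialize a coverage track
#'
#' bedGraph intervals are 0-based half-open, coordinate-sorted and
#' non-overlapping; adjacent equal-value runs are merged and zero runs
#' omitted. bigWig is written at single-bp resolution. A round trip
#' through [read_track()] returns an identical track.
#'
#' @param track A `cov_track`.
#' @param path Output path.
#' @param format `"bedGraph"` or `"bigWig"`.
#' @export
serialize_track <- function(track, path, format = c("bedGraph", "bigWig")) {
  format <- match.arg(format)
  gr <- track_to_granges(track)
  if (length(gr) == 0L && format == "bigWig") {
    stop("an all-zero track cannot be serialized to bigWig; use bedGraph")
  }
  if (format == "bedGraph") {
    rtracklayer::export.bedGraph(gr, path)
  } else {
    rtracklayer::export.bw(gr, path)
  }
  invisible(path)
}

#' Read a coverage track from bedGraph/bigWig
#' @param path Input file.
#' @param genome Named chromosome lengths.
#' @param strand_label,level Track metadata to restore.
#' @return A `cov_track`.
#' @export
read_track <- function(path, genome, strand_label = "both", level = "snr") {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "BigWig"
         else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(genome))
  if (any(bad)) {
    stop("unknown chromosome in track file: ",
         as.character(GenomicRanges::seqnames(gr))[which(bad)[1L]])
  }
  vals <- setNames(lapply(names(genome), function(ch) {
    x <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    coverage_one(GenomicRanges::start(x) - 1L, GenomicRanges::width(x),
                 x$score, genome[[ch]])
  }), names(genome))
  cov_track(genome, strand_label = strand_label, level = level, values = vals)
}
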