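# Post-alignment record filters: unmapped, secondary/supplementary,
# multimapper, duplicate, and (paired mode) improper-pair removal.

FLAG_PAIRED <- 0x1; FLAG_PROPER <- 0x2; FLAG_UNMAPPED <- 0x4
FLAG_REVERSE <- 0x10; FLAG_FIRST <- 0x40; FLAG_SECOND <- 0x80
FLAG_SECONDARY <- 0x100; FLAG_DUP <- 0x400; FLAG_SUPPLEMENTARY <- 0x800

flag_bit <- function(flag, bit) bitwAnd(flag, bit) > 0L

#' Read alignment records from SAM/BAM into a data.frame
#'
#' SAM input is converted to BAM internally (Rsamtools). One row per
#' record with 0-based half-open aligned-span coordinates (soft clips
#' excluded), decoded flags, the `NH` reported-alignment count when
#' present, and mate coordinates for paired records. Unmapped records are
#' retained (with NA coordinates) so that filter statistics are exhaustive.
#'
#' @param path SAM or BAM file.
#' @return data.frame of alignment records.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq",
             "mrnm", "mpos", "isize"),
    tag = "NH"
  )
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  w <- rep(NA_integer_, length(b$qname))
  has_cigar <- !is.na(b$cigar)
  w[has_cigar] <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[has_cigar])
  flag <- b$flag
  data.frame(
    qname = b$qname,
    chrom = as.character(b$rname),
    start = b$pos - 1,
    end = b$pos - 1 + w,
    strand = ifelse(flag_bit(flag, FLAG_REVERSE), "-", "+"),
    is_paired = flag_bit(flag, FLAG_PAIRED),
    is_first = flag_bit(flag, FLAG_FIRST),
    is_second = flag_bit(flag, FLAG_SECOND),
    is_proper = flag_bit(flag, FLAG_PROPER),
    is_secondary = flag_bit(flag, FLAG_SECONDARY),
    is_supplementary = flag_bit(flag, FLAG_SUPPLEMENTARY),
    is_unmapped = flag_bit(flag, FLAG_UNMAPPED),
    is_duplicate_marked = flag_bit(flag, FLAG_DUP),
    alignment_count = if (is.null(b$tag$NH)) NA_integer_ else b$tag$NH,
    mapq = b$mapq,
    mate_chrom = as.character(b$mrnm),
    mate_start = b$mpos - 1,
    tlen = b$isize,
    stringsAsFactors = FALSE
  )
}

#' Construct alignment records in code (test/fixture helper)
#'
#' Builds the same data.frame shape as [read_alignments()] with sensible
#' defaults for unspecified fields.
#'
#' @param chrom,start,end,strand Vectors of aligned-span coordinates
#'   (0-based half-open).
#' @param ... Overrides for any other record column.
#' @return data.frame of alignment records.
#' @export
alignment_records <- function(chrom, start, end, strand = "+", ...) {
  n <- length(start)
  d <- data.frame(
    qname = sprintf("r%04d", seq_len(n)),
    chrom = rep_len(chrom, n), start = rep_len(start, n),
    end = rep_len(end, n), strand = rep_len(strand, n),
    is_paired = rep_len(FALSE, n), is_first = rep_len(FALSE, n),
    is_second = rep_len(FALSE, n), is_proper = rep_len(FALSE, n),
    is_secondary = rep_len(FALSE, n), is_supplementary = rep_len(FALSE, n),
    is_unmapped = rep_len(FALSE, n), is_duplicate_marked = rep_len(FALSE, n),
    alignment_count = rep_len(1L, n), mapq = rep_len(60L, n),
    mate_chrom = rep_len(NA_character_, n), mate_start = rep_len(NA_real_, n),
    tlen = rep_len(NA_real_, n),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) d[[nm]] <- rep_len(dots[[nm]], n)
  d
}

check_sorted <- function(records) {
  mapped <- records[!records$is_unmapped, , drop = FALSE]
  if (nrow(mapped) < 2L) return(invisible(TRUE))
  for (ch in unique(mapped$chrom)) {
    s <- mapped$start[mapped$chrom == ch]
    bad <- which(diff(s) < 0)
    if (length(bad)) {
      qn <- mapped$qname[mapped$chrom == ch][bad[1L] + 1L]
      stop("input not coordinate-sorted: record '", qn,
           "' on ", ch, " is out of order")
    }
  }
  invisible(TRUE)
}

# Fragment-level key columns for paired dedup; NA where mate info missing.
fragment_key <- function(records) {
  fs <- pmin(records$start, records$mate_start)
  fe <- fs + abs(records$tlen)
  # strand of the first-in-pair alignment: own strand for mate 1,
  # flipped for mate 2 (FR orientation)
  s1 <- ifelse(records$is_first, records$strand,
               ifelse(records$strand == "+", "-", "+"))
  ifelse(is.na(fs) | is.na(records$tlen) | records$tlen == 0,
         NA_character_,
         paste(records$chrom, fs, fe, s1, sep = ":"))
}

#' Remove duplicate records from a coordinate-sorted stream
#'
#' Single-end duplicates share (chrom, start, end, strand); paired
#' duplicates share (chrom, fragment start, fragment end, first-in-pair
#' strand). The first record (first fragment, for pairs) per key is kept,
#' so the operation is idempotent and order-stable. Paired records whose
#' mate coordinates are missing cannot be keyed and are dropped.
#'
#' @param records Alignment data.frame, coordinate-sorted.
#' @param mode `"single"` or `"paired"`.
#' @return List: `records` (retained), `n_duplicate`, `n_missing_mate`.
#' @export
deduplicate <- function(records, mode = c("single", "paired")) {
  mode <- match.arg(mode)
  check_sorted(records)
  if (nrow(records) == 0L) {
    return(list(records = records, n_duplicate = 0L, n_missing_mate = 0L))
  }
  if (mode == "single") {
    key <- paste(records$chrom, records$start, records$end, records$strand,
                 sep = ":")
    keep <- !duplicated(key)
    return(list(records = records[keep, , drop = FALSE],
                n_duplicate = sum(!keep), n_missing_mate = 0L))
  }
  key <- fragment_key(records)
  missing <- is.na(key)
  # first FRAGMENT per key: the qname first seen for that key, in
  # coordinate order
  first_qn_per_key <- tapply(records$qname[!missing], key[!missing], `[`, 1L)
  keep <- !missing
  keep[!missing] <- records$qname[!missing] ==
    unname(first_qn_per_key[key[!missing]])
  list(records = records[keep, , drop = FALSE],
       n_duplicate = sum(!keep & !missing),
       n_missing_mate = sum(missing))
}

#' Filter an alignment stream
#'
#' Applies, in order: unmapped, secondary/supplementary, multimapper
#' (reported-alignment count > 1, falling back to MAPQ 0 when the count
#' field is absent), duplicate removal, and — in paired mode — removal of
#' records not in a proper pair. Each record is counted under the first
#' reason that applies, so the per-reason counts plus the retained count
#' always sum to the input count.
#'
#' @param records Alignment data.frame (coordinate-sorted).
#' @param mode `"single"` or `"paired"`.
#' @param min_length Optional minimum aligned length (default 0 = off).
#' @param keep_duplicates Diagnostic switch disabling the dedup pass.
#' @return List with `records` (retained) and `stats` (named integer
#'   vector: input, unmapped, secondary_supplementary, multimapper,
#'   too_short, duplicate, missing_mate, improper_pair, retained).
#' @export
filter_alignments <- function(records, mode = c("single", "paired"),
                              min_length = 0, keep_duplicates = FALSE) {
  mode <- match.arg(mode)
  check_sorted(records)
  n_in <- nrow(records)
  stats <- c(input = n_in, unmapped = 0L, secondary_supplementary = 0L,
             multimapper = 0L, too_short = 0L, duplicate = 0L,
             missing_mate = 0L, improper_pair = 0L, retained = 0L)

  drop <- records$is_unmapped
  stats["unmapped"] <- sum(drop)
  sec <- !drop & (records$is_secondary | records$is_supplementary)
  stats["secondary_supplementary"] <- sum(sec); drop <- drop | sec
  nh <- records$alignment_count
  multi <- !drop & ifelse(!is.na(nh), nh > 1L, records$mapq == 0L)
  stats["multimapper"] <- sum(multi); drop <- drop | multi
  if (min_length > 0) {
    short <- !drop & (records$end - records$start) < min_length
    stats["too_short"] <- sum(short); drop <- drop | short
  }

  kept <- records[!drop, , drop = FALSE]
  if (!keep_duplicates) {
    dd <- deduplicate(kept, mode)
    stats["duplicate"] <- dd$n_duplicate
    stats["missing_mate"] <- dd$n_missing_mate
    kept <- dd$records
  }
  if (mode == "paired") {
    bad <- !kept$is_proper
    stats["improper_pair"] <- sum(bad)
    kept <- kept[!bad, , drop = FALSE]
  }
  stats["retained"] <- nrow(kept)
  stopifnot(sum(stats[-1L]) == stats[["input"]])
  list(records = kept, stats = stats)
}
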