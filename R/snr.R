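# Single-nucleotide-resolution events: one genomic base per read or
# fragment marking the last nucleotide incorporated by RNAPII.

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' 3'-end events from single-end records
#'
#' The event marks the 3' end of the aligned span on the alignment's own
#' strand: the rightmost aligned base for a plus alignment, the leftmost
#' for a minus alignment. The event strand is the alignment strand.
#'
#' @param records Filtered single-end alignment data.frame.
#' @return data.frame of events: chrom, pos (0-based base), strand, weight.
#' @export
snr_single_end <- function(records) {
  if (any(records$is_paired)) {
    stop("paired records passed to the single-end extractor")
  }
  data.frame(
    chrom = records$chrom,
    pos = ifelse(records$strand == "+", records$end - 1, records$start),
    strand = records$strand,
    weight = rep_len(1L, nrow(records)),
    stringsAsFactors = FALSE
  )
}

#' 3'-end events from paired-end records
#'
#' In FR chemistry the second mate's 5' end sits at the fragment 3' end
#' and the second mate aligns on the strand opposite to the nascent RNA.
#' First-in-pair records therefore yield nothing; each second-in-pair
#' record yields one event at its own 5' end (leftmost aligned base for a
#' plus alignment, rightmost for a minus alignment) with the strand
#' flipped back to the nascent-RNA strand.
#'
#' @param records Filtered paired-end alignment data.frame.
#' @return data.frame of events (one per second-in-pair record).
#' @export
snr_paired_end <- function(records) {
  if (any(!records$is_first & !records$is_second)) {
    stop("paired record that is neither first nor second in pair")
  }
  r2 <- records[records$is_second, , drop = FALSE]
  data.frame(
    chrom = r2$chrom,
    pos = ifelse(r2$strand == "+", r2$start, r2$end - 1),
    strand = flip_strand(r2$strand),
    weight = rep_len(1L, nrow(r2)),
    stringsAsFactors = FALSE
  )
}

#' Extract SNR events from a filtered alignment stream
#'
#' Dispatch wrapper producing exactly one event per retained read
#' (single-end) or per retained pair (paired-end).
#'
#' @param records Filtered alignment data.frame.
#' @param mode `"single"` or `"paired"`.
#' @return data.frame of events with attribute `n_events`.
#' @export
extract_snr <- function(records, mode = c("single", "paired")) {
  mode <- match.arg(mode)
  ev <- if (mode == "single") snr_single_end(records)
        else snr_paired_end(records)
  attr(ev, "n_events") <- nrow(ev)
  ev
}

#' Write SNR events as BED6 (one base per line; score = weight)
#' @param events Event data.frame.
#' @param path Output path.
#' @export
write_snr_bed <- function(events, path) {
  writeLines(sprintf("%s\t%d\t%d\tsnr\t%d\t%s", events$chrom, events$pos,
                     events$pos + 1, events$weight, events$strand), path)
  invisible(path)
}
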