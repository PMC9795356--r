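# Anchored-window and scale-regions binning of coverage tracks, region
# aggregation, and per-sample density scaling.

#' Binning scheme
#'
#' @param kind `"point_window"` (fixed window around an anchor base) or
#'   `"scale_regions"` (flanks plus a gene body linearly rescaled to a
#'   common length).
#' @param flank_bp Flank extent each side, bp; must be divisible by
#'   `bin_bp`.
#' @param bin_bp Bin width, bp.
#' @param body_target_bp Virtual body length for `scale_regions`, bp;
#'   must be divisible by `bin_bp`.
#' @return List of class `bin_scheme`.
#' @export
bin_scheme <- function(kind = c("point_window", "scale_regions"),
                       flank_bp = 5000, bin_bp = 100,
                       body_target_bp = NULL) {
  kind <- match.arg(kind)
  if (flank_bp %% bin_bp != 0) {
    stop("flank_bp (", flank_bp, ") not divisible by bin_bp (", bin_bp, ")")
  }
  if (kind == "scale_regions") {
    if (is.null(body_target_bp)) stop("scale_regions needs body_target_bp")
    if (body_target_bp %% bin_bp != 0) {
      stop("body_target_bp not divisible by bin_bp")
    }
  }
  structure(list(kind = kind, flank_bp = flank_bp, bin_bp = bin_bp,
                 body_target_bp = body_target_bp), class = "bin_scheme")
}

#' Number of bins a scheme produces
#' @param scheme A `bin_scheme`.
#' @return Integer bin count (2*flank/bin for point windows;
#'   flank/bin + body/bin + flank/bin for scale-regions).
#' @export
n_bins <- function(scheme) {
  f <- scheme$flank_bp %/% scheme$bin_bp
  if (scheme$kind == "point_window") 2L * f
  else 2L * f + scheme$body_target_bp %/% scheme$bin_bp
}

# Per-bp values of the sense-strand track over genomic [start, end),
# zero-filled off-chromosome; attribute "clipped" reports truncation.
window_values <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$genome)) {
    stop("chromosome ", chrom, " absent from track")
  }
  cl <- track$genome[[chrom]]
  n <- end - start
  v <- numeric(n)
  lo <- max(start, 0); hi <- min(end, cl)
  clipped <- (lo > start) || (hi < end)
  if (hi > lo) {
    v[(lo - start + 1):(hi - start)] <-
      as.numeric(S4Vectors::window(track$values[[chrom]], lo + 1, hi))
  }
  attr(v, "clipped") <- clipped
  v
}

sense_track <- function(track_pair, strand) {
  if (strand %in% c("+", "-")) track_pair[[strand]]
  else combine_strands(track_pair)
}

bin_means <- function(v, bin_bp) {
  colMeans(matrix(v, nrow = bin_bp))
}

#' Bin a fixed window around an anchor base
#'
#' The window `[anchor - flank, anchor + flank)` is tiled with `bin_bp`
#' bins ordered in transcription direction (reversed for minus-strand
#' anchors); the anchor base falls in the first downstream bin. Each bin
#' holds the mean per-bp signal of the anchor's sense-strand track;
#' off-chromosome positions contribute zeros and are flagged.
#'
#' @param track_pair Named list of `cov_track` (`"+"`, `"-"`).
#' @param chrom Chromosome.
#' @param anchor 0-based anchor base (e.g. a TES or polyA site).
#' @param strand Anchor strand.
#' @param flank_bp,bin_bp Window and bin sizes; flank must be divisible by
#'   bin.
#' @return Numeric vector of `2*flank_bp/bin_bp` bin means.
#' @export
bin_point_window <- function(track_pair, chrom, anchor, strand,
                             flank_bp = 2000, bin_bp = 40) {
  if (flank_bp %% bin_bp != 0) stop("flank_bp not divisible by bin_bp")
  tr <- sense_track(track_pair, strand)
  # minus-strand windows shift one base right so that, after reversal
  # into transcription orientation, the anchor base is the first
  # downstream base — the exact mirror of the plus-strand layout
  off <- if (strand == "-") 1L else 0L
  v <- window_values(tr, chrom, anchor - flank_bp + off,
                     anchor + flank_bp + off)
  if (strand == "-") v <- rev(v)
  out <- bin_means(v, bin_bp)
  attr(out, "clipped") <- attr(v, "clipped")
  out
}

# Per-bp vector v rescaled onto n virtual bins via piecewise-linear
# cumulative interpolation: each genomic bp contributes to the virtual
# bins its image spans (proportional-overlap weighting). Bin values are
# MEAN per-genomic-bp signal of each bin's preimage, so they sit on the
# same scale as the flank bins (uniform coverage v gives every bin v)
# and sum(bins) * (L / n_bins) recovers the body mass exactly.
rescale_body <- function(v, n_virtual_bins, bin_bp) {
  L <- length(v)
  C <- c(0, cumsum(v))
  bounds <- seq(0, L, length.out = n_virtual_bins + 1L)
  Cb <- approx(x = 0:L, y = C, xout = bounds)$y
  diff(Cb) / (L / n_virtual_bins)
}

#' Bin a gene with flanks and a scaled body
#'
#' Produces, in transcription orientation: upstream flank bins, gene-body
#' bins with the body linearly rescaled to `body_target_bp` (proportional
#' overlap weighting, mass-conserving), then downstream flank bins. With
#' the default scheme (5 kb flanks, 100 bp bins, 15 kb body) the vector
#' has 50 + 150 + 50 bins.
#'
#' @param track_pair Named list of `cov_track` (`"+"`, `"-"`).
#' @param model A `transcript_model`.
#' @param scheme A `scale_regions` `bin_scheme`.
#' @return Numeric bin vector of length [n_bins()].
#' @export
bin_scaled_gene <- function(track_pair, model,
                            scheme = bin_scheme("scale_regions", 5000, 100,
                                                15000)) {
  stopifnot(scheme$kind == "scale_regions")
  tr <- sense_track(track_pair, model$strand)
  gs <- tx_start(model); ge <- tx_end(model)
  body <- window_values(tr, model$chrom, gs, ge)
  if (model$strand == "+") {
    up <- window_values(tr, model$chrom, gs - scheme$flank_bp, gs)
    dn <- window_values(tr, model$chrom, ge, ge + scheme$flank_bp)
  } else {
    up <- rev(window_values(tr, model$chrom, ge, ge + scheme$flank_bp))
    dn <- rev(window_values(tr, model$chrom, gs - scheme$flank_bp, gs))
    body <- rev(body)
  }
  n_body_bins <- scheme$body_target_bp %/% scheme$bin_bp
  c(bin_means(up, scheme$bin_bp),
    rescale_body(body, n_body_bins, scheme$bin_bp),
    bin_means(dn, scheme$bin_bp))
}

#' Build a regions-by-bins profile matrix
#'
#' @param track_pair Named list of `cov_track`.
#' @param models List of `transcript_model` (scale_regions) or a
#'   data.frame of anchors (chrom, pos, strand) for point windows.
#' @param scheme A `bin_scheme`.
#' @param sample_label Free-text label carried on the result.
#' @return Object of class `profile_matrix`: list(matrix, scheme,
#'   sample_label); rows are regions, columns bins.
#' @export
profile_matrix <- function(track_pair, models, scheme,
                           sample_label = "sample") {
  if (scheme$kind == "scale_regions") {
    rows <- lapply(models, function(m) bin_scaled_gene(track_pair, m, scheme))
    ids <- vapply(models, `[[`, character(1L), "transcript_id")
  } else {
    rows <- lapply(seq_len(nrow(models)), function(i) {
      bin_point_window(track_pair, models$chrom[i], models$pos[i],
                       models$strand[i], scheme$flank_bp, scheme$bin_bp)
    })
    ids <- if (!is.null(models$id)) models$id else as.character(seq_len(nrow(models)))
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  structure(list(matrix = m, scheme = scheme, sample_label = sample_label),
            class = "profile_matrix")
}

#' Aggregate a profile matrix across regions
#'
#' @param pm A `profile_matrix`.
#' @param stat Per-bin statistic: `"mean"` (default), `"sum"`, `"median"`.
#' @return Numeric per-bin profile vector.
#' @export
aggregate_matrix <- function(pm, stat = c("mean", "sum", "median")) {
  stat <- match.arg(stat)
  m <- pm$matrix
  if (is.null(m) || nrow(m) == 0L) stop("empty profile matrix")
  switch(stat,
         mean = colMeans(m),
         sum = colSums(m),
         median = apply(m, 2L, stats::median))
}

#' Density-scale a profile
#'
#' Divides each bin by the profile total so the area under the curve is
#' 1, making samples of different sequencing depth directly comparable.
#' Idempotent and invariant to global scaling of the input counts.
#'
#' @param profile Non-negative numeric vector with positive sum.
#' @return Vector of class `density_profile` summing to 1.
#' @export
density_scale <- function(profile) {
  s <- sum(profile)
  if (!is.finite(s) || s <= 0) {
    stop("cannot density-scale an all-zero profile")
  }
  structure(as.numeric(profile) / s, class = "density_profile")
}
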