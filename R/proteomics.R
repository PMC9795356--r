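# Label-free IP-MS enrichment: protein-group table ingestion,
# peptide-count filtering, log2 transform with down-shifted Gaussian
# imputation, two-sided t-test volcano, and threshold classification.

#' Default column map for MaxQuant-style protein-group tables
#'
#' @param table_names Column names of the table being loaded.
#' @return List mapping roles to column names: `id`, `gene`, `peptides`
#'   (per-replicate count columns), `intensity` (data.frame: column,
#'   condition, replicate, injection), `reverse`, `contaminant`.
#' @export
default_column_map <- function(table_names) {
  pep <- grep("^Peptides\\.", table_names, value = TRUE)
  lfq <- grep("^LFQ\\.intensity\\.", table_names, value = TRUE)
  parts <- regmatches(lfq, regexec("^LFQ\\.intensity\\.(.+)_r(\\d+)_i(\\d+)$", lfq))
  ok <- lengths(parts) == 4L
  intensity <- data.frame(
    column = lfq[ok],
    condition = vapply(parts[ok], `[`, character(1L), 2L),
    replicate = as.integer(vapply(parts[ok], `[`, character(1L), 3L)),
    injection = as.integer(vapply(parts[ok], `[`, character(1L), 4L)),
    stringsAsFactors = FALSE
  )
  list(id = "Protein.IDs", gene = "Gene.names", peptides = pep,
       intensity = intensity,
       reverse = if ("Reverse" %in% table_names) "Reverse" else NULL,
       contaminant = if ("Potential.contaminant" %in% table_names)
         "Potential.contaminant" else NULL)
}

#' Load a protein-group quantification table
#'
#' Reads a TSV (or takes a data.frame) of protein groups with
#' per-replicate peptide counts and per-injection linear-scale LFQ
#' intensities (0 = missing, the MaxQuant convention). Rows flagged `+`
#' in the reverse/contaminant columns are dropped when those columns
#' exist.
#'
#' @param table Path to a TSV or a data.frame.
#' @param column_map As from [default_column_map()]; `NULL` = derive from
#'   the table's own column names.
#' @return Object of class `protein_quant`: protein_id, gene_name,
#'   peptide_counts (matrix), intensities (matrix), design (data.frame
#'   condition/replicate/injection per intensity column).
#' @export
load_protein_groups <- function(table, column_map = NULL) {
  d <- if (is.character(table)) {
    read.delim(table, check.names = FALSE, stringsAsFactors = FALSE)
  } else table
  if (is.null(column_map)) column_map <- default_column_map(names(d))
  need <- c(column_map$id, column_map$peptides, column_map$intensity$column)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing mapped column(s): ",
                         paste(miss, collapse = ", "))
  for (fl in c(column_map$reverse, column_map$contaminant)) {
    d <- d[is.na(d[[fl]]) | d[[fl]] != "+", , drop = FALSE]
  }
  pep <- as.matrix(d[, column_map$peptides, drop = FALSE])
  intens <- as.matrix(d[, column_map$intensity$column, drop = FALSE])
  structure(list(
    protein_id = as.character(d[[column_map$id]]),
    gene_name = if (!is.null(column_map$gene) && column_map$gene %in% names(d))
      as.character(d[[column_map$gene]]) else NULL,
    peptide_counts = pep,
    intensities = intens,
    design = column_map$intensity,
    extra = d[, setdiff(names(d), c(column_map$peptides,
                                    column_map$intensity$column)),
              drop = FALSE]
  ), class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("<protein_quant> %d protein group(s), %d intensity column(s)\n",
              length(x$protein_id), ncol(x$intensities)))
  invisible(x)
}

pq_subset <- function(pq, keep) {
  pq$protein_id <- pq$protein_id[keep]
  if (!is.null(pq$gene_name)) pq$gene_name <- pq$gene_name[keep]
  pq$peptide_counts <- pq$peptide_counts[keep, , drop = FALSE]
  pq$intensities <- pq$intensities[keep, , drop = FALSE]
  if (!is.null(pq$log2)) pq$log2 <- pq$log2[keep, , drop = FALSE]
  if (!is.null(pq$imputed)) pq$imputed <- pq$imputed[keep, , drop = FALSE]
  if (!is.null(pq$extra)) pq$extra <- pq$extra[keep, , drop = FALSE]
  pq
}

#' Filter protein groups on combined peptide count
#'
#' Retains protein groups whose peptide count summed over the biological
#' replicates is STRICTLY greater than `min_combined` (a combined count
#' of exactly 3 is excluded at the default).
#'
#' @param pq A `protein_quant`.
#' @param min_combined Threshold (default 3).
#' @return Filtered `protein_quant`.
#' @export
filter_min_peptides <- function(pq, min_combined = 3) {
  pq_subset(pq, rowSums(pq$peptide_counts) > min_combined)
}

#' Log2 transform with down-shifted Gaussian imputation
#'
#' Observed intensities are log2-transformed. Missing cells (zeros) are
#' drawn per intensity column from a Gaussian centered `shift` column
#' standard deviations below the column mean with sd `width` times the
#' column sd — the standard down-shifted imputation for left-censored
#' label-free data. Deterministic given `seed`; imputed cells are
#' flagged.
#'
#' @param pq A `protein_quant`.
#' @param shift Down-shift in column sds (default 1.8).
#' @param width Imputation sd as a fraction of the column sd (default 0.3).
#' @param seed Integer seed.
#' @return `protein_quant` with `log2` and logical `imputed` matrices.
#' @export
impute_log_intensities <- function(pq, shift = 1.8, width = 0.3, seed = 1) {
  x <- pq$intensities
  obs <- x > 0
  if (!any(obs)) stop("no observed intensities at all")
  l2 <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  l2[obs] <- log2(x[obs])
  imputed <- !obs
  l2 <- with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      o <- obs[, j]
      if (!any(o)) stop("intensity column '", colnames(x)[j],
                        "' has no observed values")
      m <- mean(l2[o, j]); s <- stats::sd(l2[o, j])
      if (is.na(s)) s <- 0
      nmiss <- sum(!o)
      if (nmiss > 0) {
        l2[!o, j] <- rnorm(nmiss, mean = m - shift * s, sd = width * s)
      }
    }
    l2
  })
  pq$log2 <- l2
  pq$imputed <- imputed
  pq
}

# closed-form equal-variance two-sample t-test on one row
student_t_row <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (d == 0) return(c(d = d, p = 1, degenerate = 0))
    return(c(d = d, p = .Machine$double.xmin, degenerate = 1))
  }
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(d = d, p = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2), degenerate = 0)
}

#' Volcano t-test of test vs control intensity columns
#'
#' Two-sided Student's t-test (equal variance by default, Welch by flag)
#' per protein on log2 intensities, with injections as the observations
#' (or replicate means with `use = "replicate_means"`). Reports the mean
#' log2 difference (test minus control) and the negative log2 of the
#' p-value — the two volcano axes. Zero pooled variance with equal means
#' yields p = 1; with unequal means the p-value is floored at machine
#' minimum and flagged.
#'
#' @param pq A `protein_quant` after [impute_log_intensities()] (or with
#'   complete observed data).
#' @param test_condition,control_condition Condition labels in the design.
#' @param var_equal Equal-variance Student test (default) or Welch.
#' @param use `"injections"` (default) or `"replicate_means"`.
#' @return data.frame: protein_id, gene_name, log2_diff, p_value,
#'   neg_log2_p, degenerate.
#' @export
enrichment_test <- function(pq, test_condition, control_condition,
                            var_equal = TRUE,
                            use = c("injections", "replicate_means")) {
  use <- match.arg(use)
  if (is.null(pq$log2)) stop("log2 matrix absent; run impute_log_intensities first")
  des <- pq$design
  grab <- function(cond) {
    cols <- des$column[des$condition == cond]
    if (length(cols) < 2L) stop("condition '", cond, "' has < 2 columns")
    m <- pq$log2[, cols, drop = FALSE]
    if (use == "replicate_means") {
      reps <- des$replicate[des$condition == cond]
      m <- sapply(sort(unique(reps)), function(r) {
        rowMeans(m[, reps == r, drop = FALSE])
      })
      if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    }
    m
  }
  X <- grab(test_condition); Y <- grab(control_condition)
  res <- t(vapply(seq_along(pq$protein_id), function(i) {
    x <- X[i, ]; y <- Y[i, ]
    if (var_equal) student_t_row(x, y)
    else {
      d <- mean(x) - mean(y)
      v1 <- stats::var(x); v2 <- stats::var(y)
      if (v1 + v2 == 0) {
        if (d == 0) c(d = d, p = 1, degenerate = 0)
        else c(d = d, p = .Machine$double.xmin, degenerate = 1)
      } else {
        p <- stats::t.test(x, y, var.equal = FALSE)$p.value
        c(d = d, p = p, degenerate = 0)
      }
    }
  }, numeric(3L)))
  data.frame(
    protein_id = pq$protein_id,
    gene_name = if (is.null(pq$gene_name)) NA_character_ else pq$gene_name,
    log2_diff = res[, "d"],
    p_value = res[, "p"],
    neg_log2_p = -log2(res[, "p"]),
    degenerate = res[, "degenerate"] > 0,
    stringsAsFactors = FALSE
  )
}

#' Classify enrichment on the volcano axes
#'
#' A protein is called enriched when BOTH strict inequalities hold:
#' log2 difference > `fc_threshold` and -log2 p > `p_threshold`
#' (defaults 2 and 2, i.e. more than 4-fold up at p < 0.25).
#'
#' @param results Output of [enrichment_test()].
#' @param fc_threshold,p_threshold Strict thresholds.
#' @return `results` with an added logical `enriched` column.
#' @export
classify_enriched <- function(results, fc_threshold = 2, p_threshold = 2) {
  results$enriched <- results$log2_diff > fc_threshold &
    results$neg_log2_p > p_threshold
  results
}

#' Compare double-IP results against a single-IP reference
#'
#' Restricts to proteins called enriched in the reference single-IP
#' experiment and reports, for each, the double-IP volcano coordinates
#' next to the reference ones. Reference-enriched proteins absent from
#' the double-IP table are kept with NA double-IP values rather than
#' silently dropped.
#'
#' @param double_ip_results,reference_single_ip_results Classified result
#'   data.frames (see [classify_enriched()]).
#' @return data.frame: protein_id, log2_diff_reference,
#'   neg_log2_p_reference, log2_diff_double, neg_log2_p_double,
#'   enriched_double, in_double.
#' @export
compare_to_reference <- function(double_ip_results,
                                 reference_single_ip_results) {
  ref <- reference_single_ip_results
  if (is.null(ref$enriched)) ref <- classify_enriched(ref)
  ref <- ref[ref$enriched, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference single-IP set contains no enriched proteins")
  dbl <- double_ip_results
  if (is.null(dbl$enriched)) dbl <- classify_enriched(dbl)
  i <- match(ref$protein_id, dbl$protein_id)
  data.frame(
    protein_id = ref$protein_id,
    log2_diff_reference = ref$log2_diff,
    neg_log2_p_reference = ref$neg_log2_p,
    log2_diff_double = dbl$log2_diff[i],
    neg_log2_p_double = dbl$neg_log2_p[i],
    enriched_double = dbl$enriched[i],
    in_double = !is.na(i),
    stringsAsFactors = FALSE
  )
}
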