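# Generator for MaxQuant-style protein-group tables: log-normal
# background, spiked enriched proteins, missing values written as 0.

#' Simulation parameters for a label-free protein-group table
#'
#' @param n_background Number of background proteins (equal means in both
#'   conditions).
#' @param n_spiked Number of proteins shifted up in the test condition.
#' @param log2_effect Log2 intensity shift of spiked proteins in the test
#'   condition.
#' @param intensity_mean,intensity_sd Across-protein mean and sd of base
#'   log2 intensity.
#' @param noise_sd Within-protein, per-injection log2 measurement noise.
#' @param missing_rate Fraction of intensity cells set missing (written as
#'   0, the MaxQuant convention).
#' @param peptide_count_range Integer bounds for per-replicate peptide
#'   counts.
#' @param seed Integer seed.
#' @return List of class `lfq_sim_params`.
#' @export
lfq_sim_params <- function(n_background = 1000, n_spiked = 50,
                           log2_effect = 4,
                           intensity_mean = 25, intensity_sd = 2,
                           noise_sd = 0.4, missing_rate = 0.3,
                           peptide_count_range = c(1, 40), seed = 1) {
  stopifnot(n_background > 0, n_spiked >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(
    n_background = n_background, n_spiked = n_spiked,
    log2_effect = log2_effect, intensity_mean = intensity_mean,
    intensity_sd = intensity_sd, noise_sd = noise_sd,
    missing_rate = missing_rate,
    peptide_count_range = peptide_count_range, seed = seed
  ), class = "lfq_sim_params")
}

#' Simulate a protein-group quantification table
#'
#' Emits a TSV-shaped data.frame in the MaxQuant dialect: one row per
#' protein group, per-replicate peptide-count columns, per-injection
#' linear-scale LFQ intensity columns named
#' `LFQ.intensity.<group>_r<rep>_i<inj>`, empty `Reverse` and
#' `Potential.contaminant` flag columns, and a `truth_spiked` column
#' marking the enriched proteins. The first group in `groups` is the test
#' (spiked) condition. Missing cells are written as 0.
#'
#' @param params An `lfq_sim_params`.
#' @param groups Condition labels; first = test side.
#' @param n_bioreps Biological replicates per condition.
#' @param n_injections Injections per biological replicate.
#' @param path Optional TSV output path.
#' @return data.frame (invisibly written to `path` when given).
#' @export
simulate_lfq_table <- function(params, groups = c("IP", "control"),
                               n_bioreps = 2, n_injections = 3,
                               path = NULL) {
  if (length(groups) < 2) stop("need at least 2 condition groups")
  if (n_bioreps * n_injections < 2) stop("need >= 2 columns per group")
  n <- params$n_background + params$n_spiked
  design <- expand.grid(injection = seq_len(n_injections),
                        replicate = seq_len(n_bioreps),
                        condition = groups, stringsAsFactors = FALSE)
  design <- design[, c("condition", "replicate", "injection")]
  cols <- sprintf("LFQ.intensity.%s_r%d_i%d", design$condition,
                  design$replicate, design$injection)

  tab <- with_seed(params$seed, {
    base <- rnorm(n, params$intensity_mean, params$intensity_sd)
    spiked <- c(rep(FALSE, params$n_background), rep(TRUE, params$n_spiked))
    m <- matrix(rnorm(n * nrow(design), 0, params$noise_sd), nrow = n)
    m <- m + base
    test_cols <- design$condition == groups[1L]
    m[spiked, test_cols] <- m[spiked, test_cols] + params$log2_effect
    lin <- 2^m
    if (params$missing_rate > 0) {
      # left-censored missingness: low-intensity cells drop out first, as
      # in real label-free data; the logistic threshold is calibrated so
      # the marginal missing fraction equals missing_rate
      q <- stats::uniroot(function(q) mean(stats::plogis(q - m)) -
                            params$missing_rate,
                          range(m) + c(-20, 20))$root
      p_miss <- stats::plogis(q - m)
      lin[matrix(runif(n * nrow(design)) < p_miss, nrow = n)] <- 0
    }
    colnames(lin) <- cols
    pep <- matrix(
      sample(params$peptide_count_range[1]:params$peptide_count_range[2],
             n * n_bioreps, replace = TRUE), nrow = n)
    colnames(pep) <- sprintf("Peptides.r%d", seq_len(n_bioreps))
    data.frame(
      Protein.IDs = sprintf("P%05d", seq_len(n)),
      Gene.names = sprintf("GENE%05d", seq_len(n)),
      pep, lin,
      Reverse = "", Potential.contaminant = "",
      truth_spiked = spiked,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}
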