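#' Empirical false-discovery behaviour on spike-in null sites
#'
#' The spike-in block (lambda DNA added equimolar to every library) is
#' fully unmethylated in every sample, so its sites are replicates of a
#' global null: any site flagged as differentially methylated is a false
#' discovery. This runs the identical testing machinery — normalization
#' (performed jointly with the genomic rows, matching the equimolar
#' spike-in design), all pairwise Welch tests and the mdFDR selection,
#' with the minimum-difference filter off by default — on the spike-in
#' rows and reports the fraction flagged.
#'
#' The `screening` mode controls the stage-1 multiplicity treatment.
#' `"saturated"` (default) screens each site at level alpha with
#' Bonferroni follow-up across its pairs: the behaviour of the mdFDR
#' selection when the null block is embedded in a signal-dense
#' genome-wide analysis whose data-driven BH threshold approaches alpha,
#' which is how the spike-in travels through the real experiment.
#' `"bh"` applies the BH screening across the spike-in rows alone; on a
#' pure global null that flags essentially nothing (BH's expected
#' rejection count under the complete null is far below one per thousand
#' sites), so it measures the procedure's conservatism rather than a
#' per-site error rate. See the methods vignette for the discussion.
#'
#' @param x an [mscc_set] containing spike-in rows (`sites$is_spikein`),
#'   plus optionally genomic rows that participate in normalization.
#' @param alpha nominal mdFDR level.
#' @param screening `"saturated"` or `"bh"`; see above.
#' @param apply_min_diff apply the minimum-difference filter (`delta`)
#'   before counting a site as flagged; off by default so the comparison
#'   is against the pure mdFDR level.
#' @param delta minimum-difference value when `apply_min_diff = TRUE`.
#' @return list of class `calibration_report`: `n_spikein_sites`,
#'   `n_flagged`, `empirical_rate`, `nominal_alpha`, `screening`.
#' @export
empirical_fdr <- function(x, alpha = 0.10,
                          screening = c("saturated", "bh"),
                          apply_min_diff = FALSE, delta = 10) {
  screening <- match.arg(screening)
  stopifnot(inherits(x, "mscc_set"))
  if (!any(x$sites$is_spikein)) stop("no spike-in rows in this experiment")
  if (is.null(x$df)) x <- normalize_libraries(x)
  sp <- spikein_rows(x)
  if (any(colSums(sp$counts) == 0))
    stop("spike-in rows missing from library: ",
         paste(colnames(sp$counts)[colSums(sp$counts) == 0], collapse = ", "))
  w <- welch_pairs(sp$df, sp$samples$group)
  sel <- mdfdr_select(w$p, w$t, alpha, screening = screening)
  sig <- sel$sig
  if (apply_min_diff) sig <- min_diff_filter(sig, w$diff, delta)
  flagged <- sel$selected & rowSums(sig) > 0
  n <- nrow(sp$counts)
  structure(list(n_spikein_sites = n, n_flagged = sum(flagged),
                 empirical_rate = sum(flagged) / n,
                 nominal_alpha = alpha, screening = screening),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "spike-in calibration (%s screening): %d/%d flagged = %.2f%% at nominal %.0f%%\n",
    x$screening, x$n_flagged, x$n_spikein_sites, 100 * x$empirical_rate,
    100 * x$nominal_alpha))
  invisible(x)
}

#' Replicate spike-in calibration on freshly simulated nulls
#'
#' Simulates `n_reps` independent spike-in blocks (identical
#' negative-binomial count distributions in every library — the global
#' null) and averages the flagged fraction, giving the Monte-Carlo
#' estimate of the per-site flagging probability at the nominal level.
#'
#' @param n_reps number of simulation replicates.
#' @param alpha nominal mdFDR level.
#' @param config a [sim_config()]; its genomic block is dropped
#'   (`n_sites = 0`) and only the spike-in block simulated.
#' @param screening see [empirical_fdr()].
#' @param seed seed for the whole replicate series.
#' @return list: `mean_rate`, `se` (of the mean across replicates),
#'   `rates`, `n_sites`, `nominal_alpha`.
#' @export
calibrate_spikein_null <- function(n_reps = 50, alpha = 0.10,
                                   config = sim_config(),
                                   screening = c("saturated", "bh"),
                                   seed = 1) {
  screening <- match.arg(screening)
  set.seed(seed)
  cfg <- config
  cfg$n_sites <- 0
  cfg$seed <- NULL  # continue this function's RNG stream per replicate
  rates <- vapply(seq_len(n_reps), function(i) {
    sim <- simulate_methylome(cfg)
    empirical_fdr(sim$set, alpha = alpha, screening = screening)$empirical_rate
  }, numeric(1))
  list(mean_rate = mean(rates),
       se = stats::sd(rates) / sqrt(n_reps),
       rates = rates, n_sites = cfg$n_spikein_sites,
       nominal_alpha = alpha)
}
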