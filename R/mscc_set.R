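#' Container for a methyl-sensitive cut-counting experiment
#'
#' Bundles a count (and, after [normalize_libraries()], digestion-frequency)
#' matrix with its site table and sample sheet, in the style of a
#' `DGEList`: a plain list with validated components.
#'
#' @param counts integer matrix, sites x samples; rownames are site ids and
#'   colnames sample ids (filled from `sites`/`samples` when missing).
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`
#'   (0-based position of the C of the CpG), `motif`, `strand`, and
#'   optionally `is_spikein`.
#' @param samples data.frame with columns `sample_id`, `group`,
#'   `replicate`, `is_spikein_present`. `library_total` is (re)computed as
#'   the column sums of `counts`.
#' @return An object of class `mscc_set` with elements `counts`, `sites`,
#'   `samples`, and (once normalized) `df` and `norm_factors`.
#' @export
mscc_set <- function(counts, sites, samples) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0))
    stop("counts must be a non-negative numeric matrix")
  if (nrow(counts) != nrow(sites))
    stop("counts has ", nrow(counts), " rows but sites has ", nrow(sites))
  if (ncol(counts) != nrow(samples))
    stop("counts has ", ncol(counts), " columns but samples has ", nrow(samples))
  stopifnot(all(c("site_id", "chrom", "pos") %in% names(sites)),
            all(c("sample_id", "group") %in% names(samples)))
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id in site table")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(sites$pos < 0)) stop("site pos must be >= 0")
  if (is.null(sites$is_spikein)) sites$is_spikein <- FALSE
  rownames(counts) <- sites$site_id
  colnames(counts) <- samples$sample_id
  samples$library_total <- colSums(counts)
  structure(list(counts = counts, sites = sites, samples = samples),
            class = "mscc_set")
}

#' @export
print.mscc_set <- function(x, ...) {
  cat("mscc_set:", nrow(x$counts), "sites x", ncol(x$counts), "samples\n")
  cat("  groups:", paste(sprintf("%s(%d)", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = ", "), "\n")
  cat("  spike-in sites:", sum(x$sites$is_spikein), "\n")
  if (!is.null(x$df)) cat("  normalized: yes (target depth ",
                          format(sum(x$df[, 1])), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.mscc_set <- function(x) dim(x$counts)

#' Subset an experiment by sites and/or samples
#'
#' @param x an `mscc_set`.
#' @param i site index (logical, integer, or site ids).
#' @param j sample index.
#' @param ... ignored.
#' @return An `mscc_set` restricted to the requested rows/columns.
#'   Normalized values, if present, are carried over unchanged (factors are
#'   not recomputed, so calibration subsets keep whole-experiment scaling).
#' @export
`[.mscc_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$sites$site_id)
  out <- x
  out$counts <- x$counts[i, j, drop = FALSE]
  out$sites <- x$sites[i, , drop = FALSE]
  out$samples <- x$samples[j, , drop = FALSE]
  rownames(out$sites) <- NULL
  rownames(out$samples) <- NULL
  if (!is.null(x$df)) out$df <- x$df[i, j, drop = FALSE]
  if (!is.null(x$norm_factors)) out$norm_factors <- x$norm_factors[j]
  out
}

#' Split off the spike-in block
#'
#' @param x an `mscc_set`.
#' @return `spikein_rows(x)`: the subset of `x` with spike-in sites;
#'   `genomic_rows(x)`: the complement.
#' @export
spikein_rows <- function(x) x[which(x$sites$is_spikein), ]

#' @rdname spikein_rows
#' @export
genomic_rows <- function(x) x[which(!x$sites$is_spikein), ]
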