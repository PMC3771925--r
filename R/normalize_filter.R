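#' Normalize libraries to a common depth
#'
#' Each sample's counts are scaled by a factor proportional to the inverse
#' of its total read count, so that all column sums equal the target
#' depth. The scaled values are the digestion frequencies (df) used by all
#' downstream stages.
#'
#' @param x an [mscc_set].
#' @param target_depth common column total after scaling; defaults to the
#'   mean library total.
#' @return `x` with elements `df` (the normalized matrix) and
#'   `norm_factors` added, and a `norm_factor` column in the sample sheet.
#' @export
normalize_libraries <- function(x, target_depth = NULL) {
  stopifnot(inherits(x, "mscc_set"))
  totals <- colSums(x$counts)
  if (any(totals == 0))
    stop("zero-total library: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "))
  if (is.null(target_depth)) target_depth <- mean(totals)
  fac <- target_depth / totals
  x$df <- sweep(x$counts, 2, fac, `*`)
  x$norm_factors <- fac
  x$samples$norm_factor <- fac
  x
}

#' Per-CGI mean digestion frequency
#'
#' Averages the normalized df over the sites falling in each CpG island
#' (half-open interval test on the site position), per sample. Islands
#' containing no surveyed site are omitted; their number is attached as
#' attribute `n_empty`.
#'
#' @param x a normalized [mscc_set].
#' @param cgis an `interval_set` of CpG islands.
#' @return matrix (used CGIs x samples) of mean df, rownames from the CGI
#'   `name` column when present, else `chrom:start-end`.
#' @export
cgi_mean_df <- function(x, cgis) {
  stopifnot(!is.null(x$df))
  hits <- GenomicRanges::findOverlaps(.site_granges(x$sites),
                                      .iv_granges(cgis))
  q <- S4Vectors_queryHits(hits)
  s <- S4Vectors_subjectHits(hits)
  used <- sort(unique(s))
  out <- matrix(NA_real_, length(used), ncol(x$df),
                dimnames = list(NULL, colnames(x$df)))
  for (i in seq_along(used)) {
    rows <- q[s == used[i]]
    out[i, ] <- colMeans(x$df[rows, , drop = FALSE])
  }
  rn <- if (!is.null(cgis$name)) cgis$name
        else paste0(cgis$chrom, ":", cgis$start, "-", cgis$end)
  rownames(out) <- rn[used]
  attr(out, "n_empty") <- nrow(cgis) - length(used)
  out
}

#' Locate the valley of a bimodal score distribution
#'
#' Smooths the scores with a kernel density estimate, finds the two
#' largest modes, and returns the location of the density minimum between
#' them: the operative cutoff separating methylated (low-df) from
#' unmethylated (high-df) sites. When fewer than two modes are detected
#' the configured fixed cutoff is returned with a warning (method
#' `"fixed"`); with no fixed default this is an error.
#'
#' @param scores numeric vector of region mean-df scores (at least ~100
#'   recommended for a stable density).
#' @param bw kernel bandwidth passed to [stats::density()].
#' @param n_grid density grid size.
#' @param fixed_default fallback cutoff when bimodality is not detected
#'   (the operative value 10), or `NULL` to disallow the fallback.
#' @param bins number of histogram bins recorded for inspection.
#' @return list of class `cutoff_result`: `cutoff`, `method`
#'   (`"valley"`/`"fixed"`), `mode_low`, `mode_high`, `histogram` (from
#'   [graphics::hist()] without plotting), `density`.
#' @export
find_valley_cutoff <- function(scores, bw = "nrd0", n_grid = 512,
                               fixed_default = 10, bins = 50) {
  scores <- scores[is.finite(scores)]
  h <- graphics::hist(scores, breaks = bins, plot = FALSE)
  fallback <- function(msg) {
    if (is.null(fixed_default)) stop(msg, " and no fixed default configured")
    warning(msg, "; falling back to fixed cutoff ", fixed_default)
    structure(list(cutoff = fixed_default, method = "fixed",
                   mode_low = NA_real_, mode_high = NA_real_,
                   histogram = h, density = NULL),
              class = "cutoff_result")
  }
  if (length(unique(scores)) < 2) return(fallback("degenerate score set"))
  d <- stats::density(scores, bw = bw, n = n_grid)
  y <- d$y
  is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], Inf)
  # only substantial modes count; kernel wiggles in the tails do not
  modes <- which(is_max & y >= 0.05 * max(y))
  if (length(modes) < 2) return(fallback("no bimodality detected"))
  top2 <- modes[order(y[modes], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  between <- seq(lo, hi)
  valley <- between[which.min(y[between])]
  cut <- d$x[valley]
  # prominence: a real valley dips well below the smaller of the two modes
  if (!(d$x[lo] < cut && cut < d$x[hi]) ||
      y[valley] > 0.8 * min(y[top2]))
    return(fallback("no bimodality detected"))
  structure(list(cutoff = cut, method = "valley",
                 mode_low = d$x[lo], mode_high = d$x[hi],
                 histogram = h, density = d),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("cutoff:", format(x$cutoff), "(method:", x$method, ")\n")
  if (x$method == "valley")
    cat("  modes at", format(x$mode_low), "and", format(x$mode_high), "\n")
  invisible(x)
}

#' Exclude sites never reaching the cutoff
#'
#' A site is retained iff its df reaches the cutoff (inclusive `>=`) in at
#' least one library; sites below the cutoff in every library are presumed
#' heavily methylated in all groups and excluded. The alternative rule
#' "at least one library of every group" is available via `per_group`.
#'
#' @param x a normalized [mscc_set].
#' @param cutoff df cutoff (> 0), a number or a `cutoff_result`.
#' @param per_group require the cutoff to be reached in at least one
#'   library of *every* group rather than any single library.
#' @return The retained subset of `x`, with attribute `n_removed`.
#' @export
prefilter_sites <- function(x, cutoff, per_group = FALSE) {
  stopifnot(!is.null(x$df))
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  if (cutoff <= 0) stop("cutoff must be positive")
  pass <- x$df >= cutoff
  keep <- if (!per_group) rowSums(pass) >= 1
          else Reduce(`&`, lapply(split(seq_len(ncol(pass)), x$samples$group),
                                  function(ix)
                                    rowSums(pass[, ix, drop = FALSE]) >= 1))
  out <- x[which(keep), ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-region group means and focal fold change
#'
#' For each region, the per-group methylation score is the mean over the
#' region's sites of the within-group mean df (average of the replicate
#' digestion frequencies at each CpG, then averaged over CpGs). The fold
#' change is the focal group's score divided by the mean of the other
#' groups' scores.
#'
#' @param x a normalized [mscc_set].
#' @param regions an `interval_set`.
#' @param focal_group group whose score forms the fold-change numerator.
#' @return data.frame: `region`, `n_sites`, one column per group,
#'   `fold_change`, `empty` (regions with no sites are flagged, all
#'   statistics `NA`).
#' @export
region_stats <- function(x, regions, focal_group) {
  stopifnot(!is.null(x$df))
  groups <- unique(x$samples$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!focal_group %in% groups) stop("unknown focal group: ", focal_group)
  gmeans <- matrix(vapply(groups, function(g)
    rowMeans(x$df[, x$samples$group == g, drop = FALSE]),
    numeric(nrow(x$df))), nrow = nrow(x$df),
    dimnames = list(NULL, groups))
  hits <- GenomicRanges::findOverlaps(.site_granges(x$sites),
                                      .iv_granges(regions))
  q <- S4Vectors_queryHits(hits); s <- S4Vectors_subjectHits(hits)
  rn <- if (!is.null(regions$name)) regions$name
        else paste0(regions$chrom, ":", regions$start, "-", regions$end)
  out <- data.frame(region = rn, n_sites = 0L)
  for (g in groups) out[[g]] <- NA_real_
  out$fold_change <- NA_real_
  out$empty <- TRUE
  for (i in seq_len(nrow(regions))) {
    rows <- q[s == i]
    if (!length(rows)) next
    out$n_sites[i] <- length(rows)
    out$empty[i] <- FALSE
    sc <- colMeans(gmeans[rows, , drop = FALSE])
    out[i, groups] <- sc
    out$fold_change[i] <- sc[focal_group] / mean(sc[setdiff(groups, focal_group)])
  }
  out
}
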