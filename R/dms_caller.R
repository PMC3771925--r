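#' Welch's two-sample t test (closed form)
#'
#' The per-pair test behind the DMS caller: unequal-variance t statistic
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' A variance floor guards the degenerate case of two zero-variance
#' groups with different means; two zero-variance groups with equal means
#' give t = 0, p = 1.
#'
#' @param a,b numeric replicate vectors (length >= 2 each).
#' @param var_floor lower bound on the squared standard error.
#' @return list: `t`, `welch_df`, `p_value`, `direction`
#'   (sign of `mean(a) - mean(b)`).
#' @export
welch_test <- function(a, b, var_floor = 1e-8) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per group")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  d <- mean(a) - mean(b)
  if (se2 == 0 && d == 0)
    return(list(t = 0, welch_df = na + nb - 2, p_value = 1, direction = 0))
  se2f <- max(se2, var_floor)
  tt <- d / sqrt(se2f)
  dfw <- if (se2 > 0)
    se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  else na + nb - 2
  list(t = tt, welch_df = dfw,
       p_value = 2 * stats::pt(-abs(tt), dfw), direction = sign(d))
}

#' All pairwise Welch tests across groups, vectorized over sites
#'
#' @param mat sites x samples matrix of normalized df.
#' @param groups character/factor of group labels, one per column.
#' @param var_floor see [welch_test()].
#' @return list: `pairs` (data.frame `a`,`b`, one row per group pair in
#'   combination order), matrices `t`, `welch_df`, `p`, `diff`
#'   (mean_a - mean_b), and `group_means`.
#' @export
welch_pairs <- function(mat, groups, var_floor = 1e-8) {
  groups <- as.character(groups)
  gl <- split(seq_along(groups), factor(groups, unique(groups)))
  if (any(lengths(gl) < 2)) stop("every group needs >= 2 replicates")
  gn <- names(gl)
  means <- matrix(vapply(gl, function(ix) rowMeans(mat[, ix, drop = FALSE]),
                         numeric(nrow(mat))),
                  nrow = nrow(mat), dimnames = list(rownames(mat), gn))
  vars <- matrix(vapply(gl, function(ix) {
    m <- mat[, ix, drop = FALSE]
    rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  }, numeric(nrow(mat))), nrow = nrow(mat), dimnames = list(NULL, gn))
  ns <- lengths(gl)
  pr <- t(utils::combn(gn, 2))
  m <- nrow(pr)
  t_mat <- df_mat <- p_mat <- d_mat <- matrix(
    NA_real_, nrow(mat), m,
    dimnames = list(rownames(mat), paste(pr[, 1], pr[, 2], sep = "-")))
  for (j in seq_len(m)) {
    a <- pr[j, 1]; b <- pr[j, 2]
    se2 <- vars[, a] / ns[a] + vars[, b] / ns[b]
    d <- means[, a] - means[, b]
    se2f <- pmax(se2, var_floor)
    tt <- d / sqrt(se2f)
    dfw <- se2^2 / ((vars[, a] / ns[a])^2 / (ns[a] - 1) +
                    (vars[, b] / ns[b])^2 / (ns[b] - 1))
    dfw[!is.finite(dfw) | se2 == 0] <- ns[a] + ns[b] - 2
    p <- 2 * stats::pt(-abs(tt), dfw)
    p[se2 == 0 & d == 0] <- 1
    tt[se2 == 0 & d == 0] <- 0
    t_mat[, j] <- tt; df_mat[, j] <- dfw; p_mat[, j] <- p; d_mat[, j] <- d
  }
  list(pairs = data.frame(a = pr[, 1], b = pr[, 2]),
       t = t_mat, welch_df = df_mat, p = p_mat, diff = d_mat,
       group_means = means)
}

#' Standardized residuals across all samples of each site
#'
#' For each site, the residual of a sample is its df minus the site mean,
#' divided by the site standard deviation. Sites with zero standard
#' deviation are flagged and their residuals set to `NA`.
#'
#' @param mat sites x samples matrix.
#' @return list: `residuals` (same shape), `flagged` (logical per site).
#' @export
standardized_residuals <- function(mat) {
  if (ncol(mat) < 3) stop("need >= 3 samples")
  mu <- rowMeans(mat)
  sd <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1))
  flagged <- sd == 0
  r <- (mat - mu) / ifelse(flagged, NA, sd)
  list(residuals = r, flagged = flagged)
}

#' Normal quantile-quantile diagnostics for residuals
#'
#' Pairs the sorted residuals with standard normal quantiles at plotting
#' positions (i - 0.5)/n and reports their correlation. Advisory: the
#' caller warns on poor agreement but never blocks.
#'
#' @param residuals numeric vector (NAs dropped; >= 10 values required).
#' @return list: `theoretical`, `empirical`, `correlation`.
#' @export
qq_normality <- function(residuals) {
  r <- sort(residuals[is.finite(residuals)])
  n <- length(r)
  if (n < 10) stop("need >= 10 residuals")
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  list(theoretical = q, empirical = r, correlation = stats::cor(q, r))
}

#' Two-stage mixed-directional FDR selection
#'
#' Stage 1 (screening): each site's screening p-value is the
#' Bonferroni-combined minimum over its m pairwise p-values,
#' p* = min(m * min_j p_ij, 1); Benjamini-Hochberg on the p* at level
#' alpha selects R sites. Stage 2 (follow-up): within a selected site,
#' pair j is declared significant iff p_ij <= R * alpha / (N * m), with
#' the direction given by the sign of its t statistic. This controls the
#' mixed-directional FDR — false selections plus wrong-direction claims —
#' at level alpha.
#'
#' With `screening = "saturated"` stage 1 tests each site at level alpha
#' (p* <= alpha) and stage 2 uses alpha/m: the limit of the procedure when
#' the site under test is embedded in a signal-saturated experiment whose
#' BH selection threshold approaches alpha. Used by spike-in calibration;
#' see [empirical_fdr()].
#'
#' @param p N x m matrix of pairwise p-values.
#' @param t_sign N x m matrix of t-statistic signs (or the t values).
#' @param alpha target mdFDR level in (0, 1).
#' @param screening `"bh"` (the procedure proper) or `"saturated"`.
#' @return list: `selected` (logical N), `R`, `sig` (logical N x m, FALSE
#'   outside selected sites), `direction` (sign matrix masked by `sig`),
#'   `p_screen`, `p_adj`, `stage2_threshold`.
#' @export
mdfdr_select <- function(p, t_sign, alpha, screening = c("bh", "saturated")) {
  screening <- match.arg(screening)
  p <- as.matrix(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (!(alpha >= 0 && alpha < 1)) stop("alpha must be in [0, 1)")
  N <- nrow(p); m <- ncol(p)
  p_min <- do.call(pmin, as.data.frame(p))
  p_screen <- pmin(m * p_min, 1)
  if (screening == "bh") {
    p_adj <- stats::p.adjust(p_screen, "BH")
    selected <- p_adj <= alpha & alpha > 0
    R <- sum(selected)
    thr2 <- R * alpha / (N * m)
  } else {
    p_adj <- p_screen
    selected <- p_screen <= alpha & alpha > 0
    R <- sum(selected)
    thr2 <- alpha / m
  }
  sig <- p <= thr2 & selected
  direction <- sign(as.matrix(t_sign)) * sig
  list(selected = selected, R = R, sig = sig, direction = direction,
       p_screen = p_screen, p_adj = p_adj, stage2_threshold = thr2)
}

#' Minimum-difference filter on significant pairs
#'
#' Drops significant pairs whose absolute difference of group mean df is
#' below `delta` (inclusive `>=` retains a pair at exactly `delta`), so
#' that a statistically significant pair also reflects a different
#' methylation state. By convention `delta` equals the methylated/
#' unmethylated df cutoff.
#'
#' @param sig logical N x m matrix of significant pairs.
#' @param diff N x m matrix of group-mean differences (mean_a - mean_b).
#' @param delta minimum absolute difference.
#' @return Filtered logical matrix.
#' @export
min_diff_filter <- function(sig, diff, delta) {
  sig & (abs(diff) >= delta)
}

#' Classify tissue-specific sites from their significant pairs
#'
#' A site is `ts_unmeth(g)` iff its significant pairs are exactly the
#' k - 1 pairs involving group g, each with g's mean higher, and no other
#' pair is significant; `ts_meth(g)` symmetrically with g's mean lower.
#' Otherwise it is `dms` when any pair is significant, else `not_dms`.
#' `strict = FALSE` ignores the complementary pairs (those not involving
#' g) when testing the pattern.
#'
#' @param sig logical N x m significant-pair matrix.
#' @param diff N x m group-mean difference matrix.
#' @param pairs data.frame `a`,`b` describing the m columns.
#' @param groups character vector of all group names.
#' @param strict require the complementary pairs to be non-significant.
#' @return character vector: `"not_dms"`, `"dms"`, `"ts_unmeth(g)"` or
#'   `"ts_meth(g)"`.
#' @export
classify_ts <- function(sig, diff, pairs, groups, strict = TRUE) {
  sig <- as.matrix(sig); diff <- as.matrix(diff)
  N <- nrow(sig)
  k <- length(groups)
  cls <- ifelse(rowSums(sig) > 0, "dms", "not_dms")
  for (g in groups) {
    ing <- pairs$a == g | pairs$b == g
    g_hi <- ifelse(pairs$a == g, 1, -1)[ing]
    all_g <- rowSums(sig[, ing, drop = FALSE]) == (k - 1)
    if (strict)
      all_g <- all_g & rowSums(sig[, !ing, drop = FALSE]) == 0
    dgn <- sweep(sign(diff[, ing, drop = FALSE]), 2, g_hi, `*`)
    hi <- all_g & rowSums(dgn > 0) == (k - 1)
    lo <- all_g & rowSums(dgn < 0) == (k - 1)
    cls[hi] <- sprintf("ts_unmeth(%s)", g)
    cls[lo] <- sprintf("ts_meth(%s)", g)
  }
  cls
}

#' Call differentially methylated sites
#'
#' The full caller: normalize the libraries, derive (or accept) the
#' methylated/unmethylated df cutoff, exclude sites below the cutoff in
#' every library, run all pairwise Welch tests, select sites by the
#' two-stage mdFDR procedure, remove significant pairs whose group means
#' differ by less than `delta`, and classify tissue-specific sites.
#'
#' @param x an [mscc_set] (raw counts; normalization is applied here, or
#'   reused when `x` is already normalized).
#' @param alpha target mdFDR level.
#' @param cutoff df cutoff: a number, a `cutoff_result`, or `"valley"` to
#'   derive it from `cgis` via [cgi_mean_df()] + [find_valley_cutoff()].
#' @param cgis CpG islands, required when `cutoff = "valley"`.
#' @param delta minimum group-mean difference; defaults to the cutoff.
#' @param strict see [classify_ts()].
#' @param apply_min_diff apply the minimum-difference filter.
#' @param qq_warn_below warn when the residual QQ correlation falls below
#'   this (advisory only).
#' @return list of class `dms_result`: `table` (per retained site:
#'   `site_id`, group mean columns, `p_screen`, `p_adj`, `selected`,
#'   `n_sig_pairs`, `class`), `pairs`, `sig`, `diff`, `cutoff`, `delta`,
#'   `alpha`, `qq`, and `report` (stage-by-stage counts).
#' @export
call_dms <- function(x, alpha = 0.10, cutoff = 10, cgis = NULL,
                     delta = NULL, strict = TRUE, apply_min_diff = TRUE,
                     qq_warn_below = 0.95) {
  stopifnot(inherits(x, "mscc_set"))
  if (is.null(x$df)) x <- normalize_libraries(x)
  n_surveyed <- nrow(x$counts)
  if (identical(cutoff, "valley")) {
    if (is.null(cgis)) stop("cutoff = 'valley' needs a CGI interval set")
    cutoff <- find_valley_cutoff(as.vector(cgi_mean_df(x, cgis)))
  }
  cut_val <- if (inherits(cutoff, "cutoff_result")) cutoff$cutoff else cutoff
  if (is.null(delta)) delta <- cut_val
  xf <- prefilter_sites(x, cut_val)
  groups <- unique(xf$samples$group)

  w <- welch_pairs(xf$df, xf$samples$group)
  res <- standardized_residuals(xf$df)
  qq <- if (sum(is.finite(res$residuals)) >= 10)
    qq_normality(res$residuals) else NULL
  if (!is.null(qq) && qq$correlation < qq_warn_below)
    warning(sprintf(
      "residual QQ correlation %.3f below %.2f: normality assumption shaky",
      qq$correlation, qq_warn_below))

  sel <- mdfdr_select(w$p, w$t, alpha)
  sig <- sel$sig
  n_dms_pre <- sum(rowSums(sig) > 0)
  if (apply_min_diff) sig <- min_diff_filter(sig, w$diff, delta)
  cls <- classify_ts(sig, w$diff, w$pairs, groups, strict = strict)

  tab <- data.frame(site_id = xf$sites$site_id, w$group_means,
                    p_screen = sel$p_screen, p_adj = sel$p_adj,
                    selected = sel$selected,
                    n_sig_pairs = rowSums(sig), class = cls,
                    row.names = NULL, check.names = FALSE)
  is_ts <- startsWith(cls, "ts_")
  hypo <- vapply(groups, function(g)
    sum(cls == sprintf("ts_unmeth(%s)", g)), integer(1))
  hyper <- vapply(groups, function(g)
    sum(cls == sprintf("ts_meth(%s)", g)), integer(1))
  report <- list(n_surveyed = n_surveyed, n_retained = nrow(xf$counts),
                 n_selected = sel$R, n_dms_pre_min_diff = n_dms_pre,
                 n_dms = sum(cls != "not_dms"), n_ts_dms = sum(is_ts),
                 hypo_per_group = hypo, hyper_per_group = hyper,
                 alpha = alpha, cutoff = cut_val, delta = delta,
                 qq_correlation = if (is.null(qq)) NA_real_ else qq$correlation)
  structure(list(table = tab, pairs = w$pairs, sig = sig, diff = w$diff,
                 p = w$p, cutoff = cutoff, delta = delta, alpha = alpha,
                 qq = qq, report = report, groups = groups),
            class = "dms_result")
}

#' @export
print.dms_result <- function(x, ...) {
  r <- x$report
  cat("DMS call at mdFDR", r$alpha, "\n")
  cat(sprintf("  surveyed %d -> retained %d (df cutoff %.3g)\n",
              r$n_surveyed, r$n_retained, r$cutoff))
  cat(sprintf("  selected %d; DMS after min-diff %.3g: %d; TS-DMS: %d\n",
              r$n_selected, r$delta, r$n_dms, r$n_ts_dms))
  cat("  hypomethylated (ts_unmeth):",
      paste(names(r$hypo_per_group), r$hypo_per_group, sep = "=",
            collapse = " "), "\n")
  cat("  hypermethylated (ts_meth):",
      paste(names(r$hyper_per_group), r$hyper_per_group, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Extract the TS-DMS subset of a call
#'
#' @param dms a `dms_result`.
#' @return data.frame rows of `dms$table` whose class is tissue-specific.
#' @export
ts_dms <- function(dms) {
  dms$table[startsWith(dms$table$class, "ts_"), , drop = FALSE]
}
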