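#' Odds ratio for tissue-specific expression association
#'
#' For genes cross-classified as (associated with tissue-specific
#' methylation or not) x (uniquely expressed in the tissue or expressed
#' in more than one tissue), the association is OR = (a/c)/(b/d), where
#' a = associated and uniquely expressed, b = not associated but uniquely
#' expressed, c = associated, multiply expressed, d = not associated,
#' multiply expressed. The p-value is a Wald test on log OR with standard
#' error sqrt(1/a + 1/b + 1/c + 1/d) (one degree of freedom, as in a
#' single-covariate logistic regression). When any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to all four cells.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return list: `or`, `p_value`, `corrected` (whether +0.5 was applied).
#'   Two or more empty table margins leave the OR undefined (`NA` with a
#'   warning).
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  margins <- c(a + b, c + d, a + c, b + d)
  if (sum(margins == 0) >= 2) {
    warning("two or more empty margins: odds ratio undefined")
    return(list(or = NA_real_, p_value = NA_real_, corrected = FALSE))
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] / cells["c"]) / (cells["b"] / cells["d"])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  list(or = unname(or), p_value = 2 * stats::pnorm(-abs(z)),
       corrected = corrected)
}

#' Build the 2x2 expression-association table
#'
#' @param assoc_genes gene ids associated with tissue-specific
#'   methylation in the focal tissue.
#' @param expression data.frame: `gene_id` plus one logical column per
#'   tissue (the expression call table); the gene universe is its rows.
#' @param tissue focal tissue (column name).
#' @return list: the cells `a`, `b`, `c`, `d` and the
#'   [odds_ratio()] result. Genes expressed nowhere are excluded from the
#'   universe.
#' @export
expression_association <- function(assoc_genes, expression, tissue) {
  stopifnot(tissue %in% names(expression))
  tis_cols <- setdiff(names(expression), "gene_id")
  calls <- as.matrix(expression[tis_cols])
  n_tis <- rowSums(calls)
  keep <- n_tis > 0
  uniq <- keep & n_tis == 1 & calls[, tissue]
  multi <- keep & n_tis > 1
  assoc <- expression$gene_id %in% assoc_genes
  a <- sum(assoc & uniq); b <- sum(!assoc & uniq)
  c_ <- sum(assoc & multi); d <- sum(!assoc & multi)
  list(a = a, b = b, c = c_, d = d, test = odds_ratio(a, b, c_, d))
}

#' Fold enrichment of TS-DMS in a feature set
#'
#' The ratio between the fraction of TS-DMS falling in the features and
#' the fraction of all surveyed CpGs falling in the features:
#' `(n_overlap_dms / n_dms) / (n_overlap_cpg / n_cpg_total)`.
#'
#' @param n_overlap_dms TS-DMS inside the features.
#' @param n_dms total TS-DMS.
#' @param n_overlap_cpg surveyed CpGs inside the features.
#' @param n_cpg_total total surveyed CpGs.
#' @return The fold enrichment (scale-invariant in the four counts).
#' @export
fold_enrichment <- function(n_overlap_dms, n_dms, n_overlap_cpg,
                            n_cpg_total) {
  if (n_dms <= 0 || n_cpg_total <= 0 || n_overlap_cpg <= 0)
    stop("zero denominator in fold enrichment")
  (n_overlap_dms / n_dms) / (n_overlap_cpg / n_cpg_total)
}

# Count how many of the positions fall inside the intervals (per chrom,
# sorted starts/ends; half-open).
.count_in <- function(chrom, pos, iv_chrom, iv_start, iv_end) {
  total <- 0L
  for (ch in unique(iv_chrom)) {
    p <- pos[chrom == ch]
    if (!length(p)) next
    sel <- iv_chrom == ch
    st <- iv_start[sel]; en <- iv_end[sel]
    o <- order(st)
    st <- st[o]; en <- cummax(en[o])  # disjoint cover via running max
    i <- findInterval(p, st)
    total <- total + sum(i > 0 & p < en[pmax(i, 1L)])
  }
  total
}

#' Permutation p-value for feature-set fold enrichment
#'
#' Each iteration places as many random regions as there are features,
#' length-matched one-to-one (chromosome chosen with probability
#' proportional to its length among chromosomes the region fits on, start
#' uniform so the region fits), recomputes the fold enrichment, and the
#' p-value is the add-one estimator
#' `(1 + #(permuted fold >= observed)) / (B + 1)`.
#'
#' Placed regions may overlap each other (matching the feature sets,
#' which are not guaranteed disjoint). A permuted placement covering no
#' surveyed CpG contributes fold 0.
#'
#' @param features `interval_set` of features (e.g. one tissue's
#'   enhancers).
#' @param all_sites site table of every surveyed CpG.
#' @param dms_sites site table (or site-id subset of `all_sites`) of the
#'   TS-DMS.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param B number of iterations.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list of class `enrichment_result`: observed counts
#'   (`n_overlap_dms`, `n_dms`, `n_overlap_cpg`, `n_cpg_total`), `fold`,
#'   `p_perm`, `B`, `seed`.
#' @export
permutation_pvalue <- function(features, all_sites, dms_sites,
                               chrom_lengths, B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.character(dms_sites))
    dms_sites <- all_sites[all_sites$site_id %in% dms_sites, , drop = FALSE]
  lens <- features$end - features$start
  if (any(max(lens) > chrom_lengths) && all(max(lens) > chrom_lengths))
    stop("a feature is longer than every chromosome")
  obs_counts <- c(
    n_overlap_dms = .count_in(dms_sites$chrom, dms_sites$pos,
                              features$chrom, features$start, features$end),
    n_dms = nrow(dms_sites),
    n_overlap_cpg = .count_in(all_sites$chrom, all_sites$pos,
                              features$chrom, features$start, features$end),
    n_cpg_total = nrow(all_sites))
  fold_of <- function(od, oc) {
    if (oc == 0) return(0)
    (od / obs_counts["n_dms"]) / (oc / obs_counts["n_cpg_total"])
  }
  observed <- fold_of(obs_counts["n_overlap_dms"], obs_counts["n_overlap_cpg"])
  chroms <- names(chrom_lengths)
  n_ge <- 0L
  for (b in seq_len(B)) {
    pc <- ps <- integer(length(lens))
    for (i in seq_along(lens)) {
      fits <- chrom_lengths >= lens[i]
      ch <- sample(which(fits), 1, prob = chrom_lengths[fits])
      pc[i] <- ch
      ps[i] <- sample.int(chrom_lengths[ch] - lens[i] + 1L, 1L) - 1L
    }
    od <- .count_in(dms_sites$chrom, dms_sites$pos, chroms[pc], ps, ps + lens)
    oc <- .count_in(all_sites$chrom, all_sites$pos, chroms[pc], ps, ps + lens)
    if (fold_of(od, oc) >= observed) n_ge <- n_ge + 1L
  }
  structure(list(n_overlap_dms = unname(obs_counts["n_overlap_dms"]),
                 n_dms = unname(obs_counts["n_dms"]),
                 n_overlap_cpg = unname(obs_counts["n_overlap_cpg"]),
                 n_cpg_total = unname(obs_counts["n_cpg_total"]),
                 fold = unname(observed),
                 p_perm = (1 + n_ge) / (B + 1), B = B, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "fold enrichment %.2f (%d/%d DMS vs %d/%d CpGs); permutation p = %.4g (B = %d)\n",
    x$fold, x$n_overlap_dms, x$n_dms, x$n_overlap_cpg, x$n_cpg_total,
    x$p_perm, x$B))
  invisible(x)
}
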