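#' Log-scale signature matrix for selected sites
#'
#' Rows are the selected (DMS or TS-DMS) sites, columns the samples,
#' values log2(df + 1): a pseudocount of 1 maps df 0 to 0 on the log
#' scale.
#'
#' @param x a normalized [mscc_set].
#' @param site_ids sites to keep (default: all).
#' @param pseudocount added before the log.
#' @return numeric matrix with dimnames preserved.
#' @export
signature_matrix <- function(x, site_ids = NULL, pseudocount = 1) {
  stopifnot(!is.null(x$df))
  m <- x$df
  if (!is.null(site_ids)) m <- m[rownames(m) %in% site_ids, , drop = FALSE]
  log2(m + pseudocount)
}

#' Pearson correlation distance between samples
#'
#' d(i, j) = 1 - r(column_i, column_j): 0 for identical profiles, 2 for
#' perfectly anti-correlated ones.
#'
#' @param m signature matrix (sites x samples).
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
correlation_distance <- function(m) {
  if (ncol(m) < 2) stop("need >= 2 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(m)
  diag(d) <- 0
  d
}

#' Agglomerative clustering of a sample distance matrix
#'
#' @param distances symmetric distance matrix (e.g. from
#'   [correlation_distance()]).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An [stats::hclust] dendrogram (deterministic merge order).
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(distances), method = linkage)
}

#' Fraction of samples matching their cluster's majority label
#'
#' Cuts the dendrogram at k clusters; a sample is pure when its own label
#' equals the most frequent label of its cluster (ties resolved in the
#' sample's favour if its label is among the modes).
#'
#' @param dendrogram an [stats::hclust] object.
#' @param labels per-sample labels in leaf-name order of the clustering
#'   input.
#' @param k number of clusters.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(dendrogram, labels, k) {
  if (k > length(labels)) stop("k exceeds the number of samples")
  cl <- stats::cutree(dendrogram, k = k)
  mean(vapply(seq_along(labels), function(i) {
    memb <- labels[cl == cl[i]]
    tab <- table(memb)
    labels[i] %in% names(tab)[tab == max(tab)]
  }, logical(1)))
}

#' Export a dendrogram as Newick
#'
#' @param dendrogram an [stats::hclust] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dendrogram_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}

# df -> heatmap colour: black at df 0, saturated red at df >= max_df,
# log2 interpolation between.
.heatmap_colors <- function(df_values, max_df = 50) {
  v <- pmin(log2(pmax(df_values, 0) + 1), log2(max_df + 1)) / log2(max_df + 1)
  grDevices::rgb(v, 0, 0)
}

#' Render a clustered methylation heatmap
#'
#' Colour anchors follow the field's convention for digestion-frequency
#' heat maps: black at 0 reads (methylated), saturated red at `max_df`
#' and above (unmethylated), log2 scale between. Row display can be
#' limited to the first `first_n` sites; clustering always uses all rows
#' of `m`.
#'
#' @param m signature matrix (log2 df values from [signature_matrix()]).
#' @param dendrogram sample dendrogram ([stats::hclust]) or `NULL` to let
#'   the plotter cluster columns.
#' @param path output image file (png).
#' @param max_df df value at colour saturation.
#' @param first_n display only the first n rows (`NULL` = all).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(m, dendrogram = NULL, path, max_df = 50,
                           first_n = NULL) {
  disp <- if (!is.null(first_n)) m[seq_len(min(first_n, nrow(m))), ,
                                   drop = FALSE] else m
  breaks <- seq(0, log2(max_df + 1), length.out = 101)
  cols <- .heatmap_colors((2^breaks[-1]) - 1, max_df)
  ph <- pheatmap::pheatmap(
    disp,
    cluster_cols = if (is.null(dendrogram)) TRUE else stats::as.hclust(dendrogram),
    cluster_rows = nrow(disp) > 1,
    color = cols, breaks = breaks,
    show_rownames = nrow(disp) <= 60,
    silent = TRUE, filename = path)
  invisible(path)
}
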