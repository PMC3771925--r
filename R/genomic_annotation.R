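#' Read and write gene models
#'
#' TSV with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#' (0-based half-open). The TSS is `start` on '+' genes and `end - 1` on
#' '-' genes.
#'
#' @param path file path.
#' @return [read_genes()]: a validated gene-model data.frame with a `tss`
#'   column added.
#' @export
read_genes <- function(path) {
  g <- utils::read.delim(path, colClasses = c(chrom = "character"))
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  .validate_genes(g)
}

#' @param genes gene-model data.frame to write.
#' @rdname read_genes
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[c("gene_id", "chrom", "strand", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_genes <- function(g) {
  if (any(g$start >= g$end)) stop("gene start must be < end")
  if (!all(g$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

#' Classify sites relative to gene models
#'
#' Strand-aware windows: the TSS region spans 3 kb upstream to 2 kb
#' downstream of the TSS; the gene body is the annotated span; the 3' end
#' region extends 3 kb past the gene's downstream edge. When windows of
#' several genes overlap a site, the precedence is
#' `tss_region > gene_body > three_prime > intergenic`.
#'
#' @param sites site table.
#' @param genes gene-model data.frame (see [read_genes()]).
#' @param tss_up,tss_down TSS window extents (bp up/downstream of TSS).
#' @param three_prime_len 3' region length (bp).
#' @return character vector per site: `"tss_region"`, `"gene_body"`,
#'   `"three_prime"` or `"intergenic"`.
#' @export
classify_gene_region <- function(sites, genes, tss_up = 3000,
                                 tss_down = 2000, three_prime_len = 3000) {
  genes <- .validate_genes(genes)
  pos <- sites$pos
  out <- rep("intergenic", nrow(sites))
  win <- function(start, end) {  # half-open genomic windows
    ov <- rep(FALSE, nrow(sites))
    for (ch in unique(genes$chrom)) {
      i <- genes$chrom == ch
      j <- sites$chrom == ch
      if (!any(i) || !any(j)) next
      hits <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(ch, IRanges::IRanges(pos[j] + 1L, width = 1L)),
        GenomicRanges::GRanges(ch, IRanges::IRanges(
          pmax(0L, as.integer(start[i])) + 1L, as.integer(end[i]))))
      ov[which(j)[unique(S4Vectors_queryHits(hits))]] <- TRUE
    }
    ov
  }
  plus <- genes$strand == "+"
  tss_s <- ifelse(plus, genes$tss - tss_up, genes$tss - tss_down)
  tss_e <- ifelse(plus, genes$tss + tss_down, genes$tss + tss_up + 1L)
  tp_s <- ifelse(plus, genes$end, genes$start - three_prime_len)
  tp_e <- ifelse(plus, genes$end + three_prime_len, genes$start)
  in_tss <- win(tss_s, tss_e)
  in_body <- win(genes$start, genes$end)
  in_tp <- win(tp_s, tp_e)
  out[in_tp] <- "three_prime"
  out[in_body & !in_tp] <- "gene_body"
  out[in_body & in_tp] <- "gene_body"
  out[in_tss] <- "tss_region"
  out
}

#' Classify sites relative to CpG islands and shores
#'
#' `island` when the site lies inside any CGI; else `shore` when within
#' `shore_width` bp of a CGI edge; else `outside`. One CGI definition is
#' used per call; report per set.
#'
#' @param sites site table.
#' @param cgis `interval_set` of CGIs.
#' @param shore_width shore extent in bp (2 kb by convention).
#' @return character vector per site: `"island"`, `"shore"`, `"outside"`.
#' @export
classify_cgi_region <- function(sites, cgis, shore_width = 2000) {
  sg <- .site_granges(sites)
  isl <- GenomicRanges::findOverlaps(sg, .iv_granges(cgis))
  shr <- GenomicRanges::findOverlaps(
    sg, .iv_granges(data.frame(chrom = cgis$chrom,
                               start = pmax(0L, cgis$start - as.integer(shore_width)),
                               end = cgis$end + as.integer(shore_width))))
  out <- rep("outside", nrow(sites))
  out[unique(S4Vectors_queryHits(shr))] <- "shore"
  out[unique(S4Vectors_queryHits(isl))] <- "island"
  out
}

#' Associate sites with genes
#'
#' A site lying within a gene's span extended by `flank` bp on both sides
#' gets a strong association with that gene (ties among covering genes
#' broken by the lexicographically smaller `gene_id`); otherwise it gets a
#' weak association with the gene of the nearest TSS (absolute distance;
#' same tie-break).
#'
#' @param sites site table (typically the TS-DMS subset).
#' @param genes gene-model data.frame.
#' @param flank extension around the gene span in bp.
#' @return data.frame per site: `site_id`, `gene_id`, `strength`
#'   (`"strong"`/`"weak"`; `NA`/`"unassigned"` when the gene set is
#'   empty, with a warning).
#' @export
associate_genes <- function(sites, genes, flank = 3000) {
  if (nrow(genes) == 0) {
    warning("empty gene set: all sites unassigned")
    return(data.frame(site_id = sites$site_id, gene_id = NA_character_,
                      strength = "unassigned"))
  }
  genes <- .validate_genes(genes)
  ord <- order(genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  out <- data.frame(site_id = sites$site_id,
                    gene_id = rep(NA_character_, nrow(sites)),
                    strength = rep(NA_character_, nrow(sites)))
  gg <- .iv_granges(data.frame(chrom = genes$chrom,
                               start = pmax(0L, genes$start - as.integer(flank)),
                               end = genes$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(.site_granges(sites), gg)
  q <- S4Vectors_queryHits(hits); s <- S4Vectors_subjectHits(hits)
  # genes sorted by id: the first hit per site is the lexicographic winner
  first <- tapply(s, q, min)
  idx <- as.integer(names(first))
  out$gene_id[idx] <- genes$gene_id[first]
  out$strength[idx] <- "strong"
  weak <- which(is.na(out$gene_id))
  for (i in weak) {
    same <- genes$chrom == sites$chrom[i]
    cand <- if (any(same)) which(same) else seq_len(nrow(genes))
    dist <- abs(genes$tss[cand] - sites$pos[i])
    best <- cand[dist == min(dist)]
    out$gene_id[i] <- genes$gene_id[best][1]  # genes sorted by id
    out$strength[i] <- "weak"
  }
  out
}

#' Category proportions per site class
#'
#' @param category character vector of per-site categories (e.g. gene
#'   regions or CGI regions).
#' @param class character vector of per-site class labels (e.g.
#'   `"ts_dms"` vs `"equally_unmethylated"`).
#' @return data.frame of proportions, one row per class, one column per
#'   category; rows sum to 1.
#' @export
distribution_summary <- function(category, class = rep("all", length(category))) {
  tab <- table(class, category)
  prop <- prop.table(tab, 1)
  out <- as.data.frame.matrix(prop)
  out <- cbind(class = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Baseline set of equally unmethylated sites
#'
#' Sites whose average normalized df exceeds the cutoff in every group
#' and that were not called DMS: the background against which TS-DMS
#' placement is compared.
#'
#' @param x a normalized [mscc_set].
#' @param dms a `dms_result` from [call_dms()].
#' @param cutoff df cutoff (number or `cutoff_result`).
#' @return character vector of site ids.
#' @export
equally_unmethylated_sites <- function(x, dms, cutoff = 10) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  stopifnot(!is.null(x$df))
  gmeans <- matrix(vapply(unique(x$samples$group), function(g)
    rowMeans(x$df[, x$samples$group == g, drop = FALSE]),
    numeric(nrow(x$df))), nrow = nrow(x$df))
  all_unmeth <- rowSums(gmeans > cutoff) == ncol(gmeans)
  dms_ids <- dms$table$site_id[dms$table$class != "not_dms"]
  setdiff(x$sites$site_id[all_unmeth], dms_ids)
}
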