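#!/usr/bin/env Rscript
# Association statistics for the called TS-DMS: per tissue, the odds
# ratio linking TS-DMS-associated genes to unique expression in that
# tissue, and the fold enrichment of TS-DMS in the tissue's enhancer set
# with a length-matched random-placement permutation p-value.

suppressPackageStartupMessages(library(msccdm))
data_dir <- "results/data"

sites <- read.delim(file.path(data_dir, "sites.tsv"),
                    colClasses = c(chrom = "character"))
genomic <- sites[sites$chrom != "lambda", ]
enh <- read_intervals(file.path(data_dir, "enhancers.bed"),
                      kind = "enhancer")
genes <- read_genes(file.path(data_dir, "genes.tsv"))
expr <- read.delim(file.path(data_dir, "expression.tsv"))
dms_tab <- read.delim("results/dms_table.tsv")
genome <- Biostrings::readDNAStringSet(file.path(data_dir, "genome.fa"))
chrom_lengths <- setNames(Biostrings::width(genome), names(genome))

groups <- setdiff(names(expr), "gene_id")
out <- list()
for (g in groups) {
  ids <- dms_tab$site_id[dms_tab$class == sprintf("ts_unmeth(%s)", g)]
  ts_sites <- genomic[match(ids, genomic$site_id), , drop = FALSE]
  assoc <- associate_genes(ts_sites, genes)
  ea <- expression_association(unique(assoc$gene_id), expr, g)
  pe <- if (nrow(ts_sites) > 0)
    permutation_pvalue(enh[enh$name == g, ], genomic, ts_sites,
                       chrom_lengths, B = 2000, seed = 88)
  else NULL
  cat(sprintf("%-7s n_ts=%3d  OR=%5.2f (p=%.3g)", g, nrow(ts_sites),
              ea$test$or, ea$test$p_value))
  if (!is.null(pe))
    cat(sprintf("  enhancer fold=%5.2f (perm p=%.4g, B=%d)",
                pe$fold, pe$p_perm, pe$B))
  cat("\n")
  out[[g]] <- list(n_ts = nrow(ts_sites),
                   two_by_two = ea[c("a", "b", "c", "d")],
                   odds_ratio = ea$test$or, or_p = ea$test$p_value,
                   fold = if (is.null(pe)) NA else pe$fold,
                   p_perm = if (is.null(pe)) NA else pe$p_perm)
}
jsonlite::write_json(out, "results/enrichment.json", auto_unbox = TRUE,
                     digits = NA)
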