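#!/usr/bin/env Rscript
# Place the called TS-DMS relative to gene models (TSS region, body,
# 3' end, intergenic) and CpG islands/shores, compare their distribution
# with the equally-unmethylated background, and associate each TS-DMS
# with a gene (strong within +-3 kb of the gene span, else nearest TSS).

suppressPackageStartupMessages(library(msccdm))
data_dir <- "results/data"

sites <- read.delim(file.path(data_dir, "sites.tsv"),
                    colClasses = c(chrom = "character"))
samples <- read_sample_sheet(file.path(data_dir, "samples.csv"))
x <- normalize_libraries(
  read_counts(file.path(data_dir, "counts.tsv"), sites, samples))
genes <- read_genes(file.path(data_dir, "genes.tsv"))
cgis <- read_intervals(file.path(data_dir, "cgis.bed"), kind = "cgi")
dms_tab <- read.delim("results/dms_table.tsv")
cut <- jsonlite::read_json("results/cutoff.json")$cutoff

ts_ids <- dms_tab$site_id[startsWith(dms_tab$class, "ts_")]
gx <- genomic_rows(x)
fake_call <- list(table = dms_tab)  # site ids + classes drive the baseline
base_ids <- equally_unmethylated_sites(gx, fake_call, cut)

ann_for <- function(ids, label) {
  s <- gx$sites[match(ids, gx$sites$site_id), , drop = FALSE]
  data.frame(site_id = ids, set = label,
             gene_region = classify_gene_region(s, genes),
             cgi_region = classify_cgi_region(s, cgis))
}
ann <- rbind(ann_for(ts_ids, "ts_dms"),
             ann_for(base_ids, "equally_unmethylated"))

cat("gene-region distribution (proportions):\n")
print(distribution_summary(ann$gene_region, ann$set), digits = 3)
cat("\nCGI-region distribution (proportions):\n")
print(distribution_summary(ann$cgi_region, ann$set), digits = 3)

assoc <- associate_genes(gx$sites[match(ts_ids, gx$sites$site_id), ],
                         genes)
cat("\nTS-DMS gene association:", sum(assoc$strength == "strong"),
    "strong,", sum(assoc$strength == "weak"), "weak\n")

ann$gene_id <- NA_character_
ann$gene_id[match(assoc$site_id, ann$site_id)] <- assoc$gene_id
write.table(ann, "results/annotation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
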