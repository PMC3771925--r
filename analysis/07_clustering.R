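#!/usr/bin/env Rscript
# Epigenetic-signature clustering: Pearson correlation distances between
# samples over the log2 digestion frequencies of the called DMS and
# TS-DMS, average-linkage dendrograms, tissue purity at k = 4, and the
# hold-out check that a 13th library simulated from one tissue's profile
# joins that tissue's subtree.

suppressPackageStartupMessages(library(msccdm))
data_dir <- "results/data"

sites <- read.delim(file.path(data_dir, "sites.tsv"),
                    colClasses = c(chrom = "character"))
samples <- read_sample_sheet(file.path(data_dir, "samples.csv"))
x <- normalize_libraries(
  read_counts(file.path(data_dir, "counts.tsv"), sites, samples))
truth <- read.delim(file.path(data_dir, "truth.tsv"))
dms_tab <- read.delim("results/dms_table.tsv")

for (setname in c("dms", "ts_dms")) {
  ids <- if (setname == "dms") dms_tab$site_id[dms_tab$class != "not_dms"]
         else dms_tab$site_id[startsWith(dms_tab$class, "ts_")]
  sm <- signature_matrix(x, ids)
  hc <- hierarchical_cluster(correlation_distance(sm))
  pur <- cluster_purity(hc, x$samples$group, k = 4)
  cat(sprintf("%s signature: %d sites, purity at k=4: %.2f\n",
              setname, length(ids), pur))
  dendrogram_newick(hc, sprintf("results/dendrogram_%s.nwk", setname))
  if (setname == "ts_dms")
    render_heatmap(sm, hc, "results/heatmap_ts_dms.png", first_n = 40)
}

# hold-out: a fresh liver-profile library must join the liver subtree
set.seed(99)
state_liver <- truth$state_liver[match(rownames(x$counts), truth$site_id)]
mu <- ifelse(state_liver == "unmeth", 30, 2)
extra <- rnbinom(length(mu), mu = mu, size = 50)
samples13 <- rbind(samples,
                   data.frame(sample_id = "liver_embryo", group = "liver",
                              replicate = 4, is_spikein_present = TRUE))
x13 <- normalize_libraries(mscc_set(cbind(x$counts, liver_embryo = extra),
                                    x$sites, samples13))
ids <- dms_tab$site_id[startsWith(dms_tab$class, "ts_")]
hc13 <- hierarchical_cluster(correlation_distance(
  signature_matrix(x13, ids)))
cl <- cutree(hc13, k = 4)
joined <- cl[["liver_embryo"]] ==
  unique(cl[x13$samples$group == "liver" &
              x13$samples$sample_id != "liver_embryo"])[1]
cat("hold-out liver library joins the liver subtree:", joined, "\n")
dendrogram_newick(hc13, "results/dendrogram_holdout.nwk")
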