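#!/usr/bin/env Rscript
# Generate the study data: a toy genome with annotations (genes, CpG
# islands, per-tissue enhancer sets, expression calls) and a methylome
# count experiment over its recognition sites -- 4 tissues x 3 replicate
# libraries, bimodal digestion frequencies, planted tissue-specific
# sites, and the 1,202-site lambda spike-in block in every library.

suppressPackageStartupMessages(library(msccdm))
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260920

toy <- simulate_toy_genome(out_dir = data_dir, enrichment = 5, seed = seed)
sim <- simulate_methylome(sim_config(seed = seed + 1),
                          layout = list(sites = toy$sites,
                                        preset = toy$preset))

write_counts(sim$set, file.path(data_dir, "counts.tsv"))
write_sample_sheet(sim$set$samples, file.path(data_dir, "samples.csv"))
write.table(sim$truth, file.path(data_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$set$sites, file.path(data_dir, "sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("genome:", length(toy$genome), "chromosomes,",
    sum(nchar(toy$genome)), "bp;", nrow(toy$sites), "surveyed sites\n")
cat("planted tissue-specific sites:",
    sum(toy$ts_truth$ts_label != "none"), "\n")
print(sim$set)
cat("library totals:",
    paste(range(colSums(sim$set$counts)), collapse = " - "), "\n")
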