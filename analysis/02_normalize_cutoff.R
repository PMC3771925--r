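#!/usr/bin/env Rscript
# Normalize the libraries to a common depth and derive the methylated/
# unmethylated df cutoff from the valley of the per-CGI mean digestion
# frequency distribution, with the fixed fallback of 10.

suppressPackageStartupMessages(library(msccdm))
data_dir <- "results/data"

sites <- read.delim(file.path(data_dir, "sites.tsv"),
                    colClasses = c(chrom = "character"))
samples <- read_sample_sheet(file.path(data_dir, "samples.csv"))
x <- read_counts(file.path(data_dir, "counts.tsv"), sites, samples)
cgis <- read_intervals(file.path(data_dir, "cgis.bed"), kind = "cgi")

x <- normalize_libraries(x)
cat("normalization factors:",
    paste(sprintf("%.2f", range(x$norm_factors)), collapse = " - "), "\n")

scores <- cgi_mean_df(x, cgis)
cut <- find_valley_cutoff(as.vector(scores))
print(cut)

retained <- prefilter_sites(genomic_rows(x), cut)
cat("prefilter at df >=", round(cut$cutoff, 2), ":",
    nrow(retained$counts), "of", sum(!x$sites$is_spikein),
    "genomic sites retained\n")

write.table(data.frame(cgi = rownames(scores), scores, check.names = FALSE),
            "results/cgi_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(cutoff = cut$cutoff, method = cut$method,
                          mode_low = cut$mode_low, mode_high = cut$mode_high,
                          n_retained = nrow(retained$counts)),
                     "results/cutoff.json", auto_unbox = TRUE, digits = NA)
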