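#!/usr/bin/env Rscript
# Call differentially methylated sites across the six tissue pairs with
# mdFDR 10%, apply the minimum-difference filter, classify
# tissue-specific sites, and compare the calls against the planted truth.

suppressPackageStartupMessages(library(msccdm))
data_dir <- "results/data"

sites <- read.delim(file.path(data_dir, "sites.tsv"),
                    colClasses = c(chrom = "character"))
samples <- read_sample_sheet(file.path(data_dir, "samples.csv"))
x <- read_counts(file.path(data_dir, "counts.tsv"), sites, samples)
truth <- read.delim(file.path(data_dir, "truth.tsv"))
cut <- jsonlite::read_json("results/cutoff.json")$cutoff

call <- call_dms(genomic_rows(normalize_libraries(x)), alpha = 0.10,
                 cutoff = cut)
print(call)

ts <- ts_dms(call)
got <- sub("^ts_(unmeth|meth)\\((.*)\\)$", "ts_\\1:\\2", ts$class)
planted <- truth$site_id[truth$ts_label != "none"]
correct <- ts$site_id[got == truth$ts_label[match(ts$site_id,
                                                  truth$site_id)]]
cat(sprintf("recovery vs planted truth: %d/%d planted recovered (%.1f%%),
  %d/%d calls correct\n",
            length(correct), length(planted),
            100 * length(correct) / length(planted),
            length(correct), nrow(ts)))

write.table(call$table, "results/dms_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(call$report, "results/dms_report.json",
                     auto_unbox = TRUE, digits = NA)
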