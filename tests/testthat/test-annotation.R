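mk_sites <- function(pos, chrom = "chr1") {
  data.frame(site_id = paste(chrom, pos, sep = ":"), chrom = chrom,
             pos = as.integer(pos), motif = "CCGG", strand = "+",
             is_spikein = FALSE)
}

test_that("gene-relative classification uses strand-aware windows", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 10000L, end = 20000L)
  got <- classify_gene_region(mk_sites(c(8000, 12500, 20500, 26000, 6500)),
                              genes)
  expect_equal(got, c("tss_region", "gene_body", "three_prime",
                      "intergenic", "intergenic"))

  # '-' strand: TSS at end - 1, upstream extends to larger coordinates
  gneg <- data.frame(gene_id = "g2", chrom = "chr1", strand = "-",
                     start = 10000L, end = 20000L)
  got2 <- classify_gene_region(mk_sites(c(21500, 18500, 12000, 8500, 24000)),
                               gneg)
  expect_equal(got2, c("tss_region", "tss_region", "gene_body",
                       "three_prime", "intergenic"))

  # precedence: a site in one gene's TSS window and another's body
  both <- rbind(genes,
                data.frame(gene_id = "g3", chrom = "chr1", strand = "+",
                           start = 11000L, end = 15000L))
  expect_equal(classify_gene_region(mk_sites(9000), both), "tss_region")
  # invariant to gene order
  expect_equal(classify_gene_region(mk_sites(9000), both[2:1, ]),
               "tss_region")
})

test_that("CGI classification separates island, shore and outside", {
  cgis <- interval_set("chr1", 10000, 10500, kind = "cgi")
  got <- classify_cgi_region(mk_sites(c(10100, 9000, 13000, 11500)), cgis)
  expect_equal(got, c("island", "shore", "outside", "shore"))
  # shore and island are exclusive by construction
  expect_false(any(got == "island" & got == "shore"))
})

test_that("gene association is strong in the flank, else nearest TSS", {
  genes <- data.frame(gene_id = c("geneB", "geneA"), chrom = "chr1",
                      strand = "+", start = c(10000L, 40000L),
                      end = c(20000L, 50000L))
  got <- associate_genes(mk_sites(c(12000, 22000, 30000, 26000)), genes)
  expect_equal(got$strength, c("strong", "strong", "weak", "weak"))
  expect_equal(got$gene_id[1:2], c("geneB", "geneB"))
  # site 30000: TSS distances 20000 (geneB) and 10000 (geneA) -> geneA
  expect_equal(got$gene_id[3], "geneA")
  # site 26000: outside both flanks? no - within geneB end+3000? 26000 > 23000,
  # distances 16000 vs 14000 -> geneA
  expect_equal(got$gene_id[4], "geneA")

  # equidistant tie breaks to the lexicographically smaller gene id
  tie <- data.frame(gene_id = c("zeta", "alpha"), chrom = "chr1",
                    strand = "+", start = c(0L, 60000L),
                    end = c(100L, 60100L))
  got_tie <- associate_genes(mk_sites(30000), tie)
  expect_equal(got_tie$gene_id, "alpha")
  expect_equal(got_tie$strength, "weak")

  expect_warning(got_e <- associate_genes(mk_sites(100), genes[0, ]),
                 "empty gene set")
  expect_equal(got_e$strength, "unassigned")
})

test_that("nearest-TSS assignment matches a brute-force scan", {
  set.seed(19)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                      strand = sample(c("+", "-"), 20, replace = TRUE),
                      start = sort(sample.int(2e5, 20)) * 1L)
  genes$end <- genes$start + sample(1000:3000, 20)
  sites <- mk_sites(sort(sample.int(210000, 100)))
  got <- associate_genes(sites, genes, flank = 500)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  for (i in seq_len(nrow(sites))) {
    covering <- which(sites$pos[i] >= genes$start - 500 &
                      sites$pos[i] < genes$end + 500)
    if (length(covering)) {
      expect_equal(got$strength[i], "strong")
      expect_equal(got$gene_id[i], min(genes$gene_id[covering]))
    } else {
      d <- abs(tss - sites$pos[i])
      best <- which(d == min(d))
      expect_equal(got$strength[i], "weak")
      expect_equal(got$gene_id[i], min(genes$gene_id[best]))
    }
  }
})

test_that("distribution summaries are proportions that sum to one", {
  cat1 <- c("intergenic", "intergenic", "tss_region", "gene_body")
  cls <- c("ts", "ts", "ts", "bg")
  out <- distribution_summary(cat1, cls)
  expect_equal(rowSums(out[-1]), c(1, 1), ignore_attr = TRUE)
  expect_equal(out[out$class == "ts", "intergenic"], 2 / 3)
  expect_equal(out[out$class == "bg", "gene_body"], 1)

  all_int <- distribution_summary(rep("intergenic", 5))
  expect_equal(all_int$intergenic, 1)
})

test_that("equally unmethylated baseline excludes DMS and low-df sites", {
  set.seed(4)
  cfg <- sim_config(n_sites = 1500, frac_ts_unmeth = 0.04,
                    n_spikein_sites = 0, seed = 44)
  sim <- simulate_methylome(cfg)
  x <- normalize_libraries(sim$set)
  call <- call_dms(x, alpha = 0.1)
  base <- equally_unmethylated_sites(x, call, cutoff = 10)
  expect_gt(length(base), 0)
  dms_ids <- call$table$site_id[call$table$class != "not_dms"]
  expect_equal(length(intersect(base, dms_ids)), 0L)
  truth <- sim$truth[match(base, sim$truth$site_id), ]
  state_cols <- grep("^state_", names(truth))
  expect_gt(mean(rowSums(truth[state_cols] == "unmeth") == 4), 0.95)
})
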