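test_that("odds ratio follows (a/c)/(b/d) with Haldane correction", {
  r <- odds_ratio(10, 5, 20, 40)
  expect_equal(r$or, 4.0)
  expect_false(r$corrected)
  expect_true(r$p_value > 0 && r$p_value < 1)

  expect_equal(odds_ratio(10, 5, 40, 20)$or, 1.0)

  rz <- odds_ratio(0, 5, 20, 40)
  expect_true(rz$corrected)
  expect_equal(rz$or, (0.5 / 20.5) / (5.5 / 40.5))

  expect_warning(rm_ <- odds_ratio(0, 0, 0, 3), "margins")
  expect_true(is.na(rm_$or))
  expect_error(odds_ratio(-1, 1, 1, 1), "non-negative")
})

test_that("expression association builds the 2x2 table over the gene universe", {
  expr <- data.frame(gene_id = sprintf("g%d", 1:6),
                     liver = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                     brain = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  # unique liver: g1, g2; multi: g3, g5; nowhere: g6 (dropped); unique brain: g4
  ea <- expression_association(c("g1", "g3"), expr, "liver")
  expect_equal(c(ea$a, ea$b, ea$c, ea$d), c(1, 1, 1, 1))
})

test_that("fold enrichment reproduces the published enhancer overlaps", {
  total <- 6955111
  # H3K4me1 tissue-specific enhancer sets
  expect_equal(round(fold_enrichment(60, 1149, 64512, total), 2), 5.63)
  expect_equal(round(fold_enrichment(147, 1115, 44549, total), 2), 20.58)
  expect_equal(round(fold_enrichment(792, 2933, 63053, total), 2), 29.79)
  expect_equal(round(fold_enrichment(3314, 8865, 164862, total), 2), 15.77)
  # active (H3K4me1 + H3K27ac) enhancer sets
  expect_equal(round(fold_enrichment(43, 1149, 33010, total), 2), 7.89)
  expect_equal(round(fold_enrichment(115, 1115, 29187, total), 2), 24.58)
  expect_equal(round(fold_enrichment(561, 2933, 38697, total), 2), 34.38)
  expect_equal(round(fold_enrichment(758, 8865, 50783, total), 2), 11.71)

  expect_equal(fold_enrichment(5, 50, 100, 1000), 1.0)
  # scale invariance
  expect_equal(fold_enrichment(30, 120, 700, 9000),
               fold_enrichment(300, 1200, 7000, 90000))
  expect_error(fold_enrichment(1, 0, 1, 10), "denominator")
})

test_that("permutation p-value hits the add-one endpoint on planted signal", {
  set.seed(10)
  all_sites <- data.frame(site_id = sprintf("s%d", 1:500), chrom = "chr1",
                          pos = sort(sample.int(1e5, 500)))
  feat <- interval_set("chr1", 0, 1000)
  inside <- all_sites[all_sites$pos < 1000, ]
  res <- permutation_pvalue(feat, all_sites, inside,
                            c(chr1 = 100000L), B = 99, seed = 2)
  expect_equal(res$p_perm, 1 / 100)
  expect_gt(res$fold, 10)
  expect_equal(res$n_overlap_dms, nrow(inside))

  # null self-consistency: dms = all sites -> fold exactly 1, p large
  res1 <- permutation_pvalue(feat, all_sites, all_sites,
                             c(chr1 = 100000L), B = 99, seed = 3)
  expect_equal(res1$fold, 1)
  expect_gt(res1$p_perm, 0.05)

  expect_error(permutation_pvalue(interval_set("chr1", 0, 5000), all_sites,
                                  inside, c(chr1 = 4000L), B = 10),
               "longer than every chromosome")
})

test_that("planted toy-genome enrichment is called significant", {
  toy <- simulate_toy_genome(enrichment = 20, frac_ts = 0.01, seed = 15)
  g <- "liver"
  ts <- toy$sites[toy$ts_truth$ts_label == paste0("ts_unmeth:", g), ]
  res <- permutation_pvalue(toy$enhancers[toy$enhancers$name == g, ],
                            toy$sites, ts, toy$chrom_lengths,
                            B = 1000, seed = 6)
  expect_equal(res$p_perm, 1 / 1001)
  expect_gt(res$fold, 10)
})

test_that("fold-enrichment counting agrees with an interval-tree oracle", {
  set.seed(77)
  sites <- data.frame(site_id = sprintf("s%d", 1:300),
                      chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
                      pos = sample.int(5e4, 300))
  st <- sample.int(45000, 20)
  iv <- interval_set(sample(c("chr1", "chr2"), 20, replace = TRUE),
                     st, st + sample(500:4000, 20))
  res <- permutation_pvalue(iv, sites, sites[1:50, ],
                            c(chr1 = 50000L, chr2 = 50000L), B = 1, seed = 1)
  sg <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos + 1L, width = 1L))
  ig <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  expect_equal(res$n_overlap_cpg, sum(IRanges::overlapsAny(sg, ig)))
  expect_equal(res$n_overlap_dms, sum(IRanges::overlapsAny(sg[1:50], ig)))
})
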