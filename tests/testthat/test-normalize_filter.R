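test_that("library normalization equalizes column totals", {
  x <- make_set(cbind(c(10, 90), c(40, 160)), groups = c("a", "a"))
  xn <- normalize_libraries(x)  # totals 100, 200 -> target 150
  expect_equal(unname(xn$norm_factors), c(1.5, 0.75))
  expect_equal(unname(xn$df[1, 1]), 15)
  expect_equal(unname(colSums(xn$df)), c(150, 150))

  # single library: identity
  x1 <- make_set(matrix(c(3, 7)), groups = "a")
  expect_equal(normalize_libraries(x1)$df, x1$counts + 0)

  # rank order within a library is preserved
  set.seed(1)
  xr <- normalize_libraries(make_set(matrix(rpois(40, 10), 10, 4),
                                     groups = rep("a", 4)))
  for (j in 1:4)
    expect_equal(order(xr$df[, j]), order(xr$counts[, j]))

  xz <- make_set(cbind(c(1, 1), c(0, 0)), groups = c("a", "a"))
  expect_error(normalize_libraries(xz), "zero-total")
})

test_that("per-CGI mean df matches a brute-force per-interval mean", {
  set.seed(11)
  x <- normalize_libraries(make_set(matrix(rpois(200 * 4, 20), 200, 4),
                                    groups = rep(c("a", "b"), 2),
                                    pos = sort(sample(0:9999, 200))))
  cgis <- interval_set("chr1", c(0, 2500, 9990), c(1200, 6000, 9995),
                       kind = "cgi")
  got <- cgi_mean_df(x, cgis)
  for (i in seq_len(nrow(cgis))) {
    inside <- x$sites$pos >= cgis$start[i] & x$sites$pos < cgis$end[i]
    if (!any(inside)) next
    expect_equal(unname(got[paste0("chr1:", cgis$start[i], "-", cgis$end[i]), ]),
                 unname(colMeans(x$df[inside, , drop = FALSE])))
  }
  # an interval with no sites is omitted and counted
  empty <- interval_set("chr1", 10500, 10600)
  got2 <- cgi_mean_df(x, empty)
  expect_equal(nrow(got2), 0L)
  expect_equal(attr(got2, "n_empty"), 1L)

  # hand example: sites with df 20 and 30 average to 25
  xh <- normalize_libraries(make_set(cbind(c(20, 30)), groups = "a",
                                     pos = c(10, 20)))
  expect_equal(unname(cgi_mean_df(xh, interval_set("chr1", 0, 100))[1, 1]), 25)
})

test_that("valley cutoff lands between the two modes", {
  set.seed(5)
  scores <- c(rnorm(1000, 3, 1), rnorm(1000, 26, 4))
  res <- find_valley_cutoff(scores)
  expect_equal(res$method, "valley")
  expect_gt(res$cutoff, 8); expect_lt(res$cutoff, 18)
  expect_lt(res$mode_low, res$cutoff)
  expect_gt(res$mode_high, res$cutoff)

  # independent grid-search oracle on the same kernel-smoothed density
  d <- density(scores, n = 2048)
  grid <- d$x > 5 & d$x < 24
  oracle <- d$x[grid][which.min(d$y[grid])]
  expect_lt(abs(res$cutoff - oracle), 1.5)

  # permutation invariance
  res2 <- find_valley_cutoff(sample(scores))
  expect_equal(res2$cutoff, res$cutoff)

  # two point masses: cutoff strictly inside
  res3 <- find_valley_cutoff(rep(c(0, 50), each = 200))
  expect_gt(res3$cutoff, 0); expect_lt(res3$cutoff, 50)
})

test_that("unimodal scores fall back to the fixed cutoff", {
  set.seed(6)
  uni <- rnorm(2000, 20, 2)
  expect_warning(res <- find_valley_cutoff(uni), "fixed")
  expect_equal(res$method, "fixed")
  expect_equal(res$cutoff, 10)
  expect_error(suppressWarnings(
    find_valley_cutoff(rep(1, 50), fixed_default = NULL)), "no fixed")
})

test_that("prefilter keeps sites reaching the cutoff in any library", {
  df <- rbind(c(10, 0, 0), c(9.99, 9, 5), c(0, 0, 0), c(50, 50, 50))
  x <- normalize_libraries(make_set(df, groups = c("a", "a", "b")))
  x$df <- df  # use the raw values as df to test the rule exactly
  kept <- prefilter_sites(x, 10)
  expect_equal(kept$sites$site_id, x$sites$site_id[c(1, 4)])
  expect_equal(attr(kept, "n_removed"), 2L)

  # brute-force row-max oracle on random data
  set.seed(12)
  xr <- normalize_libraries(make_set(matrix(rpois(600, 8), 100, 6),
                                     groups = rep(c("a", "b"), 3)))
  kept_r <- prefilter_sites(xr, 12)
  expect_equal(kept_r$sites$site_id,
               xr$sites$site_id[apply(xr$df, 1, max) >= 12])

  # per-group variant: needs the cutoff in one library of every group
  x2 <- normalize_libraries(make_set(rbind(c(20, 0), c(20, 20)),
                                     groups = c("a", "b")))
  x2$df <- rbind(c(20, 0), c(20, 20))
  expect_equal(nrow(prefilter_sites(x2, 10, per_group = TRUE)$counts), 1L)
})

test_that("region statistics reproduce the 3' exon fold-change arithmetic", {
  groups <- rep(c("B", "K", "L", "T"), each = 3)
  # constant replicates so the region group means are exactly as printed
  df <- matrix(rep(c(3.1, 2.0, 1.7, 36.6), each = 3), 1)
  x <- make_set(df, groups = groups, pos = 10L)
  x$df <- df
  rs <- region_stats(x, interval_set("chr1", 0, 100), focal_group = "T")
  expect_equal(rs$fold_change, 36.6 / mean(c(3.1, 2.0, 1.7)), tolerance = 1e-12)
  expect_lt(abs(rs$fold_change - 16.2), 0.1)  # printed value, rounded inputs

  # equal group means give fold 1; empty regions are flagged
  df2 <- matrix(5, 1, 12)
  x2 <- make_set(df2, groups = groups, pos = 10L); x2$df <- df2
  rs2 <- region_stats(x2, interval_set("chr1", c(0, 500), c(100, 600)), "T")
  expect_equal(rs2$fold_change[1], 1)
  expect_true(rs2$empty[2])
  expect_true(is.na(rs2$fold_change[2]))

  # two-group hand computation
  dfh <- rbind(c(4, 6, 1, 3), c(10, 10, 2, 2))
  xh <- make_set(dfh, groups = c("a", "a", "b", "b"), pos = c(10L, 20L))
  xh$df <- dfh
  rsh <- region_stats(xh, interval_set("chr1", 0, 100), "a")
  expect_equal(rsh$a, mean(c(5, 10)))
  expect_equal(rsh$b, mean(c(2, 2)))
  expect_equal(rsh$fold_change, 7.5 / 2)
})
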