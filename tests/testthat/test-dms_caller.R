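test_that("Welch test matches the closed form and stats::t.test", {
  w <- welch_test(c(10, 12, 14), c(30, 33, 36))
  expect_equal(w$t, -10.088, tolerance = 1e-3)
  expect_equal(w$welch_df, 3.4846, tolerance = 1e-3)
  ref <- t.test(c(10, 12, 14), c(30, 33, 36))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)

  # symmetry: swapping groups negates t, keeps p
  w2 <- welch_test(c(30, 33, 36), c(10, 12, 14))
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p_value, w$p_value)

  # degenerate variances
  expect_equal(welch_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  wz <- welch_test(c(5, 5, 5), c(9, 9, 9))
  expect_lt(wz$p_value, 1e-6)  # variance floor makes the difference decisive

  expect_error(welch_test(1, c(1, 2)), ">= 2 replicates")
})

test_that("vectorized pairwise Welch agrees with per-site t.test calls", {
  set.seed(31)
  mat <- matrix(rnorm(50 * 12, 20, 4), 50, 12)
  groups <- rep(c("B", "K", "L", "T"), each = 3)
  w <- welch_pairs(mat, groups)
  expect_equal(dim(w$p), c(50, 6))
  for (i in c(1, 17, 50)) {
    for (j in seq_len(6)) {
      a <- mat[i, groups == w$pairs$a[j]]
      b <- mat[i, groups == w$pairs$b[j]]
      ref <- t.test(a, b)
      expect_equal(unname(w$t[i, j]), unname(ref$statistic), tolerance = 1e-10)
      expect_equal(unname(w$welch_df[i, j]), unname(ref$parameter), tolerance = 1e-10)
      expect_equal(unname(w$p[i, j]), ref$p.value, tolerance = 1e-10)
    }
  }
  # direction matches the sign of the group-mean difference
  expect_true(all(sign(w$t) == sign(w$diff) | w$diff == 0))
})

test_that("standardized residuals are centered and scaled per site", {
  r <- standardized_residuals(matrix(c(1, 2, 3), 1))
  expect_equal(unname(r$residuals[1, ]), c(-1, 0, 1))

  rc <- standardized_residuals(matrix(5, 2, 4))
  expect_true(all(rc$flagged))
  expect_true(all(is.na(rc$residuals)))

  set.seed(13)
  m <- matrix(rnorm(200), 20, 10)
  rr <- standardized_residuals(m)$residuals
  expect_equal(unname(rowMeans(rr)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(rr, 1, sd)), rep(1, 20), tolerance = 1e-12)
})

test_that("QQ diagnostics track normality", {
  set.seed(17)
  qnorm_res <- qq_normality(rnorm(10000))
  expect_gt(qnorm_res$correlation, 0.99)

  sym <- c(-3, -2, -1, -0.5, -0.1, 0.1, 0.5, 1, 2, 3)
  qs <- qq_normality(sym)
  expect_equal(qs$empirical, -rev(qs$empirical))
  expect_equal(qs$theoretical, -rev(qs$theoretical))

  qheavy <- qq_normality(rt(10000, df = 2))
  expect_lt(qheavy$correlation, qnorm_res$correlation)
})

test_that("two-stage mdFDR selection follows the hand-traced rule", {
  # all p = 1: nothing selected
  none <- mdfdr_select(matrix(1, 10, 6), matrix(1, 10, 6), alpha = 0.1)
  expect_equal(none$R, 0L)
  expect_false(any(none$sig))

  # single site, one strong pair
  p <- matrix(c(0.001, rep(0.9, 5)), 1)
  tm <- matrix(c(3, rep(0.1, 5)), 1)
  sel <- mdfdr_select(p, tm, alpha = 0.1)
  expect_true(sel$selected[1])
  expect_equal(sel$p_screen[1], 0.006)
  expect_equal(sel$stage2_threshold, 0.1 / 6)
  expect_equal(unname(which(sel$sig[1, ])), 1L)
  expect_equal(unname(sel$direction[1, 1]), 1)

  expect_error(mdfdr_select(matrix(1.5, 1, 2), matrix(1, 1, 2), 0.1),
               "outside")

  # alpha = 0 selects nothing even with p = 0
  sel0 <- mdfdr_select(matrix(0, 3, 2), matrix(1, 3, 2), alpha = 0)
  expect_equal(sel0$R, 0L)
})

test_that("mdFDR rejections are monotone in alpha", {
  set.seed(23)
  p <- matrix(rbeta(500 * 6, 0.5, 3), 500, 6)
  tm <- matrix(rnorm(500 * 6), 500, 6)
  prev <- rep(FALSE, 500)
  for (a in c(0.01, 0.05, 0.1, 0.2, 0.4)) {
    sel <- mdfdr_select(p, tm, a)
    expect_true(all(which(prev) %in% which(sel$selected)))
    prev <- sel$selected
  }
})

test_that("minimum-difference filtering and TS classification follow the rules", {
  expect_true(min_diff_filter(TRUE, 30 - 5, delta = 10))
  expect_false(min_diff_filter(TRUE, 12 - 5, delta = 10))
  expect_true(min_diff_filter(TRUE, 10, delta = 10))  # inclusive at delta

  groups <- c("B", "K", "L", "T")
  pairs <- data.frame(a = c("B", "B", "B", "K", "K", "L"),
                      b = c("K", "L", "T", "L", "T", "T"))
  # testis higher in all its three pairs: T appears as 'b' -> negative diffs
  sig <- matrix(c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE), 1)
  diff <- matrix(c(0, 0, -25, 0, -25, -25), 1)
  expect_equal(classify_ts(sig, diff, pairs, groups), "ts_unmeth(T)")
  expect_equal(classify_ts(sig, -diff, pairs, groups), "ts_meth(T)")

  # only two of the three testis pairs: plain dms
  sig2 <- matrix(c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE), 1)
  expect_equal(classify_ts(sig2, diff, pairs, groups), "dms")

  # extra significant pair elsewhere blocks strict TS
  sig3 <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE), 1)
  diff3 <- matrix(c(12, 0, -25, 0, -25, -25), 1)
  expect_equal(classify_ts(sig3, diff3, pairs, groups), "dms")
  expect_equal(classify_ts(sig3, diff3, pairs, groups, strict = FALSE),
               "ts_unmeth(T)")

  sig4 <- matrix(FALSE, 1, 6)
  expect_equal(classify_ts(sig4, diff, pairs, groups), "not_dms")
})

test_that("the caller finds planted hypomethylated sites and no phantoms", {
  # null: no planted effects -> essentially no TS-DMS
  null_cfg <- sim_config(n_sites = 3000, frac_ts_unmeth = 0,
                         frac_ts_meth = 0, n_spikein_sites = 0, seed = 41)
  null_call <- call_dms(simulate_methylome(null_cfg)$set, alpha = 0.1)
  expect_lte(null_call$report$n_ts_dms, 2)

  # planted ts_unmeth only: every recovered TS class is ts_unmeth
  cfg <- sim_config(n_sites = 2000, frac_methylated_everywhere = 0.75,
                    frac_ts_unmeth = 0.05, frac_ts_meth = 0,
                    n_spikein_sites = 0, seed = 43)
  sim <- simulate_methylome(cfg)
  call <- call_dms(sim$set, alpha = 0.1)
  cls <- call$table$class
  expect_gt(sum(startsWith(cls, "ts_unmeth")), 0)
  expect_equal(sum(startsWith(cls, "ts_meth")), 0)

  # recovered TS labels match the planted group
  ts <- ts_dms(call)
  truth <- sim$truth$ts_label[match(ts$site_id, sim$truth$site_id)]
  got <- sub("^ts_unmeth\\((.*)\\)$", "ts_unmeth:\\1", ts$class)
  expect_gt(mean(got == truth), 0.9)

  # structural invariants: TS subset of DMS, per-group sets disjoint
  expect_true(all(ts$class != "not_dms"))
  expect_equal(call$report$n_ts_dms,
               sum(call$report$hypo_per_group) +
                 sum(call$report$hyper_per_group))
  expect_lte(call$report$n_ts_dms, call$report$n_dms)

  # directional coherence of every significant pair
  expect_true(all(sign(call$diff[call$sig]) != 0))

  # alpha = 0: nothing selected
  call0 <- call_dms(sim$set, alpha = 0)
  expect_equal(call0$report$n_dms, 0L)
})

test_that("unequal replicate designs are supported end to end", {
  # nutritional-history style design: 4 diet groups with 4/5/2/5 litters
  cfg <- sim_config(n_sites = 1200,
                    groups = c(CC = 4, CU = 5, UC = 2, UU = 5),
                    frac_ts_unmeth = 0.03, n_spikein_sites = 0, seed = 61)
  sim <- simulate_methylome(cfg)
  call <- call_dms(sim$set, alpha = 0.15)
  expect_equal(sort(call$groups), c("CC", "CU", "UC", "UU"))
  expect_equal(ncol(call$p), choose(4, 2))
  expect_gte(call$report$n_dms, 0)
  # group means come from the right replicate counts
  expect_equal(sum(sim$set$samples$group == "UC"), 2L)
  w <- welch_pairs(normalize_libraries(sim$set)$df, sim$set$samples$group)
  i <- which(w$pairs$a == "CC" & w$pairs$b == "UC")[1]
  a_vals <- normalize_libraries(sim$set)$df[5, sim$set$samples$group == "CC"]
  b_vals <- normalize_libraries(sim$set)$df[5, sim$set$samples$group == "UC"]
  ref <- t.test(a_vals, b_vals)
  expect_equal(unname(w$t[5, i]), unname(ref$statistic), tolerance = 1e-10)
})
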