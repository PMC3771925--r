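#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the operative
#' defaults: mdFDR level 0.10 (0.15 for the nutritional-history design),
#' valley-derived df cutoff with fixed fallback 10, minimum group-mean
#' difference equal to the cutoff, TSS window -3/+2 kb, 3' region 3 kb,
#' shores 2 kb, gene association flank 3 kb, and a seeded permutation
#' count.
#'
#' @param out_dir where `run_all()` writes its artifacts.
#' @param sim a [sim_config()] for the synthetic methylome.
#' @param alpha mdFDR level.
#' @param cutoff `"valley"` or a fixed df value.
#' @param fixed_cutoff fallback when the valley is undetectable.
#' @param delta minimum-difference value (`NULL`: use the cutoff).
#' @param tss_up,tss_down,three_prime_len,shore_width,gene_flank
#'   annotation window sizes in bp.
#' @param B permutation iterations for enrichment p-values.
#' @param n_calib_reps spike-in calibration replicates.
#' @param heatmap render the heatmap png.
#' @param seed master seed; every stage derives its stream from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("msccdm_run_"),
                       sim = sim_config(),
                       alpha = 0.10, cutoff = "valley", fixed_cutoff = 10,
                       delta = NULL, tss_up = 3000, tss_down = 2000,
                       three_prime_len = 3000, shore_width = 2000,
                       gene_flank = 3000, B = 200, n_calib_reps = 20,
                       heatmap = TRUE, seed = 1) {
  stopifnot(alpha >= 0, alpha < 1,
            all(c(tss_up, tss_down, three_prime_len, shore_width,
                  gene_flank) > 0))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis end to end
#'
#' Simulates a toy genome and methylome, normalizes, derives the df
#' cutoff from the CGI score distribution, calls DMS/TS-DMS, calibrates
#' the empirical false-discovery rate on the spike-in block, annotates
#' the TS-DMS against genes and CGIs, computes expression odds ratios and
#' enhancer fold enrichments with permutation p-values, clusters the
#' samples on the TS-DMS signature, and writes every artifact with a
#' checksum manifest. Identical config and seed give identical manifests.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: per-stage counts, calibration
#'   summary, enrichment and association tables, clustering purity, the
#'   thresholds actually applied, and the output manifest.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  groups <- names(config$sim$groups)

  # stage: simulate (genome layout + counts; seeded sub-streams)
  toy <- simulate_toy_genome(out_dir = config$out_dir, groups = groups,
                             seed = config$seed)
  simcfg <- config$sim
  simcfg$seed <- config$seed + 1L
  sim <- simulate_methylome(simcfg, layout = list(sites = toy$sites,
                                                  preset = toy$preset))
  write_counts(sim$set, p("counts.tsv"))
  write_sample_sheet(sim$set$samples, p("samples.csv"))
  utils::write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # stage: normalize + cutoff
  x <- normalize_libraries(sim$set)
  scores <- as.vector(cgi_mean_df(x, toy$cgis))
  cutoff <- if (identical(config$cutoff, "valley"))
    find_valley_cutoff(scores, fixed_default = config$fixed_cutoff)
  else config$cutoff
  cut_val <- if (inherits(cutoff, "cutoff_result")) cutoff$cutoff else cutoff
  delta <- if (is.null(config$delta)) cut_val else config$delta

  # stage: call DMS on the genomic rows
  gx <- genomic_rows(x)
  dms <- call_dms(gx, alpha = config$alpha, cutoff = cut_val, delta = delta)
  utils::write.table(dms$table, p("dms_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage: spike-in calibration
  calib <- empirical_fdr(x, alpha = config$alpha)

  # stage: annotation of TS-DMS
  ts <- ts_dms(dms)
  ts_sites <- gx$sites[match(ts$site_id, gx$sites$site_id), , drop = FALSE]
  ann <- data.frame(
    site_id = ts$site_id, class = ts$class,
    gene_region = classify_gene_region(ts_sites, toy$genes,
                                       config$tss_up, config$tss_down,
                                       config$three_prime_len),
    cgi_region = classify_cgi_region(ts_sites, toy$cgis,
                                     config$shore_width))
  assoc <- associate_genes(ts_sites, toy$genes, config$gene_flank)
  ann$gene_id <- assoc$gene_id
  ann$strength <- assoc$strength
  utils::write.table(ann, p("annotation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # stage: enrichment (per group: expression OR, enhancer fold + perm p)
  enrich <- list()
  for (g in groups) {
    gsub_ts <- ts_sites[ts$class == sprintf("ts_unmeth(%s)", g), ,
                        drop = FALSE]
    ex <- expression_association(
      assoc$gene_id[ts$class == sprintf("ts_unmeth(%s)", g)],
      toy$expression, g)
    pe <- if (nrow(gsub_ts) > 0)
      permutation_pvalue(toy$enhancers[toy$enhancers$name == g, ,
                                       drop = FALSE],
                         toy$sites, gsub_ts, toy$chrom_lengths,
                         B = config$B, seed = config$seed + 2L)
    else NULL
    enrich[[g]] <- list(expression = ex, enhancers = pe)
  }
  jsonlite::write_json(
    lapply(enrich, function(e) list(
      odds_ratio = e$expression$test$or, or_p = e$expression$test$p_value,
      fold = if (is.null(e$enhancers)) NA else e$enhancers$fold,
      p_perm = if (is.null(e$enhancers)) NA else e$enhancers$p_perm)),
    p("enrichment.json"), auto_unbox = TRUE, digits = NA)

  # stage: clustering on TS-DMS signature
  clust <- NULL
  if (nrow(ts) >= 2 &&
      all(apply(signature_matrix(x, ts$site_id), 2, stats::sd) > 0)) {
    sm <- signature_matrix(x, ts$site_id)
    d <- correlation_distance(sm)
    hc <- hierarchical_cluster(d)
    purity <- cluster_purity(hc, x$samples$group, k = length(groups))
    dendrogram_newick(hc, p("dendrogram.nwk"))
    if (isTRUE(config$heatmap))
      render_heatmap(sm, hc, p("heatmap.png"), first_n = 40)
    clust <- list(purity = purity, dendrogram = hc)
  }

  files <- setdiff(list.files(config$out_dir), "heatmap.png")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(p(files))))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(
    report = dms$report,
    counts = c(sites_surveyed = nrow(sim$set$counts),
               genomic_sites = sum(!sim$set$sites$is_spikein),
               spikein_sites = sum(sim$set$sites$is_spikein),
               retained = dms$report$n_retained,
               dms = dms$report$n_dms, ts_dms = dms$report$n_ts_dms),
    cutoff = cutoff, delta = delta, alpha = config$alpha,
    calibration = calib,
    annotation = ann, association = assoc, enrichment = enrich,
    clustering = clust, truth = sim$truth, dms = dms,
    manifest = manifest, out_dir = config$out_dir),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (alpha", x$alpha, ", cutoff",
      format(if (inherits(x$cutoff, "cutoff_result")) x$cutoff$cutoff
             else x$cutoff, digits = 3), ")\n")
  print(x$counts)
  print(x$calibration)
  if (!is.null(x$clustering))
    cat("clustering purity:", x$clustering$purity, "\n")
  invisible(x)
}
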