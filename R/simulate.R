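#' Configuration for the synthetic methylome generator
#'
#' Defaults describe the study design the package emulates: four tissues
#' with three replicate libraries each, bimodal per-site digestion
#' frequencies (unmethylated-high around 30, methylated-low around 2), a
#' small planted fraction of tissue-specific sites dominated by
#' hypomethylation, an all-unmethylated lambda spike-in block of 1,202
#' sites shared by every library, and multiplicative library-size
#' variation.
#'
#' @param n_sites number of genomic (non-spike-in) sites.
#' @param groups named integer vector: replicates per group. Unequal
#'   designs (e.g. `c(CC = 4, CU = 5, UC = 2, UU = 5)`) are supported.
#' @param frac_methylated_everywhere proportion of sites methylated in all
#'   groups (mammalian genomes: roughly 70-80% of CpGs).
#' @param frac_ts_unmeth,frac_ts_meth per-group proportion of sites
#'   unmethylated (resp. methylated) in exactly that group. Hypermethylated
#'   tissue-specific sites default to 10x rarer, mirroring the observed
#'   dominance of hypomethylated TS-DMS.
#' @param mu_unmeth,mu_meth mean normalized count for unmethylated and
#'   methylated sites (digestion-frequency scale).
#' @param dispersion negative-binomial size parameter; `Inf` gives the
#'   Poisson limit. The default 50 (CV ~23% at the unmethylated mean)
#'   models isogenic-mouse triplicates: near-technical counting noise with
#'   mild biological overdispersion.
#' @param libsize_factors per-sample depth multipliers; `NULL` draws them
#'   from `Uniform(libsize_range)`.
#' @param libsize_range range for drawn library-size factors.
#' @param n_spikein_sites size of the spike-in block (lambda convention:
#'   1,202 fully unmethylated sites).
#' @param seed integer seed, or `NULL` to continue the caller's RNG stream
#'   (used by replicate loops).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10000,
                       groups = c(brain = 3, kidney = 3, liver = 3, testis = 3),
                       frac_methylated_everywhere = 0.75,
                       frac_ts_unmeth = 0.01,
                       frac_ts_meth = 0.001,
                       mu_unmeth = 30,
                       mu_meth = 2,
                       dispersion = 50,
                       libsize_factors = NULL,
                       libsize_range = c(0.7, 1.3),
                       n_spikein_sites = 1202,
                       seed = 1) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of replicate counts")
  k <- length(groups)
  props <- frac_methylated_everywhere + k * (frac_ts_unmeth + frac_ts_meth)
  if (any(c(frac_methylated_everywhere, frac_ts_unmeth, frac_ts_meth) < 0) ||
      props > 1)
    stop("state proportions must be in [0,1] and sum to at most 1")
  if (!(mu_unmeth > mu_meth && mu_meth >= 0))
    stop("need mu_unmeth > mu_meth >= 0")
  if (dispersion <= 0) stop("dispersion must be positive (Inf = Poisson)")
  structure(list(n_sites = n_sites, groups = groups,
                 frac_methylated_everywhere = frac_methylated_everywhere,
                 frac_ts_unmeth = frac_ts_unmeth,
                 frac_ts_meth = frac_ts_meth,
                 mu_unmeth = mu_unmeth, mu_meth = mu_meth,
                 dispersion = dispersion,
                 libsize_factors = libsize_factors,
                 libsize_range = libsize_range,
                 n_spikein_sites = n_spikein_sites, seed = seed),
            class = "sim_config")
}

# Negative-binomial draw with Poisson limit and exact-zero mean support.
.rcounts <- function(n, mu, size) {
  out <- numeric(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (is.infinite(size)) stats::rpois(sum(pos), mu[pos])
                else stats::rnbinom(sum(pos), mu = mu[pos], size = size)
  }
  out
}

#' Simulate a methylome count experiment with planted truth
#'
#' Draws negative-binomial counts per (site, sample) with mean equal to
#' the site's state mean in that sample's group times the sample's
#' library-size factor, appends a spike-in block that is unmethylated in
#' every sample, and returns the ground-truth state table.
#'
#' @param config a [sim_config()].
#' @param layout optional site layout from [simulate_toy_genome()]: a list
#'   with `sites` (site table) and `preset` (per-site state labels: `NA`
#'   for free assignment, `"meth"`, `"unmeth"`, `"ts_unmeth:<group>"` or
#'   `"ts_meth:<group>"`). Overrides `config$n_sites`.
#' @return list with `set` (an [mscc_set]) and `truth` (data.frame:
#'   `site_id`, one `state_<group>` column per group, `ts_label`).
#' @export
simulate_methylome <- function(config = sim_config(), layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$groups < 2))
    stop("every group needs at least 2 replicates for the Welch test")
  if (!is.null(config$seed)) set.seed(config$seed)
  gnames <- names(config$groups)
  k <- length(gnames)

  if (is.null(layout)) {
    n <- config$n_sites
    labels <- c("meth",
                paste0("ts_unmeth:", gnames), paste0("ts_meth:", gnames),
                "unmeth")
    probs <- c(config$frac_methylated_everywhere,
               rep(config$frac_ts_unmeth, k), rep(config$frac_ts_meth, k))
    probs <- c(probs, max(0, 1 - sum(probs)))
    state <- sample(labels, n, replace = TRUE, prob = probs)
    sites <- data.frame(site_id = sprintf("chrS:%d", seq_len(n) * 50L),
                        chrom = rep("chrS", n), pos = seq_len(n) * 50L,
                        motif = rep("CCGG", n), strand = rep("+", n),
                        is_spikein = rep(FALSE, n))
  } else {
    sites <- layout$sites
    n <- nrow(sites)
    state <- layout$preset
    free <- is.na(state)
    if (any(free)) {
      pm <- config$frac_methylated_everywhere
      state[free] <- sample(c("meth", "unmeth"), sum(free), replace = TRUE,
                            prob = c(pm, 1 - pm))
    }
    if (is.null(sites$is_spikein)) sites$is_spikein <- FALSE
  }

  state_mu <- matrix(config$mu_meth, n, k, dimnames = list(NULL, gnames))
  state_mu[state == "unmeth", ] <- config$mu_unmeth
  for (g in gnames) {
    state_mu[state == paste0("ts_unmeth:", g), ] <- config$mu_meth
    state_mu[state == paste0("ts_unmeth:", g), g] <- config$mu_unmeth
    state_mu[state == paste0("ts_meth:", g), ] <- config$mu_unmeth
    state_mu[state == paste0("ts_meth:", g), g] <- config$mu_meth
  }

  nsp <- config$n_spikein_sites
  if (nsp > 0) {
    sp_sites <- data.frame(
      site_id = sprintf("lambda:%d", seq_len(nsp) * 40L),
      chrom = "lambda", pos = seq_len(nsp) * 40L, motif = "CCGG",
      strand = "+", is_spikein = TRUE)
    sites <- rbind(sites[c("site_id", "chrom", "pos", "motif", "strand",
                           "is_spikein")], sp_sites)
    state_mu <- rbind(state_mu,
                      matrix(config$mu_unmeth, nsp, k,
                             dimnames = list(NULL, gnames)))
    state <- c(state, rep("unmeth", nsp))
  }

  samples <- data.frame(
    sample_id = unlist(lapply(gnames, function(g)
      paste0(g, "_", seq_len(config$groups[[g]])))),
    group = rep(gnames, config$groups),
    replicate = unlist(lapply(config$groups, seq_len)),
    is_spikein_present = nsp > 0)
  ns <- nrow(samples)
  fac <- config$libsize_factors
  if (is.null(fac))
    fac <- stats::runif(ns, config$libsize_range[1], config$libsize_range[2])
  if (length(fac) != ns) stop("libsize_factors must have one entry per sample")

  counts <- matrix(vapply(seq_len(ns), function(s)
    .rcounts(nrow(state_mu), state_mu[, samples$group[s]] * fac[s],
             config$dispersion),
    numeric(nrow(state_mu))), nrow = nrow(state_mu))

  truth <- data.frame(site_id = sites$site_id)
  for (g in gnames) {
    st <- rep("meth", length(state))
    st[state == "unmeth" | state == paste0("ts_unmeth:", g)] <- "unmeth"
    st[startsWith(state, "ts_meth:") & state != paste0("ts_meth:", g)] <- "unmeth"
    truth[[paste0("state_", g)]] <- st
  }
  truth$ts_label <- ifelse(startsWith(state, "ts_"), state, "none")

  list(set = mscc_set(counts, sites, samples), truth = truth)
}

#' Simulate a toy genome with annotations and planted enrichment
#'
#' Generates a random genome, enumerates its recognition sites, lays down
#' CpG islands (with coherent all-methylated or all-unmethylated states),
#' per-group enhancer sets, and gene models with a tissue-expression call
#' table, and plants tissue-specific sites inside group-matched enhancers
#' at a configured fold-enrichment ratio.
#'
#' @param out_dir directory to write `genome.fa`, `genes.tsv`, `cgis.bed`,
#'   `enhancers.bed` and `expression.tsv` into; `NULL` skips writing.
#' @param groups group names.
#' @param n_chroms,chrom_length genome shape.
#' @param n_cgis,cgi_length CpG-island count and length; each CGI is
#'   assigned a coherent methylation state (`frac_cgi_meth` methylated).
#' @param n_enhancers_per_group,enhancer_length enhancer sets, one per
#'   group (BED name column carries the group).
#' @param n_genes,gene_length gene models with random strand.
#' @param frac_ts per-group fraction of sites planted tissue-specific
#'   (unmethylated in that group only).
#' @param enrichment target fold enrichment of planted sites in the
#'   group-matched enhancer set (1 = null placement).
#' @param frac_cgi_meth fraction of CGIs methylated in all groups.
#' @param expr_assoc probability that a gene within 3 kb of a planted
#'   tissue-specific site is called uniquely expressed in that tissue.
#' @param expr_base baseline probability of unique expression.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list with `genome` (named character), `sites`, `cgis`,
#'   `enhancers`, `genes`, `expression`, `preset` (per-site state labels
#'   for [simulate_methylome()]), `ts_truth` and, when `out_dir` is given,
#'   `paths`.
#' @export
simulate_toy_genome <- function(out_dir = NULL,
                                groups = c("brain", "kidney", "liver", "testis"),
                                n_chroms = 2, chrom_length = 150000,
                                n_cgis = 30, cgi_length = 600,
                                n_enhancers_per_group = 12,
                                enhancer_length = 1000,
                                n_genes = 40, gene_length = 4000,
                                frac_ts = 0.01, enrichment = 5,
                                frac_cgi_meth = 0.5,
                                expr_assoc = 0.6, expr_base = 0.25,
                                seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (max(cgi_length, enhancer_length, gene_length) > chrom_length)
    stop("requested features exceed the chromosome length")
  total_feat <- n_cgis * cgi_length +
    length(groups) * n_enhancers_per_group * enhancer_length +
    n_genes * gene_length
  if (total_feat > n_chroms * chrom_length)
    stop("requested features exceed the genome length")

  chroms <- sprintf("chr%d", seq_len(n_chroms))
  genome <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = ""), "")
  sites <- enumerate_sites(genome)

  rand_iv <- function(n, len) {
    ch <- sample(chroms, n, replace = TRUE)
    st <- vapply(ch, function(x)
      sample.int(chrom_length - len, 1L) - 1L, integer(1))
    data.frame(chrom = ch, start = st, end = st + len)
  }
  cgis <- rand_iv(n_cgis, cgi_length)
  cgis$name <- sprintf("cgi%03d", seq_len(n_cgis))
  cgis <- interval_set(cgis$chrom, cgis$start, cgis$end, cgis$name, "cgi")

  enh <- rand_iv(length(groups) * n_enhancers_per_group, enhancer_length)
  enh$name <- rep(groups, each = n_enhancers_per_group)
  enhancers <- interval_set(enh$chrom, enh$start, enh$end, enh$name,
                            "enhancer")

  genes <- rand_iv(n_genes, gene_length)
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = genes$chrom, strand = sample(c("+", "-"),
                      n_genes, replace = TRUE),
                      start = genes$start, end = genes$end)

  in_iv <- function(iv) {
    hits <- GenomicRanges::findOverlaps(.site_granges(sites), .iv_granges(iv))
    unique(S4Vectors_queryHits(hits))
  }

  preset <- rep(NA_character_, nrow(sites))
  in_cgi_state <- sample(c("meth", "unmeth"), n_cgis, replace = TRUE,
                         prob = c(frac_cgi_meth, 1 - frac_cgi_meth))
  hits <- GenomicRanges::findOverlaps(.site_granges(sites), .iv_granges(cgis))
  preset[S4Vectors_queryHits(hits)] <- in_cgi_state[S4Vectors_subjectHits(hits)]

  n_ts <- round(frac_ts * nrow(sites))
  for (g in groups) {
    gset <- enhancers[enhancers$name == g, , drop = FALSE]
    idx_in <- setdiff(in_iv(gset), which(!is.na(preset)))
    idx_out <- setdiff(seq_len(nrow(sites)),
                       union(which(!is.na(preset)), in_iv(enhancers)))
    bg <- length(in_iv(gset)) / nrow(sites)
    want_in <- min(length(idx_in), round(n_ts * min(1, enrichment * bg)))
    want_out <- max(0, n_ts - want_in)
    pick <- c(sample(idx_in, want_in),
              sample(idx_out, min(want_out, length(idx_out))))
    preset[pick] <- paste0("ts_unmeth:", g)
  }

  ts_truth <- data.frame(site_id = sites$site_id,
                         ts_label = ifelse(is.na(preset) |
                                           !startsWith(preset, "ts_"),
                                           "none", preset))

  # expression calls: unique expression follows planted TS association
  gg <- .iv_granges(data.frame(chrom = genes$chrom,
                               start = pmax(0L, genes$start - 3000L),
                               end = genes$end + 3000L))
  expr <- matrix(FALSE, n_genes, length(groups),
                 dimnames = list(genes$gene_id, groups))
  ts_idx <- which(startsWith(ifelse(is.na(preset), "", preset), "ts_"))
  ov <- GenomicRanges::findOverlaps(.site_granges(sites[ts_idx, , drop = FALSE]), gg)
  assoc_group <- tapply(sub("^ts_unmeth:", "", preset[ts_idx][S4Vectors_queryHits(ov)]),
                        S4Vectors_subjectHits(ov), function(x) x[1])
  for (i in seq_len(n_genes)) {
    ag <- if (as.character(i) %in% names(assoc_group))
      assoc_group[[as.character(i)]] else NULL
    if (!is.null(ag) && !is.na(ag) && stats::runif(1) < expr_assoc) {
      expr[i, ag] <- TRUE
    } else if (stats::runif(1) < expr_base) {
      expr[i, sample(length(groups), 1)] <- TRUE
    } else {
      expr[i, sample(length(groups), sample(2:length(groups), 1))] <- TRUE
    }
  }
  expression <- data.frame(gene_id = genes$gene_id, expr, row.names = NULL)

  out <- list(genome = genome, sites = sites, cgis = cgis,
              enhancers = enhancers, genes = genes, expression = expression,
              preset = preset, ts_truth = ts_truth,
              chrom_lengths = stats::setNames(rep(chrom_length, n_chroms),
                                              chroms))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), p("genome.fa"))
    write_intervals(cgis, p("cgis.bed"))
    write_intervals(enhancers, p("enhancers.bed"))
    write_genes(genes, p("genes.tsv"))
    utils::write.table(expression, p("expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- c(genome = p("genome.fa"), cgis = p("cgis.bed"),
                   enhancers = p("enhancers.bed"), genes = p("genes.tsv"),
                   expression = p("expression.tsv"))
  }
  out
}

# Avoid hard S4Vectors import churn: queryHits/subjectHits shims.
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)
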