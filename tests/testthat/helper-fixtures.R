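# Small in-code fixtures shared across the suite.

# Build an mscc_set from a bare count matrix; sites are laid out 100 bp
# apart on one chromosome unless positions are given.
make_set <- function(counts, groups, pos = NULL, chrom = "chr1",
                     spike = rep(FALSE, nrow(counts))) {
  counts <- as.matrix(counts)
  if (is.null(pos)) pos <- seq_len(nrow(counts)) * 100L
  sites <- data.frame(site_id = paste(chrom, pos, sep = ":"),
                      chrom = chrom, pos = pos, motif = "CCGG",
                      strand = "+", is_spikein = spike)
  reps <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  samples <- data.frame(sample_id = paste0(groups, "_", reps),
                        group = groups, replicate = reps,
                        is_spikein_present = any(spike))
  mscc_set(counts, sites, samples)
}

# Exhaustive substring scan: the independent oracle for enumerate_sites.
brute_force_sites <- function(seqs, motifs) {
  rows <- list()
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    for (k in seq_along(motifs)) {
      m <- motifs[k]
      L <- nchar(m)
      cg <- as.integer(regexpr("CG", m, fixed = TRUE))
      if (nchar(s) >= L) for (i in seq_len(nchar(s) - L + 1)) {
        if (substr(s, i, i + L - 1) == m)
          rows[[length(rows) + 1]] <- data.frame(
            chrom = ch, pos = i - 1L + (cg - 1L), motif = m, prio = k)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      motif = character()))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$chrom, tab$pos, tab$prio), ]
  tab <- tab[!duplicated(tab[c("chrom", "pos")]), c("chrom", "pos", "motif")]
  rownames(tab) <- NULL
  tab
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
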