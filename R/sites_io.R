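#' Recognition motifs surveyed by the assay
#'
#' The five methyl-sensitive restriction motifs whose flanking sequence
#' tags are counted: CCGG, ACGT, GCGC, CCGC and GGCG. Each contains exactly
#' one CG dinucleotide; the position of a site is the position of the C of
#' that CG on the forward strand.
#'
#' @return Character vector of motifs, in the configured priority order
#'   used to break ties when several motifs hit the same CpG.
#' @export
mscc_motifs <- function() c("CCGG", "ACGT", "GCGC", "CCGC", "GGCG")

#' Enumerate methyl-sensitive recognition sites in a genome
#'
#' Scans the forward strand of each sequence for the given motifs and
#' records one site per CpG: the 0-based position of the C of the motif's
#' CG dinucleotide. When distinct motifs place a site at the same CpG the
#' first motif in `motifs` wins.
#'
#' @param genome a named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param motifs character vector of recognition motifs; each must contain
#'   exactly one CG.
#' @return A site table: data.frame with `site_id` ("chrom:pos"), `chrom`,
#'   `pos`, `motif`, `strand` ("+"), sorted by (chrom, pos). Non-ACGT
#'   characters never match; their total is attached as attribute
#'   `n_ambiguous` and reported with a warning when positive.
#' @export
enumerate_sites <- function(genome, motifs = mscc_motifs()) {
  cg_at <- vapply(motifs, function(m) {
    hits <- gregexpr("CG", m, fixed = TRUE)[[1]]
    if (identical(c(hits), -1L) || length(hits) != 1L)
      stop("motif '", m, "' must contain exactly one CG dinucleotide")
    hits[1]
  }, integer(1))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  n_amb <- sum(vapply(seq_along(genome), function(i) {
    f <- Biostrings::alphabetFrequency(genome[[i]])
    sum(f) - sum(f[c("A", "C", "G", "T")])
  }, numeric(1)))
  if (n_amb > 0)
    warning(n_amb, " non-ACGT characters in genome; they never match a motif")
  res <- list()
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    for (k in seq_along(motifs)) {
      st <- Biostrings::start(
        Biostrings::matchPattern(motifs[k], genome[[i]], fixed = TRUE))
      if (length(st))
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, pos = st - 1L + (cg_at[k] - 1L),
          motif = motifs[k], prio = k)
    }
  }
  if (!length(res)) {
    out <- data.frame(site_id = character(), chrom = character(),
                      pos = integer(), motif = character(),
                      strand = character())
    attr(out, "n_ambiguous") <- n_amb
    return(out)
  }
  tab <- do.call(rbind, res)
  tab <- tab[order(tab$chrom, tab$pos, tab$prio), ]
  tab <- tab[!duplicated(tab[c("chrom", "pos")]), ]
  out <- data.frame(site_id = paste(tab$chrom, tab$pos, sep = ":"),
                    chrom = tab$chrom, pos = tab$pos, motif = tab$motif,
                    strand = "+", row.names = NULL)
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Read and write per-site count tables
#'
#' The on-disk format is TSV with columns `chrom`, `pos`, then one column
#' per sample. Sites present in `sites` but absent from the file are
#' filled with zero counts (their number is attached as attribute
#' `n_missing_sites`); a site in the file but not in `sites` is an error.
#'
#' @param path file path.
#' @param sites site table (see [enumerate_sites()]).
#' @param samples sample sheet data.frame (`sample_id`, `group`,
#'   `replicate`, `is_spikein_present`).
#' @return [read_counts()]: an [mscc_set]; [write_counts()]: `path`,
#'   invisibly.
#' @export
read_counts <- function(path, sites, samples) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(chrom = "character"))
  if (!all(c("chrom", "pos") %in% names(tab)))
    stop("counts file must have 'chrom' and 'pos' columns")
  file_samples <- setdiff(names(tab), c("chrom", "pos"))
  unknown <- setdiff(file_samples, samples$sample_id)
  if (length(unknown))
    stop("unknown sample column(s): ", paste(unknown, collapse = ", "))
  ids <- paste(tab$chrom, tab$pos, sep = ":")
  stray <- setdiff(ids, sites$site_id)
  if (length(stray))
    stop("site(s) not in the site table: ",
         paste(utils::head(stray, 5), collapse = ", "))
  m <- as.matrix(tab[file_samples])
  if (any(m < 0)) stop("negative counts in ", path)
  full <- matrix(0L, nrow(sites), length(samples$sample_id),
                 dimnames = list(sites$site_id, samples$sample_id))
  full[ids, file_samples] <- m
  out <- mscc_set(full, sites, samples)
  attr(out, "n_missing_sites") <- nrow(sites) - length(unique(ids))
  out
}

#' @param x an [mscc_set] to write.
#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  tab <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    x$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample sheets
#'
#' CSV with columns `sample_id`, `group`, `replicate`,
#' `is_spikein_present`.
#'
#' @param path file path.
#' @return [read_sample_sheet()]: a data.frame; every group must have at
#'   least one sample and sample ids must be unique.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "replicate", "is_spikein_present")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id")
  ss$is_spikein_present <- as.logical(ss$is_spikein_present)
  ss
}

#' @param x sample sheet to write.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.csv(
    x[c("sample_id", "group", "replicate", "is_spikein_present")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3+ in the 0-based half-open convention. Intervals are validated
#' (`start < end`, error cites the offending line) and sorted within each
#' chromosome; overlapping intervals are preserved, never merged.
#'
#' @param path BED file path.
#' @param kind label for the interval set: "cgi", "enhancer" or "generic".
#' @return data.frame of class `interval_set` with columns `chrom`,
#'   `start`, `end` and, when present in the file, `name` (4th column).
#' @export
read_intervals <- function(path, kind = c("generic", "cgi", "enhancer")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line ", which(nf < 3)[1], " has fewer than 3 fields")
  tab <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.integer(vapply(fields, `[`, "", 2)),
    end = as.integer(vapply(fields, `[`, "", 3)))
  if (any(nf >= 4)) tab$name <- vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, "")
  bad <- which(!(tab$start < tab$end))
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end (", tab$start[bad[1]], " >= ",
         tab$end[bad[1]], ")")
  if (any(tab$start < 0)) stop("negative BED start")
  tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("interval_set", "data.frame")
  attr(tab, "kind") <- kind
  tab
}

#' @param x interval set (or plain data.frame with chrom/start/end) to
#'   write as BED.
#' @rdname read_intervals
#' @export
write_intervals <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  utils::write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build an interval set in code
#'
#' @param chrom,start,end,name interval columns (0-based half-open).
#' @param kind see [read_intervals()].
#' @return An `interval_set` data.frame, per-chromosome sorted.
#' @export
interval_set <- function(chrom, start, end, name = NULL,
                         kind = "generic") {
  tab <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end))
  if (!is.null(name)) tab$name <- name
  if (any(tab$start >= tab$end)) stop("interval start must be < end")
  tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("interval_set", "data.frame")
  attr(tab, "kind") <- kind
  tab
}

# GRanges view of an interval set (BED half-open -> 1-based closed).
.iv_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(iv$start + 1L, iv$end))
}

# GRanges of site positions (width-1 at the C of the CpG).
.site_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$pos + 1L, width = 1L))
}
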