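# Length profiles: per-5'-end median lengths (3' trimming detection),
# length histograms, nucleotide composition, genomic-origin assignment.

#' Copy-weighted median length per 5' end
#'
#' Groups reads by (chromosome, strand, 5' position) and computes the
#' copy-weighted median of their lengths. Reads are first restricted to the
#' `min_len..max_len` window (default 24-40 nt, the usual piRNA range for
#' 3'-end comparisons).
#'
#' @param reads read table.
#' @param min_len,max_len length window applied before grouping.
#' @param tie even-weight tie rule: `"lower"` (default; integer-valued,
#'   direction-consistent for trimming detection) or `"midpoint"` (mean of the
#'   two central order statistics, may be half-integer).
#' @return `data.table` with `chrom`, `strand`, `p5`, `n_copies`,
#'   `median_length`.
#' @export
median_length_by_5prime <- function(reads, min_len = 24L, max_len = 40L,
                                    tie = c("lower", "midpoint")) {
  tie <- match.arg(tie)
  r <- reads[length >= min_len & length <= max_len]
  if (!nrow(r))
    return(data.table(chrom = character(), strand = character(), p5 = integer(),
                      n_copies = numeric(), median_length = numeric()))
  r[, .(n_copies = sum(as.numeric(copies)),
        median_length = weighted_median(length, copies, tie)),
    by = .(chrom, strand, p5)]
}

# median of the multiset in which value[i] appears weight[i] times
weighted_median <- function(values, weights, tie = "lower") {
  o <- order(values)
  v <- values[o]
  w <- as.numeric(weights[o])
  n <- sum(w)
  cw <- cumsum(w)
  lower <- v[which(cw >= floor((n + 1) / 2))[1]]
  if (tie == "lower" || n %% 2 == 1) return(as.numeric(lower))
  upper <- v[which(cw >= n / 2 + 1)[1]]
  (lower + upper) / 2
}

#' Per-5'-end median-length differences between two libraries
#'
#' For every (chromosome, strand, 5' position) present in both libraries,
#' computes `delta = median_b - median_a`. A negative mode indicates 3'
#' trimming in library b relative to a.
#'
#' @param groups_a,groups_b outputs of [median_length_by_5prime()] (read
#'   tables are accepted and grouped automatically).
#' @param ... passed to [median_length_by_5prime()] when raw reads are given.
#' @return list with `per_key` (`data.table` of shared keys and `delta`),
#'   `histogram` (table over observed delta values), `n_shared`, and
#'   `disjoint` flag (`TRUE` when no key is shared).
#' @export
delta_median <- function(groups_a, groups_b, ...) {
  if (!"median_length" %in% names(groups_a))
    groups_a <- median_length_by_5prime(groups_a, ...)
  if (!"median_length" %in% names(groups_b))
    groups_b <- median_length_by_5prime(groups_b, ...)
  m <- merge(groups_a[, .(chrom, strand, p5, median_a = median_length)],
             groups_b[, .(chrom, strand, p5, median_b = median_length)],
             by = c("chrom", "strand", "p5"))
  m[, delta := median_b - median_a]
  hist <- if (nrow(m)) table(m$delta) else table(numeric())
  list(per_key = m[], histogram = hist, n_shared = nrow(m),
       disjoint = nrow(m) == 0L)
}

#' Copy-weighted read-length histogram
#'
#' @param reads read table.
#' @param min_len,max_len histogram domain (default 24-40).
#' @return named numeric vector over `min_len..max_len`; sums to the total
#'   copy-weighted count of in-range reads.
#' @export
length_histogram <- function(reads, min_len = 24L, max_len = 40L) {
  lens <- min_len:max_len
  h <- setNames(numeric(length(lens)), lens)
  r <- reads[length >= min_len & length <= max_len,
             .(w = sum(as.numeric(copies))), by = length]
  h[as.character(r$length)] <- r$w
  h
}

#' Positional nucleotide composition of reads
#'
#' Extracts each read's sequence 5' to 3' from the genome (reverse complement
#' on the minus strand), reports per-position base frequencies with T written
#' as U, copy-weighted. Each position is normalized over the reads that reach
#' it, so every row is a probability vector.
#'
#' @param reads read table.
#' @param genome named character vector of chromosome sequences
#'   (see [read_fasta()]).
#' @param positions number of 5'-anchored positions to report (default 10).
#' @return list with `freq` (positions x `A,C,G,U` matrix), `u1_fraction`
#'   (first-position U fraction, the 1U bias).
#' @export
nucleotide_composition <- function(reads, genome, positions = 10L) {
  seqs <- read_sequences(reads, genome)
  bases <- c("A", "C", "G", "U")
  freq <- matrix(0, nrow = positions, ncol = 4,
                 dimnames = list(seq_len(positions), bases))
  if (!length(seqs)) return(list(freq = freq, u1_fraction = NA_real_))
  w <- as.numeric(reads$copies)
  for (p in seq_len(positions)) {
    covered <- nchar(seqs) >= p
    if (!any(covered)) next
    b <- substr(seqs[covered], p, p)
    b[b == "T"] <- "U"
    tot <- tapply(w[covered], factor(b, levels = bases), sum)
    tot[is.na(tot)] <- 0
    freq[p, ] <- tot / sum(w[covered])
  }
  list(freq = freq, u1_fraction = freq[1, "U"])
}

# 5'->3' read sequences; errors when a read exceeds its chromosome
read_sequences <- function(reads, genome) {
  if (!nrow(reads)) return(character())
  missing <- setdiff(unique(reads$chrom), names(genome))
  if (length(missing)) stop("chromosome absent from genome: ", missing[1])
  lens <- nchar(genome)[reads$chrom]
  if (any(reads$end > lens)) stop("read beyond genome bounds")
  s <- substr_vec(genome[reads$chrom], reads$start + 1L, reads$end)
  minus <- reads$strand == "-"
  if (any(minus)) s[minus] <- revcomp(s[minus])
  s
}

substr_vec <- function(x, start, stop) substr(x, start, stop)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign each read to one genomic feature category
#'
#' Every read is assigned to exactly one category: the first annotation set in
#' `precedence` for which at least `min_overlap_frac` of the read's span
#' overlaps one of its intervals, else `"intergenic"`. Counts therefore
#' partition the read set.
#'
#' @param reads read table.
#' @param annotations named list of interval tables (`chrom`, `start`, `end`),
#'   e.g. `list(cluster = ..., gene = ..., repeat. = ...)`.
#' @param precedence category order; defaults to the order of `annotations`.
#' @param min_overlap_frac minimum fraction of the read covered (default 0.5).
#' @param weighted copy-weighted counts (default) or raw read counts.
#' @return list with `counts` (named vector over categories + `intergenic`)
#'   and `category` (per-read assignment).
#' @export
genomic_feature_assignment <- function(reads, annotations,
                                       precedence = names(annotations),
                                       min_overlap_frac = 0.5,
                                       weighted = TRUE) {
  stopifnot(all(precedence %in% names(annotations)))
  n <- nrow(reads)
  category <- rep("intergenic", n)
  if (n) {
    rg <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$start + 1L, reads$end))
    unassigned <- rep(TRUE, n)
    for (cat in precedence) {
      ann <- as.data.table(annotations[[cat]])
      if (!nrow(ann)) next
      ag <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$start + 1L, ann$end))
      ov <- GenomicRanges::findOverlaps(rg, ag)
      if (!length(ov)) next
      qh <- S4Vectors::queryHits(ov)
      inter <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rg)[qh], IRanges::ranges(ag)[S4Vectors::subjectHits(ov)]))
      frac <- inter / IRanges::width(rg)[qh]
      hit <- unique(qh[frac >= min_overlap_frac])
      take <- hit[unassigned[hit]]
      category[take] <- cat
      unassigned[take] <- FALSE
    }
  }
  lev <- c(precedence, "intergenic")
  w <- if (weighted && n) as.numeric(reads$copies) else rep(1, n)
  counts <- setNames(numeric(length(lev)), lev)
  if (n) {
    tot <- tapply(w, factor(category, levels = lev), sum)
    tot[is.na(tot)] <- 0
    counts[] <- tot
  }
  list(counts = counts, category = category)
}
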