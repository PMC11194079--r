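# piRNA target prediction and degradome validation.
#
# A piRNA representative is the 25 genomic nucleotides downstream of the
# mapped 5' end; length variants sharing these 25 nt collapse into one
# identity. Targets are scanned ungapped and antisense on transcript sense
# sequences: piRNA nt i pairs the transcript base at site_start + 25 - i
# (0-based), so nt 1 faces the 3'-most base of the site. Slicing occurs
# between the bases paired to piRNA nt 10 and 11; the predicted cut is the
# transcript coordinate of the 5' base of the downstream (3') fragment, the
# base paired to nt 10.

REP_LEN <- 25L

#' Collapse reads into 25-nt genome-derived piRNA representatives
#'
#' Takes the 25 genomic nucleotides downstream from each read's mapped 5'
#' position (in the read's orientation), merges identical 25-mers, and sums
#' copy-weighted abundance per sample. The 25-mer sequence is the piRNA
#' identity used by all downstream steps.
#'
#' @param reads read table.
#' @param genome named character vector of chromosome sequences.
#' @return list with `representatives` (`data.table`: `sequence`, `chrom`,
#'   `strand`, `p5` of the first-seen origin, `abundance` summed over
#'   samples), `abundance` (long `data.table`: `sequence`, `sample`,
#'   `abundance`), and `n_skipped` (reads within 25 nt of a contig edge on
#'   their 3' side, dropped with a warning).
#' @export
collapse_representatives <- function(reads, genome) {
  if (!nrow(reads)) {
    empty <- data.table(sequence = character(), chrom = character(),
                        strand = character(), p5 = integer(),
                        abundance = numeric())
    return(list(representatives = empty,
                abundance = data.table(sequence = character(),
                                       sample = character(),
                                       abundance = numeric()),
                n_skipped = 0L))
  }
  missing <- setdiff(unique(reads$chrom), names(genome))
  if (length(missing)) stop("chromosome absent from genome: ", missing[1])
  clen <- nchar(genome)[reads$chrom]
  plus <- reads$strand == "+"
  lo <- ifelse(plus, reads$p5, reads$p5 - REP_LEN + 1L)         # 0-based
  hi <- lo + REP_LEN
  ok <- lo >= 0L & hi <= clen
  n_skipped <- sum(!ok)
  if (n_skipped)
    warning(n_skipped, " read(s) within ", REP_LEN,
            " nt of a contig edge skipped")
  r <- reads[ok]
  seqs <- substr(genome[r$chrom], lo[ok] + 1L, hi[ok])
  minus <- r$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  r[, sequence := seqs]
  ab <- r[, .(abundance = sum(as.numeric(copies))), by = .(sequence, sample)]
  reps <- r[, .(chrom = chrom[1], strand = strand[1], p5 = p5[1],
                abundance = sum(as.numeric(copies))), by = sequence]
  list(representatives = reps[], abundance = ab[], n_skipped = n_skipped)
}

#' Scan one transcript for target sites of one piRNA
#'
#' Slides the 25-nt piRNA antisense along the transcript (ungapped, every
#' register). A register is a candidate when piRNA positions 2-6 are perfectly
#' Watson-Crick complementary (configurable), position 1 is free, and
#' positions 7-25 contain at least `min_matches` complementary pairs. G:U
#' wobble and non-ACGT characters count as mismatches.
#'
#' @param pirna 25-nt piRNA representative sequence (DNA alphabet, 5'->3').
#' @param transcript mRNA sense-strand sequence, 5'->3'.
#' @param min_matches minimum matches within piRNA positions 7-25
#'   (default 14).
#' @param allow_pos1_mismatch mismatch allowed at piRNA position 1
#'   (default `TRUE`).
#' @param seed_exact require perfect pairing at positions 2-6
#'   (default `TRUE`).
#' @return `data.table` with one row per passing register: `site_start`
#'   (0-based transcript coordinate of the 5'-most paired base),
#'   `pairing_start` (coordinate opposite piRNA nt 1, `site_start + 24`),
#'   `cut` (coordinate of the base paired to piRNA nt 10, `site_start + 15`),
#'   `matches_7_25`, `mismatch_positions` (comma-separated piRNA positions).
#'   Transcripts shorter than 25 nt yield zero rows.
#' @export
scan_targets <- function(pirna, transcript, min_matches = 14L,
                         allow_pos1_mismatch = TRUE, seed_exact = TRUE) {
  stopifnot(nchar(pirna) == REP_LEN)
  empty <- data.table(site_start = integer(), pairing_start = integer(),
                      cut = integer(), matches_7_25 = integer(),
                      mismatch_positions = character())
  L <- nchar(transcript)
  if (L < REP_LEN) return(empty)
  tc <- strsplit(toupper(transcript), "")[[1]]
  cp <- comp_base(strsplit(toupper(chartr("U", "T", pirna)), "")[[1]])
  R <- L - REP_LEN + 1L
  # eq[i] over registers s = 0..R-1: transcript base at s + 25 - i equals the
  # complement of piRNA nt i  (1-based transcript index s + 26 - i)
  eq <- function(i) {
    from <- 26L - i
    tc[from:(from + R - 1L)] == cp[i]
  }
  m725 <- integer(R)
  for (i in 7:25) m725 <- m725 + eq(i)
  pass <- m725 >= min_matches
  if (seed_exact) for (i in 2:6) pass <- pass & eq(i)
  if (!allow_pos1_mismatch) pass <- pass & eq(1L)
  s <- which(pass) - 1L
  if (!length(s)) return(empty)
  mm <- vapply(s, function(s0) {
    pos <- c(1L, 7:25)
    bad <- pos[tc[s0 + 26L - pos] != cp[pos]]
    paste(bad, collapse = ",")
  }, "")
  data.table(site_start = s, pairing_start = s + REP_LEN - 1L,
             cut = s + 15L, matches_7_25 = m725[s + 1L],
             mismatch_positions = mm)
}

comp_base <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

#' Scan a set of transcripts with a set of piRNA representatives
#'
#' @param representatives `data.table` with a `sequence` column (e.g. from
#'   [collapse_representatives()]), or a character vector of 25-mers.
#' @param transcripts named character vector of transcript sense sequences.
#' @inheritParams scan_targets
#' @return `data.table` of candidate sites with `pirna` (sequence) and
#'   `transcript` columns prepended to the [scan_targets()] columns.
#' @export
scan_all_targets <- function(representatives, transcripts, min_matches = 14L,
                             allow_pos1_mismatch = TRUE, seed_exact = TRUE) {
  seqs <- unique(if (is.character(representatives)) representatives
                 else representatives$sequence)
  empty <- data.table(pirna = character(), transcript = character(),
                      site_start = integer(), pairing_start = integer(),
                      cut = integer(), matches_7_25 = integer(),
                      mismatch_positions = character())
  if (!length(seqs) || !length(transcripts)) return(empty)
  # complement codes of every piRNA, N x 25 (0 = non-ACGT, never matches)
  code <- function(x) {
    v <- utf8ToInt(x)
    # A<->T, C<->G complements as integer codes
    out <- integer(length(v))
    out[v == utf8ToInt("A")] <- 4L  # matches transcript T
    out[v == utf8ToInt("T")] <- 1L  # matches transcript A
    out[v == utf8ToInt("C")] <- 3L  # matches transcript G
    out[v == utf8ToInt("G")] <- 2L  # matches transcript C
    out
  }
  txcode <- function(x) {
    v <- utf8ToInt(x)
    out <- integer(length(v)) - 1L
    out[v == utf8ToInt("A")] <- 1L
    out[v == utf8ToInt("C")] <- 2L
    out[v == utf8ToInt("G")] <- 3L
    out[v == utf8ToInt("T")] <- 4L
    out
  }
  if (!seed_exact) {
    # rare configuration: fall back to the per-pair scan
    out <- list()
    for (tx in names(transcripts)) for (p in seqs) {
      hits <- scan_targets(p, transcripts[[tx]], min_matches,
                           allow_pos1_mismatch, seed_exact)
      if (nrow(hits))
        out[[length(out) + 1L]] <-
          cbind(data.table(pirna = p, transcript = tx), hits)
    }
    if (!length(out)) return(empty)
    res <- rbindlist(out)
    setorder(res, transcript, pirna, site_start)
    return(res[])
  }
  C <- t(vapply(toupper(chartr("U", "T", seqs)), code, integer(REP_LEN)))
  # seed anchor: an exact 2-6 pairing forces the transcript 5-mer at
  # site_start + 19..23 to equal the reverse complement of piRNA nt 2-6
  rc5 <- revcomp(substr(toupper(chartr("U", "T", seqs)), 2L, 6L))
  pkey <- data.table(pi_i = seq_along(seqs), five = rc5)
  out <- list()
  for (tx in names(transcripts)) {
    txs <- toupper(chartr("U", "T", transcripts[[tx]]))
    t_int <- txcode(txs)
    L <- length(t_int)
    if (L < REP_LEN) next
    tkey <- data.table(five = substring(txs, 1:(L - 4L), 5:L),
                       s = 0:(L - 5L) - 19L)[s >= 0L & s <= L - REP_LEN]
    cand <- merge(pkey, tkey, by = "five", allow.cartesian = TRUE)
    if (!nrow(cand)) next
    # full vectorized check over candidates
    m725 <- integer(nrow(cand))
    for (i in 7:25)
      m725 <- m725 + (t_int[cand$s + 26L - i] == C[cbind(cand$pi_i, i)])
    keep <- m725 >= min_matches
    if (!allow_pos1_mismatch)
      keep <- keep & (t_int[cand$s + 25L] == C[cbind(cand$pi_i, 1L)])
    if (!any(keep)) next
    cand <- cand[keep]
    m725 <- m725[keep]
    mm <- vapply(seq_len(nrow(cand)), function(j) {
      pos <- c(1L, 7:25)
      bad <- pos[t_int[cand$s[j] + 26L - pos] != C[cand$pi_i[j], pos]]
      paste(bad, collapse = ",")
    }, "")
    out[[length(out) + 1L]] <- data.table(
      pirna = seqs[cand$pi_i], transcript = tx, site_start = cand$s,
      pairing_start = cand$s + REP_LEN - 1L, cut = cand$s + 15L,
      matches_7_25 = m725, mismatch_positions = mm)
  }
  if (!length(out)) return(empty)
  res <- rbindlist(out)
  setorder(res, transcript, pirna, site_start)
  res[]
}

#' Flag target sites supported by degradome 5' ends
#'
#' A replicate supports a site when at least one degradome 5' end falls
#' within `tolerance` nt of the site's predicted cut coordinate (default 0,
#' i.e. exact coincidence). The verdict `supported` requires support in every
#' replicate; with fewer than two replicates no site can be supported and the
#' result carries `insufficient_replicates = TRUE`.
#'
#' @param sites site table from [scan_all_targets()] (needs `transcript`,
#'   `cut`).
#' @param degradome `data.table` of 5'-end records with columns `replicate`,
#'   `transcript`, `pos` (0-based transcript coordinate of the fragment's 5'
#'   base).
#' @param tolerance maximum |record - cut| distance in nt (default 0).
#' @param require_all_replicates verdict requires all replicates
#'   (default `TRUE`); otherwise any replicate suffices.
#' @return `sites` with one logical column `support_<replicate>` per
#'   replicate, `n_replicates_supported`, and `supported`; attribute
#'   `insufficient_replicates` is set accordingly.
#' @export
degradome_support <- function(sites, degradome, tolerance = 0L,
                              require_all_replicates = TRUE) {
  sites <- copy(as.data.table(sites))
  reps <- sort(unique(as.character(degradome$replicate)))
  if (nrow(sites)) {
    sites[, cut_lo := cut - as.integer(tolerance)]
    sites[, cut_hi := cut + as.integer(tolerance)]
  }
  for (r in reps) {
    dr <- unique(as.data.table(degradome)[as.character(replicate) == r,
                                          .(transcript, pos)])
    col <- paste0("support_", r)
    if (!nrow(sites)) { sites[, (col) := logical()]; next }
    if (!nrow(dr)) { sites[, (col) := FALSE]; next }
    hit <- dr[sites, on = .(transcript, pos >= cut_lo, pos <= cut_hi),
              nomatch = NA, which = TRUE, mult = "first"]
    sites[, (col) := !is.na(hit)]
  }
  if (nrow(sites)) sites[, c("cut_lo", "cut_hi") := NULL]
  supc <- paste0("support_", reps)
  nsup <- if (length(supc) && nrow(sites))
    rowSums(as.matrix(sites[, supc, with = FALSE])) else rep(0L, nrow(sites))
  sites[, n_replicates_supported := as.integer(nsup)]
  insufficient <- length(reps) < 2L
  sites[, supported := if (!nrow(sites)) logical() else if (require_all_replicates)
    (!insufficient & n_replicates_supported == length(reps))
    else n_replicates_supported >= 1L]
  setattr(sites, "insufficient_replicates", insufficient)
  sites[]
}

#' Metatranscript region assignment of predicted cuts
#'
#' Assigns each cut to 5'UTR, CDS or 3'UTR by transcript coordinate and
#' computes the meta-position (fractional position within the region).
#' Transcripts without an annotated CDS are `noncoding`.
#'
#' @param sites site table (needs `transcript`, `cut`).
#' @param tx_regions `data.table` with `transcript`, `utr5_len`, `cds_len`,
#'   `utr3_len` (transcript-space region lengths in nt).
#' @return list with `sites` (region and `meta_position` columns added) and
#'   `region_counts` (named vector over 5'UTR/CDS/3'UTR/noncoding).
#' @export
metatranscript_distribution <- function(sites, tx_regions) {
  sites <- copy(as.data.table(sites))
  tx <- as.data.table(tx_regions)
  m <- merge(sites, tx, by = "transcript", all.x = TRUE, sort = FALSE)
  u5 <- m$utr5_len; cds <- m$cds_len; u3 <- m$utr3_len
  region <- rep("noncoding", nrow(m))
  meta <- rep(NA_real_, nrow(m))
  coding <- !is.na(cds) & cds > 0
  in5 <- coding & m$cut < u5
  incds <- coding & m$cut >= u5 & m$cut < u5 + cds
  in3 <- coding & m$cut >= u5 + cds & m$cut < u5 + cds + u3
  region[in5] <- "5'UTR"; region[incds] <- "CDS"; region[in3] <- "3'UTR"
  meta[in5] <- m$cut[in5] / u5[in5]
  meta[incds] <- (m$cut[incds] - u5[incds]) / cds[incds]
  meta[in3] <- (m$cut[in3] - u5[in3] - cds[in3]) / u3[in3]
  sites[, region := region]
  sites[, meta_position := meta]
  lev <- c("5'UTR", "CDS", "3'UTR", "noncoding")
  counts <- setNames(tabulate(factor(region, levels = lev), 4L), lev)
  list(sites = sites[], region_counts = counts)
}

#' Sense/antisense repeat classification of genomic features
#'
#' Overlaps strand-aware features (piRNA origins or genome-space cut sites)
#' with a repeat annotation. Class is `sense` when the feature and repeat
#' strands agree, `antisense` when they differ, `none` without overlap; a
#' feature overlapping several repeats takes the one with the largest
#' overlap.
#'
#' @param features `data.table` with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param repeats repeat annotation `data.table` with the same columns.
#' @return character vector of classes, one per feature row.
#' @export
repeat_overlap <- function(features, repeats) {
  features <- as.data.table(features)
  repeats <- as.data.table(repeats)
  cls <- rep("none", nrow(features))
  if (!nrow(features) || !nrow(repeats)) return(cls)
  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start + 1L,
                                                features$end))
  rg <- GenomicRanges::GRanges(repeats$chrom,
                               IRanges::IRanges(repeats$start + 1L,
                                                repeats$end))
  ov <- GenomicRanges::findOverlaps(fg, rg)
  if (!length(ov)) return(cls)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(fg)[qh],
                                          IRanges::ranges(rg)[sh]))
  best <- data.table(q = qh, s = sh, w = w)[order(q, -w)][, .SD[1], by = q]
  cls[best$q] <- ifelse(features$strand[best$q] == repeats$strand[best$s],
                        "sense", "antisense")
  cls
}

#' 25-nt genomic origin interval of a piRNA representative
#'
#' @param reps representative table (`chrom`, `strand`, `p5`).
#' @return `data.table` with `chrom`, `start`, `end`, `strand` covering the
#'   25 genomic nt downstream of the 5' end in the piRNA's orientation.
#' @export
representative_origin_intervals <- function(reps) {
  reps <- as.data.table(reps)
  data.table(
    chrom = reps$chrom,
    start = fifelse(reps$strand == "+", reps$p5, reps$p5 - REP_LEN + 1L),
    end = fifelse(reps$strand == "+", reps$p5 + REP_LEN, reps$p5 + 1L),
    strand = reps$strand
  )
}
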