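#' @import data.table
#' @importFrom stats median rnbinom rpois rbinom rlnorm runif var setNames
#' @importFrom utils head tail
NULL

# Internal canonical read table. All coordinates are 0-based, half-open
# [start, end); the 5' end is `start` on the plus strand and `end - 1` on the
# minus strand. `copies` is the collapsed-read copy number.
READ_COLS <- c("chrom", "start", "end", "name", "copies", "strand", "sample")

#' Construct a table of aligned piRNA reads
#'
#' Builds the canonical read container used throughout the package: a
#' `data.table` with columns `chrom`, `start`, `end`, `name`, `copies`,
#' `strand`, `sample` plus derived columns `length` (`end - start`) and `p5`
#' (strand-aware 5' position).
#'
#' @param chrom character vector of reference names.
#' @param start,end integer vectors, 0-based half-open interval.
#' @param strand character vector, `"+"` or `"-"`.
#' @param name read identifiers (default auto-generated).
#' @param copies positive integer copy numbers (default 1).
#' @param sample sample label carried along (default `NA`).
#' @return A `data.table` of aligned reads.
#' @export
pirna_reads <- function(chrom, start, end, strand, name = NULL, copies = 1L,
                        sample = NA_character_) {
  n <- length(start)
  if (is.null(name)) name <- if (n) paste0("read", seq_len(n)) else character()
  dt <- data.table(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    copies = as.integer(copies),
    strand = as.character(strand),
    sample = as.character(sample)
  )
  validate_reads(dt)
}

validate_reads <- function(dt) {
  if (nrow(dt)) {
    if (any(is.na(dt$start) | is.na(dt$end) | dt$start < 0L | dt$end <= dt$start))
      stop("invalid interval: require 0 <= start < end")
    if (!all(dt$strand %in% c("+", "-")))
      stop("strand must be '+' or '-' for aligned reads")
    if (any(is.na(dt$copies) | dt$copies < 1L))
      stop("copies must be a positive integer")
  }
  dt[, length := end - start]
  dt[, p5 := fifelse(strand == "+", start, end - 1L)]
  dt[]
}

#' Read aligned small-RNA reads from BED6 or SAM
#'
#' BED6 is the canonical exchange format: 0-based half-open coordinates,
#' copy number in the score column (a `name_xN` collapsed-read suffix is also
#' honoured when the score column is not a positive count). SAM is accepted
#' read-only; multimappers are identified by the `NH` tag or secondary/
#' supplementary flags. Reading is gzip-transparent.
#'
#' @param path BED6 (`.bed`, `.bed.gz`) or SAM (`.sam`) file.
#' @param min_len,max_len retain reads with `min_len <= length <= max_len`.
#'   Defaults to the 1-50 hard bound; use 24/40 for 3'-end comparisons.
#' @param unique_only drop records flagged or tagged as multimapping
#'   (SAM input only; BED input is assumed already unique).
#' @param sample sample label to attach.
#' @return Read table as from [pirna_reads()]; an empty file yields an empty
#'   table, malformed records raise an error naming the line.
#' @export
read_alignments <- function(path, min_len = 1L, max_len = 50L,
                            unique_only = TRUE, sample = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- sub("\\.gz$", "", tolower(path))
  reads <- if (grepl("\\.sam$", ext)) {
    read_sam_reads(path, unique_only = unique_only)
  } else {
    read_bed_reads(path)
  }
  reads[, sample := as.character(sample)]
  reads <- validate_reads(reads)
  reads[length >= min_len & length <= max_len]
}

read_bed_reads <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), copies = integer(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed BED6 record at line ", which(nf < 6L)[1], ": expected >= 6 fields")
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED6 record at line ", bad[1], ": non-integer coordinates")
  score <- suppressWarnings(as.numeric(m[, 4 + 1]))
  copies <- ifelse(!is.na(score) & score >= 1 & score == round(score),
                   as.integer(score), NA_integer_)
  # collapsed-read dialect: copy number as a name_xN suffix
  sufx <- suppressWarnings(as.integer(sub("^.*_x([0-9]+)$", "\\1", m[, 4])))
  sufx[!grepl("_x[0-9]+$", m[, 4])] <- NA_integer_
  copies <- fifelse(is.na(copies), fifelse(is.na(sufx), 1L, sufx), copies)
  data.table(chrom = m[, 1], start = start, end = end, name = m[, 4],
             copies = copies, strand = m[, 6])
}

read_sam_reads <- function(path, unique_only = TRUE) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), copies = integer(), strand = character())
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM record at line ", which(nf < 11L)[1])
  name <- vapply(fields, `[`, "", 1L)
  flag <- as.integer(vapply(fields, `[`, "", 2L))
  chrom <- vapply(fields, `[`, "", 3L)
  pos1 <- as.integer(vapply(fields, `[`, "", 4L))
  cigar <- vapply(fields, `[`, "", 6L)
  seq <- vapply(fields, `[`, "", 10L)
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else NA_integer_
  }, 1L)
  keep <- !bitwAnd(flag, 4L)                       # mapped
  if (unique_only)
    keep <- keep & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L) &
      (is.na(nh) | nh == 1L)
  if (!any(keep)) return(empty)
  alen <- cigar_reference_span(cigar[keep])
  alen[is.na(alen)] <- nchar(seq[keep])[is.na(alen)]
  sufx <- suppressWarnings(as.integer(sub("^.*_x([0-9]+)$", "\\1", name[keep])))
  sufx[!grepl("_x[0-9]+$", name[keep])] <- 1L
  data.table(chrom = chrom[keep], start = pos1[keep] - 1L,
             end = pos1[keep] - 1L + alen, name = name[keep],
             copies = sufx,
             strand = fifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"))
}

cigar_reference_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
}

read_text_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (gzip-transparent).
#' @return Named character vector of upper-case sequences; duplicate headers
#'   raise an error.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence name in FASTA: ",
                              nm[duplicated(nm)][1])
  setNames(toupper(as.character(ss)), nm)
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED6 file into a genomic-interval table
#'
#' @param path BED file with at least 3 columns; missing name/score/strand
#'   columns are filled with `"."`, `0`, `"."`.
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open).
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("malformed BED record at line ", which(nf < 3L)[1])
  grab <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, "")
  dt <- data.table(
    chrom = grab(1, ""), start = as.integer(grab(2, NA)),
    end = as.integer(grab(3, NA)), name = grab(4, "."),
    score = suppressWarnings(as.numeric(grab(5, "0"))), strand = grab(6, ".")
  )
  if (any(is.na(dt$start) | is.na(dt$end) | dt$start < 0L | dt$end < dt$start))
    stop("invalid BED coordinates in ", path)
  dt
}

#' Write a genomic-interval table as BED6
#' @param dt table with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (score may be carried in a `copies` column).
#' @param path output file.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  out <- data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("copies" %in% names(dt)) dt$copies
            else if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else "."
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count table
#'
#' @param path TSV with a header row; first column holds feature identifiers.
#' @return Integer matrix with feature rownames. Negative or non-integer
#'   entries raise an error.
#' @export
read_counts <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers: ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a count matrix as TSV
#' @param m matrix with feature rownames.
#' @param path output file.
#' @param id_col name of the identifier column.
#' @export
write_counts <- function(m, path, id_col = "feature") {
  dt <- data.table(feature = rownames(m))
  setnames(dt, "feature", id_col)
  fwrite(cbind(dt, as.data.table(m)), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write any tabular record set as TSV with a header row
#' @param records data.frame/data.table.
#' @param path output file.
#' @export
write_tsv <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV with header
#' @param path input file.
#' @return data.table.
#' @export
read_tsv <- function(path) fread(path, sep = "\t", header = TRUE)

#' Write reads as BED6 with copy number in the score column
#' @param reads read table.
#' @param path output file.
#' @export
write_alignments <- function(reads, path) write_bed(reads, path)
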