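# Ping-pong amplification signature.
#
# Distance convention: for a plus-strand read with 5' end p and a minus-strand
# read with 5' end m on the same chromosome, the 5'-5' overlap distance is
# d = m - p + 1, so the canonical ping-pong configuration (5' ends overlapping
# by 10 nt) scores d = 10. Distances outside 1..window are discarded.

#' Opposite-strand 5'-5' distance histogram
#'
#' Accumulates, over all pairs (x in `reads_a` on the plus strand, y in
#' `reads_b` on the minus strand, same chromosome), the overlap distance
#' `d = p5(y) - p5(x) + 1` into bins `1..window`. In heterotypic mode
#' (`reads_a` and `reads_b` are different libraries) both orientations are
#' accumulated, so the histogram is symmetric in its arguments; in homotypic
#' mode each unordered pair is counted once.
#'
#' @param reads_a,reads_b read tables from [pirna_reads()]/[read_alignments()].
#' @param window largest overlap distance considered (default 30).
#' @param weighting `"product"` (weight = product of copy numbers) or
#'   `"unique"` (each read pair weighs 1).
#' @param homotypic treat the two sets as the same library; defaults to `TRUE`
#'   when `reads_b` is missing.
#' @return Object of class `distance_histogram`: list with `w` (named numeric
#'   vector over 1..window), `window`, `weighting`, `empty` flag.
#' @export
five_prime_distance_histogram <- function(reads_a, reads_b = NULL, window = 30L,
                                          weighting = c("product", "unique"),
                                          homotypic = is.null(reads_b)) {
  weighting <- match.arg(weighting)
  force(homotypic)          # default depends on reads_b before reassignment
  if (is.null(reads_b)) reads_b <- reads_a
  w <- overlap_weights(reads_a, reads_b, window, weighting)
  if (!homotypic) w <- w + overlap_weights(reads_b, reads_a, window, weighting)
  structure(list(w = w, window = as.integer(window), weighting = weighting,
                 empty = nrow(reads_a) == 0L || nrow(reads_b) == 0L),
            class = "distance_histogram")
}

# one orientation: plus strand from `a`, minus strand from `b`
overlap_weights <- function(a, b, window, weighting) {
  w <- numeric(window)
  names(w) <- as.character(seq_len(window))
  plus <- a[strand == "+", .(n = .N, cp = sum(as.numeric(copies))),
            by = .(chrom, p5)]
  minus <- b[strand == "-", .(n = .N, cp = sum(as.numeric(copies))),
             by = .(chrom, p5)]
  if (!nrow(plus) || !nrow(minus)) return(w)
  for (d in seq_len(window)) {
    hit <- merge(minus[, .(chrom, p5 = p5 - d + 1L, n_m = n, cp_m = cp)],
                 plus, by = c("chrom", "p5"))
    if (nrow(hit))
      w[d] <- if (weighting == "product") sum(hit$cp * hit$cp_m)
              else sum(as.numeric(hit$n) * hit$n_m)
  }
  w
}

#' Ping-pong z-score from a distance histogram
#'
#' Standardized excess of the weight at distance 10 over the background of the
#' other bins: `z = (w(10) - mean(w(d != 10))) / sqrt(var(w(d != 10)) / n)`
#' with `n` the number of background bins (29 for a 30-nt window) and `var`
#' the unbiased sample variance.
#'
#' @param hist a `distance_histogram`.
#' @param peak the signature distance (default 10).
#' @return Object of class `pingpong_stat`: list with `z`, `w10`,
#'   `background_mean`, `background_var`, `n_background`, `degenerate` flag
#'   (`TRUE` with `z = NA` when the background variance is zero).
#' @export
pingpong_zscore <- function(hist, peak = 10L) {
  stopifnot(inherits(hist, "distance_histogram"))
  w <- hist$w
  bg <- w[-peak]
  m <- mean(bg)
  v <- var(bg)
  n <- length(bg)
  # zero background variance: a perfectly flat histogram has no excess at
  # the peak (z = 0 by symmetry); any other case is undefined and flagged
  degenerate <- (!is.finite(v) || v == 0) && w[[peak]] != m
  z <- if (degenerate) NA_real_
       else if (v == 0) 0
       else (w[[peak]] - m) / sqrt(v / n)
  structure(list(z = z, w10 = w[[peak]], background_mean = m,
                 background_var = v, n_background = n, degenerate = degenerate),
            class = "pingpong_stat")
}

#' @export
print.pingpong_stat <- function(x, ...) {
  cat(sprintf("ping-pong z-score: %s (w10 = %g, bg mean = %g, bg var = %g, n = %d)\n",
              if (x$degenerate) "degenerate (zero background variance)"
              else formatC(x$z, digits = 4, format = "f"),
              x$w10, x$background_mean, x$background_var, x$n_background))
  invisible(x)
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("5'-5' distance histogram (window %d, weighting %s)%s\n",
              x$window, x$weighting, if (x$empty) " [empty input]" else ""))
  print(x$w)
  invisible(x)
}

#' Fraction of reads engaged in ping-pong pairs
#'
#' Copy-weighted fraction of reads that have at least one opposite-strand
#' partner at overlap distance `peak` (default 10). Homotypic mode pools the
#' library against itself; heterotypic mode reports the fraction for each
#' library against the other, plus the pooled value.
#'
#' @inheritParams five_prime_distance_histogram
#' @param peak overlap distance defining a ping-pong pair.
#' @return list with `fraction` (pooled), `fraction_a`, `fraction_b`, and
#'   `empty` flag. Empty input yields fraction 0 and `empty = TRUE`.
#' @export
pingpong_pair_fraction <- function(reads_a, reads_b = NULL, peak = 10L,
                                   homotypic = is.null(reads_b)) {
  force(homotypic)          # default depends on reads_b before reassignment
  if (is.null(reads_b)) reads_b <- reads_a
  if (!nrow(reads_a) && !nrow(reads_b))
    return(list(fraction = 0, fraction_a = 0, fraction_b = 0, empty = TRUE))
  fa <- paired_weight(reads_a, reads_b, peak)
  fb <- paired_weight(reads_b, reads_a, peak)
  if (homotypic) {
    list(fraction = fa$frac, fraction_a = fa$frac, fraction_b = fa$frac,
         empty = FALSE)
  } else {
    tot <- fa$total + fb$total
    list(fraction = if (tot > 0) (fa$paired + fb$paired) / tot else 0,
         fraction_a = fa$frac, fraction_b = fb$frac, empty = FALSE)
  }
}

# copy-weighted fraction of reads in `a` with a partner at distance `peak`
# among opposite-strand reads of `b`
paired_weight <- function(a, b, peak) {
  total <- sum(as.numeric(a$copies))
  if (total == 0) return(list(frac = 0, paired = 0, total = 0))
  # partner 5' position required on the opposite strand of b
  need <- fifelse(a$strand == "+", a$p5 + peak - 1L, a$p5 - peak + 1L)
  need_strand <- fifelse(a$strand == "+", "-", "+")
  bkey <- unique(b[, .(chrom, strand, p5)])
  has <- merge(data.table(i = seq_len(nrow(a)), chrom = a$chrom,
                          strand = need_strand, p5 = need),
               bkey, by = c("chrom", "strand", "p5"))
  paired <- sum(as.numeric(a$copies[unique(has$i)]))
  list(frac = paired / total, paired = paired, total = total)
}
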