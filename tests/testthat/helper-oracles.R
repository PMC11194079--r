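# Independent oracles and small fixture builders used across the suite.

library(data.table)

# --- ping-pong: all-pairs brute force ------------------------------------
# Direct enumeration of every (plus read, minus read) combination; no
# grouping or joins, unlike the production per-distance merge.
bf_distance_histogram <- function(a, b = NULL, window = 30L,
                                  weighting = "product",
                                  homotypic = is.null(b)) {
  force(homotypic)
  if (is.null(b)) b <- a
  one_way <- function(x, y) {
    w <- setNames(numeric(window), seq_len(window))
    p <- x[x$strand == "+", ]
    m <- y[y$strand == "-", ]
    if (!nrow(p) || !nrow(m)) return(w)
    g <- expand.grid(i = seq_len(nrow(p)), j = seq_len(nrow(m)))
    same <- p$chrom[g$i] == m$chrom[g$j]
    d <- m$p5[g$j] - p$p5[g$i] + 1L
    ok <- same & d >= 1L & d <= window
    wt <- if (weighting == "product")
      as.numeric(p$copies[g$i]) * m$copies[g$j] else rep(1, nrow(g))
    for (dd in unique(d[ok])) w[dd] <- sum(wt[ok & d == dd])
    w
  }
  w <- one_way(as.data.frame(a), as.data.frame(b))
  if (!homotypic) w <- w + one_way(as.data.frame(b), as.data.frame(a))
  w
}

# one-line transcription of the z-score formula
bf_zscore <- function(w, peak = 10L) {
  bg <- w[-peak]
  unname((w[peak] - mean(bg)) / sqrt(var(bg) / length(bg)))
}

# --- target scan: dense per-register verification ------------------------
# Evaluates every register with a full 25-position base-by-base comparison
# (no seed anchoring / hashing as in the production scanner).
oracle_scan <- function(pirna, transcript, min_matches = 14L,
                        allow_pos1_mismatch = TRUE, seed_exact = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pc <- comp[strsplit(toupper(chartr("U", "T", pirna)), "")[[1]]]
  tc <- strsplit(toupper(transcript), "")[[1]]
  L <- length(tc)
  if (L < 25L) return(integer())
  hits <- integer()
  for (s in 0:(L - 25L)) {
    m <- !is.na(pc) & tc[s + 26L - (1:25)] == pc
    ok <- sum(m[7:25]) >= min_matches
    if (seed_exact) ok <- ok && all(m[2:6])
    if (!allow_pos1_mismatch) ok <- ok && m[1]
    if (ok) hits <- c(hits, s)
  }
  hits
}

# vectorised-over-registers variant used for the large acceptance runs;
# same dense every-register logic, no anchoring. `transcript` may be a
# pre-split character vector to amortise strsplit across piRNAs.
oracle_scan_fast <- function(pirna, transcript, min_matches = 14L,
                             allow_pos1_mismatch = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pc <- comp[strsplit(toupper(chartr("U", "T", pirna)), "")[[1]]]
  tc <- if (length(transcript) > 1L) transcript
        else strsplit(toupper(transcript), "")[[1]]
  L <- length(tc)
  if (L < 25L) return(integer())
  R <- L - 25L + 1L
  n725 <- integer(R); n26 <- integer(R)
  for (i in 1:25) {
    eq <- !is.na(pc[i]) & tc[(26L - i):(26L - i + R - 1L)] == pc[i]
    if (i >= 7L) n725 <- n725 + eq
    else if (i >= 2L) n26 <- n26 + eq
    else eq1 <- eq
  }
  ok <- n725 >= min_matches & n26 == 5L
  if (!allow_pos1_mismatch) ok <- ok & eq1
  which(ok) - 1L
}

# --- misc fixtures --------------------------------------------------------
random_reads <- function(n, chroms = "chr1", max_pos = 1000L,
                         lens = 24:32, max_copies = 5L, sample = "s1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(lens, n, replace = TRUE)
  pirna_reads(chrom = sample(chroms, n, replace = TRUE),
              start = start, end = start + len,
              strand = sample(c("+", "-"), n, replace = TRUE),
              copies = sample.int(max_copies, n, replace = TRUE),
              sample = sample)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

# small, fast simulation for ping-pong-only experiments
pingpong_config <- function(fraction, seed, n_reads = 400L) {
  simulation_config(genome_length = 30000L, n_clusters = 2L,
                    cluster_length = 3000L, pingpong_fraction = fraction,
                    n_transcripts = 0L, n_planted_targets = 0L,
                    n_replicates = 1L, n_reads_per_library = n_reads,
                    seed = seed)
}

simulate_reads_only <- function(cfg) {
  gen <- simulate_genome(cfg)
  simulate_pirna_libraries(cfg, gen$genome, gen)
}
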