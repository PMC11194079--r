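test_that("representative collapse merges identical 25-mers", {
  genome <- c(chr1 = random_seq(200))
  # same 5' end and strand, different lengths -> one representative
  r <- rbind(pirna_reads("chr1", 50, 78, "+", name = "a", copies = 2L),
             pirna_reads("chr1", 50, 81, "+", name = "b", copies = 3L))
  col <- collapse_representatives(r, genome)
  expect_equal(nrow(col$representatives), 1L)
  expect_equal(col$representatives$abundance, 5)
  expect_equal(col$representatives$sequence, unname(substr(genome, 51, 75)))
  # mirrored opposite-strand reads stay distinct
  r2 <- rbind(pirna_reads("chr1", 50, 80, "+"),
              pirna_reads("chr1", 50, 80, "-"))
  expect_equal(nrow(collapse_representatives(r2, genome)$representatives), 2L)
  # contig-edge reads are skipped with a warning
  r3 <- pirna_reads("chr1", 190, 199, "+")
  expect_warning(col3 <- collapse_representatives(r3, genome), "skipped")
  expect_equal(col3$n_skipped, 1L)
})

test_that("representative abundances equal a brute-force 25-mer tally", {
  set.seed(14)
  genome <- c(chr1 = random_seq(2000))
  r <- random_reads(1000, max_pos = 1900)
  r <- r[(strand == "+" & p5 + 25 <= 2000) | (strand == "-" & p5 >= 24)]
  col <- collapse_representatives(r, genome)
  bf <- vapply(seq_len(nrow(r)), function(i) {
    if (r$strand[i] == "+") substr(genome, r$p5[i] + 1, r$p5[i] + 25)
    else revcomp_chr(substr(genome, r$p5[i] - 23, r$p5[i] + 1))
  }, "")
  tally <- tapply(as.numeric(r$copies), bf, sum)
  expect_equal(nrow(col$representatives), length(tally))
  expect_equal(col$representatives$abundance,
               as.numeric(tally[col$representatives$sequence]))
})

test_that("scan honours the complementarity rules on constructed cases", {
  set.seed(6)
  tx <- random_seq(400)
  site <- substr(tx, 101, 125)
  pirna <- revcomp_chr(site)            # perfect antisense complement
  hits <- scan_targets(pirna, tx)
  expect_true(100 %in% hits$site_start)
  h <- hits[site_start == 100]
  expect_equal(h$matches_7_25, 19L)
  expect_equal(h$mismatch_positions, "")
  expect_equal(h$pairing_start, 124L)
  expect_equal(h$cut, 115L)             # base paired to piRNA nt 10
  # mismatch at piRNA position 1 (transcript base opposite nt 1) is allowed
  tx1 <- tx
  substr(tx1, 125, 125) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tx, 125, 125))[1]
  h1 <- scan_targets(pirna, tx1)[site_start == 100]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mismatch_positions, "1")
  expect_equal(nrow(scan_targets(pirna, tx1,
                                 allow_pos1_mismatch = FALSE)[site_start == 100]),
               0L)
  # six extra mismatches opposite positions 7-25 -> only 13 matches, rejected
  tx6 <- tx1
  for (p in c(7L, 9L, 12L, 15L, 20L, 25L)) {
    i <- 100L + 26L - p                # 1-based transcript base opposite p
    substr(tx6, i, i) <- setdiff(c("A", "C", "G", "T"), substr(tx6, i, i))[1]
  }
  expect_equal(nrow(scan_targets(pirna, tx6)[site_start == 100]), 0L)
  # a seed (2-6) mismatch kills the register even with 14+ matches
  txs <- tx
  substr(txs, 121, 121) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tx, 121, 121))[1]  # opposite nt 4
  expect_equal(nrow(scan_targets(pirna, txs)[site_start == 100]), 0L)
  expect_equal(nrow(scan_targets(pirna, txs,
                                 seed_exact = FALSE)[site_start == 100]), 1L)
})

test_that("short transcripts and relaxed thresholds behave as specified", {
  p <- random_seq(25)
  expect_equal(nrow(scan_targets(p, random_seq(20))), 0L)
  # monotonicity: relaxing min-matches never loses candidates
  set.seed(33)
  for (i in 1:10) {
    tx <- random_seq(300)
    p <- random_seq(25)
    n14 <- nrow(scan_targets(p, tx, min_matches = 14))
    n13 <- nrow(scan_targets(p, tx, min_matches = 13))
    expect_gte(n13, n14)
  }
})

test_that("production scan agrees with the dense per-register oracle", {
  set.seed(77)
  # literal double-loop oracle on short transcripts
  for (i in 1:30) {
    tx <- random_seq(120)
    site <- substr(tx, 41, 65)
    p <- revcomp_chr(site)
    nmut <- sample(0:7, 1)
    if (nmut) for (q in sample(25, nmut)) {
      i1 <- 40L + 26L - q
      substr(tx, i1, i1) <- sample(c("A", "C", "G", "T"), 1)
    }
    expect_equal(scan_targets(p, tx)$site_start, oracle_scan(p, tx))
  }
  # batched scanner agrees with the per-pair scanner
  txs <- setNames(vapply(1:5, function(i) random_seq(500), ""),
                  paste0("tx", 1:5))
  ps <- vapply(1:20, function(i) random_seq(25), "")
  planted <- revcomp_chr(substr(txs[[2]], 101, 125))
  ps <- c(ps, planted)
  batch <- scan_all_targets(ps, txs)
  single <- data.table::rbindlist(lapply(names(txs), function(tn) {
    data.table::rbindlist(lapply(ps, function(p) {
      h <- scan_targets(p, txs[[tn]])
      if (nrow(h)) cbind(data.table(pirna = p, transcript = tn), h)
    }))
  }))
  data.table::setorder(single, transcript, pirna, site_start)
  expect_equal(as.data.frame(batch), as.data.frame(single))
  expect_true(nrow(batch[pirna == planted & transcript == "tx2"]) >= 1)
})

test_that("degradome support applies tolerance and the both-replicate rule", {
  sites <- data.table(pirna = "P", transcript = c("t1", "t2"),
                      cut = c(50L, 80L))
  deg <- data.table(replicate = c(1L, 2L, 1L),
                    transcript = c("t1", "t1", "t2"),
                    pos = c(50L, 50L, 80L))
  s <- degradome_support(sites, deg)
  expect_equal(s$supported, c(TRUE, FALSE))   # t2 in one replicate only
  expect_equal(s$n_replicates_supported, c(2L, 1L))
  # offset by 1: unsupported at tolerance 0, supported at 1
  deg1 <- data.table(replicate = c(1L, 2L), transcript = "t1",
                     pos = c(51L, 49L))
  expect_false(degradome_support(sites[1], deg1)$supported)
  expect_true(degradome_support(sites[1], deg1, tolerance = 1)$supported)
  # < 2 replicates can never support
  s1 <- degradome_support(sites, deg[replicate == 1])
  expect_true(attr(s1, "insufficient_replicates"))
  expect_false(any(s1$supported))
})

test_that("metatranscript assignment and conservation", {
  reg <- data.table(transcript = c("t1", "t2"),
                    utr5_len = c(100L, 0L), cds_len = c(600L, 0L),
                    utr3_len = c(100L, 0L))
  sites <- data.table(transcript = c("t1", "t1", "t1", "t2"),
                      cut = c(700L, 400L, 10L, 5L))
  md <- metatranscript_distribution(sites, reg)
  expect_equal(md$sites$region, c("3'UTR", "CDS", "5'UTR", "noncoding"))
  expect_equal(md$sites$meta_position[1], 0.0)    # first base of 3'UTR
  expect_equal(md$sites$meta_position[2], 0.5)    # CDS midpoint
  expect_equal(sum(md$region_counts), nrow(sites))
})

test_that("repeat classes follow strand agreement and largest overlap", {
  reps <- data.table(chrom = "chr1", start = c(100L, 300L),
                     end = c(200L, 400L), strand = c("+", "-"))
  f <- data.table(chrom = "chr1",
                  start = c(120L, 120L, 500L), end = c(145L, 145L, 525L),
                  strand = c("+", "-", "+"))
  expect_equal(repeat_overlap(f, reps), c("sense", "antisense", "none"))
  # overlapping both-strand repeats: larger overlap wins
  reps2 <- data.table(chrom = "chr1", start = c(100L, 125L),
                      end = c(135L, 230L), strand = c("+", "-"))
  f2 <- data.table(chrom = "chr1", start = 120L, end = 145L, strand = "+")
  expect_equal(repeat_overlap(f2, reps2), "antisense")  # 20 nt beats 15 nt
})
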