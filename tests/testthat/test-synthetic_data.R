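small_cfg <- function(seed = 1, n_replicates = 2L, ...) {
  simulation_config(genome_length = 40000L, n_clusters = 2L,
                    cluster_length = 3000L, n_transcripts = 6L,
                    n_planted_targets = 3L, n_reads_per_library = 200L,
                    n_replicates = n_replicates, seed = seed, ...)
}

test_that("configuration validation rejects invalid worlds", {
  expect_error(simulation_config(pingpong_fraction = 1.5))
  expect_error(simulation_config(nb_dispersion = -1))
  lm <- default_length_model()
  names(lm$MIWI)[1] <- "23"
  expect_error(simulation_config(length_model = lm), "24-40")
  expect_error(simulate_genome(simulation_config(genome_length = 1000L,
                                                 cluster_length = 5000L)),
               "bounds")
})

test_that("genome layout: disjoint clusters, gene structure, 3'UTR repeats", {
  gen <- simulate_genome(simulation_config(n_clusters = 2L,
                                           genome_length = 100000L))
  expect_equal(nrow(gen$clusters), 2L)
  expect_true(all(gen$clusters$end <= 100000L))
  o <- order(gen$clusters$start)
  expect_true(all(head(gen$clusters$end[o], -1) <=
                    tail(gen$clusters$start[o], -1)))
  expect_true(all(gen$genes$utr5_len + gen$genes$cds_len +
                    gen$genes$utr3_len == gen$genes$end - gen$genes$start))
  # repeats sit inside 3'UTRs
  u3 <- gen$genes[, .(start = start + utr5_len + cds_len, end = end)]
  for (i in seq_len(nrow(gen$repeats)))
    expect_true(any(gen$repeats$start[i] >= u3$start &
                      gen$repeats$end[i] <= u3$end))
  # degenerate case: no clusters is a valid world
  gen0 <- simulate_genome(simulation_config(n_clusters = 0L,
                                            pingpong_fraction = 0))
  expect_equal(nrow(gen0$clusters), 0L)
  expect_equal(unname(nchar(gen0$genome)), 100000L)
})

test_that("generation is deterministic, byte for byte", {
  s1 <- simulate_dataset(small_cfg(seed = 42))
  s2 <- simulate_dataset(small_cfg(seed = 42))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$degradome, s2$degradome)
  expect_identical(s1$gene_counts, s2$gene_counts)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  s3 <- simulate_dataset(small_cfg(seed = 43))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("planted pair bookkeeping matches the stated fractions", {
  lib0 <- simulate_reads_only(pingpong_config(0, seed = 2))
  expect_equal(nrow(lib0$truth$planted_pairs), 0L)
  # fraction 0.5, 1000 responders in total over 4 libraries of 250 each
  lib <- simulate_reads_only(pingpong_config(0.5, seed = 2, n_reads = 500L))
  n <- nrow(lib$truth$planted_pairs)
  expect_true(n >= qbinom(0.005, 1000, 0.5) && n <= qbinom(0.995, 1000, 0.5))
  # exact count reproduced by rerun
  lib2 <- simulate_reads_only(pingpong_config(0.5, seed = 2, n_reads = 500L))
  expect_equal(nrow(lib2$truth$planted_pairs), n)
  # cluster too short for planting errors out
  expect_error(simulate_reads_only(
    simulation_config(genome_length = 2000L, n_clusters = 1L,
                      cluster_length = 30L, pingpong_fraction = 0.5,
                      n_transcripts = 0L, n_planted_targets = 0L)),
    "cluster")
})

test_that("planted pairs score distance 10 under the pipeline's own metric", {
  lib <- simulate_reads_only(pingpong_config(0.6, seed = 9))
  pairs <- lib$truth$planted_pairs
  reads <- lib$reads
  m <- merge(pairs,
             reads[, .(plus_name = name, p_plus = p5)], by = "plus_name")
  m <- merge(m, reads[, .(minus_name = name, p_minus = p5)],
             by = "minus_name")
  expect_true(all(m$p_minus - m$p_plus + 1L == 10L))
})

test_that("primary reads carry the 1U bias", {
  lib <- simulate_reads_only(pingpong_config(0, seed = 5, n_reads = 600))
  gen <- lib$genome
  prim <- lib$reads[strand == "+"]
  first <- substr(gen[prim$chrom], prim$p5 + 1L, prim$p5 + 1L)
  expect_gte(mean(first == "T"), 0.8)
})

test_that("read lengths follow the per-protein models", {
  lib <- simulate_reads_only(pingpong_config(0, seed = 6, n_reads = 2000))
  miwi <- lib$reads[grepl("^MIWI", sample)]
  mili <- lib$reads[grepl("^MILI", sample)]
  expect_true(mean(miwi$length %in% 29:31) > 0.7)
  expect_true(mean(mili$length %in% 26:27) > 0.55)
  expect_true(all(lib$reads$length %in% 24:40))
})

test_that("every planted site passes the scanner and is degradome-closed", {
  sim <- simulate_dataset(small_cfg(seed = 31, degradome_depth = 5L,
                                    degradome_background_rate = 0))
  ps <- sim$truth$planted_sites
  expect_gt(nrow(ps), 0)
  for (i in seq_len(nrow(ps))) {
    hits <- scan_targets(ps$pirna[i], sim$transcripts[[ps$transcript[i]]])
    expect_true(ps$site_start[i] %in% hits$site_start)
    expect_true(ps$cut[i] %in% hits$cut)
  }
  expect_true(all(substr(ps$pirna, 1, 1) == "T"))   # targeting piRNAs are 1U
  # degradome records all coincide with planted cuts at background 0
  d <- merge(sim$degradome, ps[, .(transcript, cut)],
             by.x = c("transcript", "pos"), by.y = c("transcript", "cut"))
  expect_equal(nrow(d), nrow(sim$degradome))
  # depth 0 -> no support anywhere
  sim0 <- simulate_dataset(small_cfg(seed = 31, degradome_depth = 0L,
                                     degradome_background_rate = 0))
  expect_equal(nrow(sim0$degradome), 0L)
})

test_that("degradome background rate has the stated Poisson expectation", {
  cfg <- small_cfg(seed = 1, degradome_depth = 0L,
                   degradome_background_rate = 1e-3)
  gen <- simulate_genome(cfg)
  tx <- transcript_sequences(gen$genome, gen$genes)
  tot_len <- sum(nchar(tx))
  counts <- vapply(1:40, function(s) {
    c2 <- small_cfg(seed = s, degradome_depth = 0L,
                    degradome_background_rate = 1e-3)
    nrow(simulate_degradome(c2, data.table(transcript = character(),
                                           cut = integer()), tx))
  }, 0)
  lambda <- 1e-3 * tot_len * cfg$degradome_replicates
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.35)
})

test_that("count matrices carry the planted effects and the Poisson limit", {
  cfg <- small_cfg(seed = 8, target_effect = 4, pirna_effect = 4,
                   count_mean = 500, n_replicates = 3L)
  truth <- list(regulated_genes = c("gene001", "gene002"),
                down_pirnas = "AAAAAAAAAAAAAAAAAAAAAAAAA")
  genes <- sprintf("gene%03d", 1:6)
  pis <- c(truth$down_pirnas, "CCCCCCCCCCCCCCCCCCCCCCCCC")
  set.seed(77)
  ratios <- replicate(15, {
    cfg$seed <- sample.int(1e6, 1)
    cnt <- simulate_counts(cfg, genes, pis, truth)
    het <- rowMeans(cnt$gene_counts[, cnt$groups == "Het"])
    rk <- rowMeans(cnt$gene_counts[, cnt$groups == "RK"])
    mean(rk[truth$regulated_genes] / het[truth$regulated_genes])
  })
  expect_equal(mean(ratios), 4, tolerance = 0.25)
  # piRNA down-regulation
  set.seed(2)
  cnt <- simulate_counts(cfg, genes, pis, truth)
  expect_lt(mean(cnt$pirna_counts[1, cnt$groups == "RK"]),
            mean(cnt$pirna_counts[1, cnt$groups == "Het"]))
  # dispersion 0 -> Poisson-like variance
  cfg0 <- small_cfg(seed = 3, nb_dispersion = 0, count_mean = 100,
                    n_replicates = 2L)
  cnt0 <- simulate_counts(cfg0, genes, pis,
                          list(regulated_genes = character(),
                               down_pirnas = character()))
  expect_true(all(cnt0$gene_counts >= 0))
})
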