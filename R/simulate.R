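# Synthetic-data generator with a machine-readable ground truth.
#
# The generator states a small, explicit world: one chromosome carrying
# non-overlapping piRNA clusters and plus-strand genes with 5'UTR/CDS/3'UTR
# structure; MIWI-like (29-31 nt) and MILI-like (26-27 nt) read length
# models; a 1U bias >= 0.8; a controllable fraction of responder reads
# planted at exactly 10-nt 5' overlap with a primary partner; planted target
# sites written into 3'UTRs as the perfect reverse complement of a
# cluster-derived 25-mer (so every planted site passes the target scan by
# construction); degradome reads whose 5' ends sit exactly on planted cuts in
# every replicate; and negative-binomial counts across two genotypes
# ("Het" control, "RK" mutant) with planted gene up- and piRNA
# down-regulation. Every planted signal is recorded in the ground truth.

#' Build and validate a simulation configuration
#'
#' @param genome_length chromosome length in bases.
#' @param n_clusters,cluster_length piRNA cluster count and length.
#' @param pingpong_fraction fraction in `[0, 1]` of responder reads placed at
#'   exactly 10-nt 5' overlap with a primary partner.
#' @param length_model per-protein probability vectors over read lengths
#'   24-40 nt (named `MIWI`, `MILI`).
#' @param abundance_model log-normal (`meanlog`, `sdlog`) for read copy
#'   numbers (rounded up).
#' @param u1_bias probability that a primary read starts at a genomic U.
#' @param n_transcripts number of genes; `utr5_len`, `cds_len`, `utr3_len`
#'   give their (fixed) region lengths.
#' @param n_planted_targets genes receiving a planted antisense target site
#'   in their 3'UTR.
#' @param target_effect multiplicative mRNA up-regulation of regulated genes
#'   in the mutant.
#' @param pirna_effect multiplicative down-regulation of targeting piRNAs in
#'   the mutant.
#' @param degradome_depth reads per planted cut per replicate (exact).
#' @param degradome_background_rate per-base rate of spurious degradome 5'
#'   ends.
#' @param degradome_replicates degradome replicate count (default 2).
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param n_replicates RNA/piRNA count replicates per genotype (>= 2).
#' @param n_reads_per_library aligned reads per (protein, genotype,
#'   replicate) library.
#' @param count_mean mean sequencing depth per feature in count matrices.
#' @param utr5_len,cds_len,utr3_len gene region lengths (nt).
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(genome_length = 100000L, n_clusters = 4L,
                              cluster_length = 4000L, pingpong_fraction = 0.5,
                              length_model = default_length_model(),
                              abundance_model = list(meanlog = 1, sdlog = 1.2),
                              u1_bias = 0.85,
                              n_transcripts = 20L, n_planted_targets = 8L,
                              target_effect = 4, pirna_effect = 4,
                              degradome_depth = 10L,
                              degradome_background_rate = 1e-4,
                              degradome_replicates = 2L,
                              nb_dispersion = 0.05, n_replicates = 3L,
                              n_reads_per_library = 1000L, count_mean = 200,
                              utr5_len = 100L, cds_len = 600L,
                              utr3_len = 300L, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_clusters = as.integer(n_clusters),
              cluster_length = as.integer(cluster_length),
              pingpong_fraction = pingpong_fraction,
              length_model = length_model, abundance_model = abundance_model,
              u1_bias = u1_bias,
              n_transcripts = as.integer(n_transcripts),
              n_planted_targets = as.integer(n_planted_targets),
              target_effect = target_effect, pirna_effect = pirna_effect,
              degradome_depth = as.integer(degradome_depth),
              degradome_background_rate = degradome_background_rate,
              degradome_replicates = as.integer(degradome_replicates),
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              n_reads_per_library = as.integer(n_reads_per_library),
              count_mean = count_mean,
              utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
              utr3_len = as.integer(utr3_len), seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

default_length_model <- function() {
  lens <- 24:40
  miwi <- setNames(rep(0.01, 17), lens)
  miwi[c("29", "30", "31")] <- c(0.22, 0.40, 0.24)
  miwi["28"] <- 0.02; miwi["32"] <- 0.02
  miwi <- miwi / sum(miwi)
  mili <- setNames(rep(0.01, 17), lens)
  mili[c("25", "26", "27", "28")] <- c(0.10, 0.38, 0.30, 0.07)
  mili <- mili / sum(mili)
  list(MIWI = miwi, MILI = mili)
}

validate_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0, cfg$n_clusters >= 0,
            cfg$cluster_length > 0,
            cfg$pingpong_fraction >= 0, cfg$pingpong_fraction <= 1,
            cfg$u1_bias >= 0, cfg$u1_bias <= 1,
            cfg$degradome_depth >= 0, cfg$degradome_background_rate >= 0,
            cfg$nb_dispersion >= 0, cfg$target_effect > 0,
            cfg$pirna_effect > 0, cfg$n_replicates >= 1,
            cfg$n_planted_targets <= cfg$n_transcripts)
  for (m in cfg$length_model) {
    lens <- as.integer(names(m))
    if (any(lens < 24L | lens > 40L)) stop("length model outside 24-40 nt")
    if (abs(sum(m) - 1) > 1e-8) stop("length model must sum to 1")
  }
  invisible(cfg)
}

#' Simulate a toy genome with cluster, gene and repeat annotations
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character), `clusters`, `genes`
#'   (`gene`, coordinates, region lengths), `repeats` (all 0-based half-open
#'   BED-like tables). Clusters occupy the first half of the chromosome,
#'   genes the second; a 40-nt repeat is embedded in every other gene's
#'   3'UTR.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  genome <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  # clusters, evenly spaced in the first half
  cl <- data.table(chrom = character(), start = integer(), end = integer(),
                   name = character(), score = numeric(), strand = character())
  if (config$n_clusters > 0) {
    pitch <- (L %/% 2) %/% config$n_clusters
    if (pitch < config$cluster_length)
      stop("cluster annotation exceeds genome bounds")
    st <- (seq_len(config$n_clusters) - 1L) * pitch
    cl <- data.table(chrom = "chr1", start = st,
                     end = st + config$cluster_length,
                     name = paste0("cluster", seq_len(config$n_clusters)),
                     score = 0, strand = "+")
  }
  # genes, evenly spaced in the second half, plus strand
  txlen <- config$utr5_len + config$cds_len + config$utr3_len
  genes <- data.table(gene = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      utr5_len = integer(), cds_len = integer(),
                      utr3_len = integer())
  if (config$n_transcripts > 0) {
    pitch <- (L - L %/% 2) %/% config$n_transcripts
    if (pitch < txlen) stop("gene annotation exceeds genome bounds")
    st <- L %/% 2 + (seq_len(config$n_transcripts) - 1L) * pitch
    genes <- data.table(gene = sprintf("gene%03d", seq_len(config$n_transcripts)),
                        chrom = "chr1", start = st, end = st + txlen,
                        strand = "+", utr5_len = config$utr5_len,
                        cds_len = config$cds_len, utr3_len = config$utr3_len)
  }
  # repeats inside every other 3'UTR, random strand
  reps <- genes[seq_len(nrow(genes)) %% 2L == 1L]
  repeats <- if (nrow(reps)) {
    u3s <- reps$start + reps$utr5_len + reps$cds_len
    data.table(chrom = "chr1", start = u3s + 20L, end = u3s + 60L,
               name = paste0("rep_", reps$gene), score = 0,
               strand = sample(c("+", "-"), nrow(reps), replace = TRUE))
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character())
  }
  if (nrow(cl) && any(cl$end > L)) stop("cluster annotation exceeds genome bounds")
  if (nrow(genes) && any(genes$end > L)) stop("gene annotation exceeds genome bounds")
  list(genome = setNames(genome, "chr1"), clusters = cl, genes = genes,
       repeats = repeats)
}

#' Simulate piRNA libraries with planted ping-pong pairs and target sites
#'
#' Generates one library per (protein in MILI/MIWI, genotype in Het/RK,
#' replicate). Half of each library are primary plus-strand reads (1U bias
#' `u1_bias`), half are responders; each responder is planted on the minus
#' strand at exactly 10-nt 5' overlap with a random primary partner with
#' probability `pingpong_fraction`, otherwise placed uniformly. Planted
#' target sites are created by writing the reverse complement of a
#' cluster-derived 25-mer (the targeting piRNA, forced to start with U) into
#' a gene's 3'UTR, which edits the genome; the edited genome is returned and
#' must be used downstream.
#'
#' @param config a [simulation_config()].
#' @param genome named character vector from [simulate_genome()].
#' @param annotations list with `clusters` and `genes` tables.
#' @return list with `reads` (one read table, `sample` =
#'   `protein_genotype_rep`), `truth` (`planted_pairs`, `planted_sites`,
#'   `regulated_genes`, `down_pirnas`), and `genome` (edited).
#' @export
simulate_pirna_libraries <- function(config, genome, annotations) {
  set.seed(config$seed + 1L)
  cl <- annotations$clusters
  genes <- annotations$genes
  if (config$pingpong_fraction > 0 && !nrow(cl))
    stop("ping-pong planting requires at least one cluster")
  if (nrow(cl) && config$pingpong_fraction > 0 && any(cl$end - cl$start < 40L))
    stop("cluster shorter than 40 nt cannot host planted ping-pong pairs")
  gseq <- genome[[1]]
  chrom <- names(genome)[1]

  # --- plant target sites: piRNA origins in cluster 1, sites in 3'UTRs ---
  n_t <- min(config$n_planted_targets, nrow(genes))
  planted_sites <- data.table(pirna = character(), transcript = character(),
                              site_start = integer(), cut = integer(),
                              origin_p5 = integer())
  if (n_t > 0) {
    if (!nrow(cl)) stop("planted targets require a cluster for piRNA origins")
    tgt_genes <- genes[sort(sample.int(nrow(genes), n_t))]
    slot0 <- cl$start[1]
    for (i in seq_len(n_t)) {
      o <- slot0 + (i - 1L) * 30L               # origin 5' (plus strand)
      if (o + 25L > cl$end[1]) stop("cluster too short for planted origins")
      substr(gseq, o + 1L, o + 1L) <- "T"       # 1U for the targeting piRNA
      pseq <- substr(gseq, o + 1L, o + 25L)
      g <- tgt_genes[i]
      u3 <- g$start + g$utr5_len + g$cds_len    # 3'UTR start, genome coords
      w <- u3 + 100L                            # site window [w, w + 25)
      stopifnot(w + 25L <= g$end)
      substr(gseq, w + 1L, w + 25L) <- revcomp(pseq)
      planted_sites <- rbind(planted_sites, data.table(
        pirna = pseq, transcript = g$gene,
        site_start = w - g$start, cut = w - g$start + 15L, origin_p5 = o))
    }
  }

  # --- libraries ---
  maxlen <- 40L
  tpos_plus <- which(strsplit(gseq, "")[[1]] == "T") - 1L  # 0-based U starts
  all_reads <- list()
  pairs <- list()
  for (protein in c("MILI", "MIWI")) {
    lm <- config$length_model[[protein]]
    lens_dom <- as.integer(names(lm))
    for (genotype in c("Het", "RK")) for (rep in seq_len(config$n_replicates)) {
      smp <- paste(protein, genotype, rep, sep = "_")
      n <- config$n_reads_per_library
      n_prim <- ceiling(n / 2); n_resp <- n - n_prim
      # primaries: plus strand, uniform within a random cluster, 1U bias;
      # kept >= 31 nt from the cluster start so a planted minus-strand
      # responder (5' at p + 9) always fits in the genome
      ci <- sample.int(nrow(cl), n_prim, replace = TRUE)
      lo <- cl$start[ci] + 31L; hi <- cl$end[ci] - maxlen
      if (any(hi <= lo)) stop("cluster too short to place reads")
      p5 <- lo + floor(runif(n_prim) * (hi - lo))
      forceU <- runif(n_prim) < config$u1_bias
      if (any(forceU) && length(tpos_plus)) {
        # snap to the nearest genomic T (vectorized; T density ~1/4 makes
        # the nearest T stay inside the cluster in practice)
        j <- which(forceU)
        right <- findInterval(p5[j], tpos_plus) + 1L
        left <- pmax(right - 1L, 1L)
        right <- pmin(right, length(tpos_plus))
        snap <- fifelse(abs(tpos_plus[left] - p5[j]) <=
                          abs(tpos_plus[right] - p5[j]),
                        tpos_plus[left], tpos_plus[right])
        ok_snap <- snap >= lo[j] & snap <= hi[j]
        p5[j[ok_snap]] <- snap[ok_snap]
      }
      plen <- sample(lens_dom, n_prim, replace = TRUE, prob = lm)
      prim <- data.table(chrom = chrom, start = p5, end = p5 + plen,
                         name = paste0(smp, "_p", seq_len(n_prim)),
                         copies = as.integer(ceiling(rlnorm(
                           n_prim, config$abundance_model$meanlog,
                           config$abundance_model$sdlog))),
                         strand = "+", sample = smp)
      # responders: minus strand; planted at d = 10 w.p. pingpong_fraction
      planted <- runif(n_resp) < config$pingpong_fraction
      partner <- sample.int(n_prim, n_resp, replace = TRUE)
      rlen <- sample(lens_dom, n_resp, replace = TRUE, prob = lm)
      m5 <- integer(n_resp)
      m5[planted] <- p5[partner[planted]] + 9L
      if (any(!planted)) {
        ci2 <- sample.int(nrow(cl), sum(!planted), replace = TRUE)
        lo2 <- cl$start[ci2] + maxlen; hi2 <- cl$end[ci2] - 1L
        m5[!planted] <- lo2 + floor(runif(sum(!planted)) * (hi2 - lo2))
      }
      resp <- data.table(chrom = chrom, start = m5 - rlen + 1L,
                         end = m5 + 1L,
                         name = paste0(smp, "_r", seq_len(n_resp)),
                         copies = as.integer(ceiling(rlnorm(
                           n_resp, config$abundance_model$meanlog,
                           config$abundance_model$sdlog))),
                         strand = "-", sample = smp)
      if (any(planted))
        pairs[[smp]] <- data.table(sample = smp,
                                   plus_name = prim$name[partner[planted]],
                                   minus_name = resp$name[planted])
      lib <- rbind(prim, resp)
      # targeting piRNAs live in the MIWI libraries: add their origin reads
      if (protein == "MIWI" && nrow(planted_sites)) {
        o <- planted_sites$origin_p5
        lib <- rbind(lib, data.table(
          chrom = chrom, start = o, end = o + 30L,
          name = paste0(smp, "_t", seq_along(o)), copies = 20L,
          strand = "+", sample = smp))
      }
      all_reads[[smp]] <- lib
    }
  }
  reads <- validate_reads(rbindlist(all_reads))
  genome[[1]] <- gseq
  truth <- list(
    planted_pairs = if (length(pairs)) rbindlist(pairs) else
      data.table(sample = character(), plus_name = character(),
                 minus_name = character()),
    planted_sites = planted_sites,
    regulated_genes = unique(planted_sites$transcript),
    down_pirnas = unique(planted_sites$pirna)
  )
  list(reads = reads, truth = truth, genome = genome)
}

#' Extract transcript sense sequences from the genome
#'
#' @param genome named character vector (use the edited genome returned by
#'   [simulate_pirna_libraries()]).
#' @param genes gene table from [simulate_genome()].
#' @return named character vector of transcript sequences (genes are
#'   plus-strand and unspliced in the simulated world).
#' @export
transcript_sequences <- function(genome, genes) {
  setNames(substr(genome[genes$chrom], genes$start + 1L, genes$end),
           genes$gene)
}

#' Simulate degradome 5'-end records
#'
#' Every planted cut receives exactly `degradome_depth` reads at the cut
#' coordinate in each replicate; spurious 5' ends are added at
#' `degradome_background_rate` per transcript base (Poisson), uniformly
#' placed.
#'
#' @param config a [simulation_config()].
#' @param planted_sites `truth$planted_sites` table (`transcript`, `cut`).
#' @param transcripts named character vector of transcript sequences.
#' @return `data.table` with `replicate`, `transcript`, `pos` (0-based 5'
#'   end), `count`.
#' @export
simulate_degradome <- function(config, planted_sites, transcripts) {
  set.seed(config$seed + 2L)
  txlen <- nchar(transcripts)
  if (nrow(planted_sites)) {
    bad <- planted_sites$cut >= txlen[planted_sites$transcript] |
      planted_sites$cut < 0
    if (any(bad)) stop("planted cut outside transcript bounds")
  }
  out <- list()
  for (r in seq_len(config$degradome_replicates)) {
    if (nrow(planted_sites) && config$degradome_depth > 0)
      out[[length(out) + 1L]] <- data.table(
        replicate = r, transcript = planted_sites$transcript,
        pos = planted_sites$cut, count = config$degradome_depth)
    n_bg <- rpois(1, config$degradome_background_rate * sum(txlen))
    if (n_bg > 0) {
      tx <- sample(names(transcripts), n_bg, replace = TRUE,
                   prob = txlen / sum(txlen))
      out[[length(out) + 1L]] <- data.table(
        replicate = r, transcript = tx,
        pos = floor(runif(n_bg) * txlen[tx]), count = 1L)
    }
  }
  if (!length(out))
    return(data.table(replicate = integer(), transcript = character(),
                      pos = integer(), count = integer()))
  rbindlist(out)
}

#' Simulate gene and piRNA count matrices across genotypes
#'
#' Negative-binomial counts (`nb_dispersion = 0` gives the Poisson limit)
#' with equal means across genotypes except that regulated genes are scaled
#' by `target_effect` and down-regulated piRNAs by `1/pirna_effect` in the
#' mutant ("RK") genotype. Per-feature base means are log-normal around
#' `count_mean`; piRNA base means are proportional to library abundance when
#' supplied.
#'
#' @param config a [simulation_config()] (`n_replicates >= 2`).
#' @param genes gene table (or character vector of gene ids).
#' @param pirnas representative table with `sequence` and `abundance`
#'   columns (or character vector of piRNA sequences).
#' @param truth ground-truth list (`regulated_genes`, `down_pirnas`).
#' @return list with `gene_counts` and `pirna_counts` (integer matrices,
#'   columns `Het_1..n, RK_1..n`) and `groups` (genotype factor).
#' @export
simulate_counts <- function(config, genes, pirnas, truth) {
  if (config$n_replicates < 2L) stop("n_replicates must be >= 2")
  set.seed(config$seed + 3L)
  gene_ids <- if (is.character(genes)) genes else genes$gene
  pi_ids <- if (is.character(pirnas)) pirnas else pirnas$sequence
  pi_w <- if (is.character(pirnas) || !"abundance" %in% names(pirnas))
    rep(1, length(pi_ids)) else pirnas$abundance
  samples <- paste(rep(c("Het", "RK"), each = config$n_replicates),
                   seq_len(config$n_replicates), sep = "_")
  groups <- factor(rep(c("Het", "RK"), each = config$n_replicates),
                   levels = c("Het", "RK"))
  draw <- function(mu_mat) {
    n <- length(mu_mat)
    cnt <- if (config$nb_dispersion > 0)
      rnbinom(n, mu = mu_mat, size = 1 / config$nb_dispersion)
    else rpois(n, mu_mat)
    matrix(as.integer(cnt), nrow = nrow(mu_mat),
           dimnames = dimnames(mu_mat))
  }
  gmu <- rlnorm(length(gene_ids), log(config$count_mean), 0.5)
  gmat <- matrix(gmu, length(gene_ids), length(samples),
                 dimnames = list(gene_ids, samples))
  up <- gene_ids %in% truth$regulated_genes
  gmat[up, groups == "RK"] <- gmat[up, groups == "RK"] * config$target_effect
  pmu <- pi_w / mean(pi_w) * config$count_mean
  pmat <- matrix(pmu, length(pi_ids), length(samples),
                 dimnames = list(pi_ids, samples))
  dn <- pi_ids %in% truth$down_pirnas
  pmat[dn, groups == "RK"] <- pmat[dn, groups == "RK"] / config$pirna_effect
  list(gene_counts = draw(gmat), pirna_counts = draw(pmat), groups = groups)
}

#' Run the full generator
#'
#' Orchestrates [simulate_genome()], [simulate_pirna_libraries()],
#' [simulate_degradome()] and [simulate_counts()] under a single
#' configuration; deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `genome` (edited), `clusters`, `genes`,
#'   `repeats`, `transcripts`, `reads`, `truth`, `degradome`, `gene_counts`,
#'   `pirna_counts`, `groups`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  validate_config(config)
  gen <- simulate_genome(config)
  lib <- simulate_pirna_libraries(config, gen$genome, gen)
  tx <- transcript_sequences(lib$genome, gen$genes)
  deg <- simulate_degradome(config, lib$truth$planted_sites, tx)
  # piRNA count matrix rows: representatives collapsed from one MIWI library
  miwi1 <- lib$reads[sample == paste0("MIWI_Het_1")]
  reps <- collapse_representatives(miwi1, lib$genome)$representatives
  cnt <- simulate_counts(config, gen$genes, reps, lib$truth)
  list(config = config, genome = lib$genome, clusters = gen$clusters,
       genes = gen$genes, repeats = gen$repeats, transcripts = tx,
       reads = lib$reads, truth = lib$truth, degradome = deg,
       gene_counts = cnt$gene_counts, pirna_counts = cnt$pirna_counts,
       groups = cnt$groups)
}

#' Write a simulated dataset to standard file formats
#'
#' FASTA genome; BED6 clusters/genes/repeats and per-sample reads (copy
#' number in the score column); degradome records as BED6 per replicate in
#' transcript space; counts, region table and ground truth as TSV; the
#' configuration as JSON.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_fasta(sim$genome, fp("genome.fa"))
  write_bed(sim$clusters, fp("clusters.bed"))
  write_bed(sim$genes[, .(chrom, start, end, name = gene, score = 0, strand)],
            fp("genes.bed"))
  write_bed(sim$repeats, fp("repeats.bed"))
  write_tsv(sim$genes, fp("genes.tsv"))
  for (s in unique(sim$reads$sample))
    write_bed(sim$reads[sample == s], fp(paste0("reads_", s, ".bed")))
  for (r in unique(sim$degradome$replicate)) {
    d <- sim$degradome[replicate == r]
    write_bed(data.table(chrom = d$transcript, start = d$pos,
                         end = d$pos + 1L, name = ".", score = d$count,
                         strand = "+"),
              fp(paste0("degradome_rep", r, ".bed")))
  }
  write_counts(sim$gene_counts, fp("gene_counts.tsv"), "gene")
  write_counts(sim$pirna_counts, fp("pirna_counts.tsv"), "pirna")
  write_tsv(sim$truth$planted_pairs, fp("truth_planted_pairs.tsv"))
  write_tsv(sim$truth$planted_sites, fp("truth_planted_sites.tsv"))
  write_tsv(data.table(gene = sim$truth$regulated_genes),
            fp("truth_regulated_genes.tsv"))
  write_tsv(data.table(pirna = sim$truth$down_pirnas),
            fp("truth_down_pirnas.tsv"))
  jsonlite::write_json(unclass(sim$config), fp("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
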