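# End-to-end orchestration: simulate (or load) -> ping-pong -> length
# profiles -> expression filter -> collapse/scan/degradome -> DE ->
# integration, with a JSON report and TSV stage outputs.

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages run in dependency order; each stage's tables are written under
#' `outdir` before dependents start, and the summary report collects
#' z-scores and pair fractions per (protein, genotype), the median-length
#' difference summary, representative counts, theoretical versus supported
#' site counts, region and repeat-class tallies, and the regulated-pair
#' list. Two runs with the same configuration produce identical reports.
#'
#' @param config a [simulation_config()] (the dataset is generated from it),
#'   or a pre-built dataset from [simulate_dataset()].
#' @param outdir output directory; `NULL` (default) skips file output.
#' @param window,weighting ping-pong histogram parameters.
#' @param min_matches,allow_pos1_mismatch target-scan parameters.
#' @param tolerance degradome matching tolerance in nt.
#' @param expression_threshold expression filter (reads in >= 1 sample).
#' @param gene_adj_p,pirna_adj_p integration thresholds.
#' @return list with `report` (summary list) and the stage outputs
#'   (`pingpong`, `delta_median`, `representatives`, `sites`,
#'   `supported_sites`, `gene_de`, `pirna_de`, `regulated`).
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         window = 30L, weighting = "product",
                         min_matches = 14L, allow_pos1_mismatch = TRUE,
                         tolerance = 0L, expression_threshold = 100,
                         gene_adj_p = 0.1, pirna_adj_p = 0.25) {
  sim <- if (inherits(config, "simulation_config")) simulate_dataset(config)
         else config
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, file.path(outdir, "data"))
  }

  # --- stage: ping-pong per (protein, genotype), replicates pooled ---
  pp <- list()
  for (protein in c("MILI", "MIWI")) for (genotype in c("Het", "RK")) {
    lib <- sim$reads[grepl(paste0("^", protein, "_", genotype, "_"), sample)]
    h <- five_prime_distance_histogram(lib, window = window,
                                       weighting = weighting)
    zs <- pingpong_zscore(h)
    fr <- pingpong_pair_fraction(lib)
    pp[[paste(protein, genotype, sep = "_")]] <-
      list(z = zs$z, w10 = zs$w10, degenerate = zs$degenerate,
           pair_fraction = fr$fraction)
  }

  # --- stage: length profiles, Het vs RK per protein ---
  dm <- list()
  for (protein in c("MILI", "MIWI")) {
    a <- sim$reads[grepl(paste0("^", protein, "_Het_"), sample)]
    b <- sim$reads[grepl(paste0("^", protein, "_RK_"), sample)]
    d <- delta_median(a, b)
    dm[[protein]] <- list(n_shared = d$n_shared,
                          mean_delta = if (d$n_shared) mean(d$per_key$delta)
                                       else NA_real_)
  }

  # --- stage: targeting ---
  expressed <- expressed_transcript_filter(sim$gene_counts,
                                           expression_threshold)
  tx <- sim$transcripts[intersect(names(sim$transcripts), expressed)]
  miwi <- sim$reads[grepl("^MIWI_", sample)]
  col <- collapse_representatives(miwi, sim$genome)
  sites <- scan_all_targets(col$representatives, tx,
                            min_matches = min_matches,
                            allow_pos1_mismatch = allow_pos1_mismatch)
  supp <- degradome_support(sites, sim$degradome, tolerance = tolerance)
  regions <- metatranscript_distribution(
    supp, sim$genes[, .(transcript = gene, utr5_len, cds_len, utr3_len)])
  supp <- regions$sites
  origins <- representative_origin_intervals(
    col$representatives[match(supp$pirna, sequence)])
  supp[, repeat_class := repeat_overlap(origins, sim$repeats)]

  # --- stage: differential expression + integration ---
  gene_de <- differential_expression(sim$gene_counts, sim$groups)
  pirna_de <- differential_expression(sim$pirna_counts, sim$groups)
  known <- supp$pirna %in% pirna_de$feature
  reg <- integrate_regulated_targets(supp[known], gene_de, pirna_de,
                                     gene_adj_p = gene_adj_p,
                                     pirna_adj_p = pirna_adj_p)

  report <- list(
    seed = sim$config$seed,
    pingpong = pp,
    delta_median = dm,
    n_representatives = nrow(col$representatives),
    n_expressed_transcripts = length(tx),
    n_theoretical_sites = nrow(sites),
    n_supported_sites = sum(supp$supported),
    region_counts = as.list(regions$region_counts),
    repeat_class_counts = as.list(table(supp[supported == TRUE]$repeat_class)),
    n_regulated_genes = reg$n_genes,
    n_regulated_pirnas = reg$n_pirnas
  )
  out <- list(report = report, pingpong = pp, delta_median = dm,
              representatives = col$representatives, sites = sites,
              supported_sites = supp, gene_de = gene_de, pirna_de = pirna_de,
              regulated = reg)
  if (!is.null(outdir)) {
    write_tsv(supp, file.path(outdir, "sites.tsv"))
    write_tsv(gene_de, file.path(outdir, "gene_de.tsv"))
    write_tsv(pirna_de, file.path(outdir, "pirna_de.tsv"))
    write_tsv(reg$pairs, file.path(outdir, "regulated_pairs.tsv"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
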