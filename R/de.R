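# Differential expression (stand-in exact-style NB test) and the integration
# step that nominates piRNA-regulated genes.
#
# The test is deliberately simple: library-size normalization by total-count
# scaling, a common negative-binomial dispersion estimated by moments across
# features, and a two-sided conditional exact-style test on group sums
# (binomial conditional in the Poisson limit). It stands in for off-the-shelf
# GLM fitters; externally computed DE tables can be supplied to the
# integration step instead.

#' Expression filter: features with enough reads in at least one sample
#'
#' @param counts feature x sample count matrix.
#' @param threshold minimum reads (default 100).
#' @return character vector of retained feature ids
#'   (`max over samples >= threshold`).
#' @export
expressed_transcript_filter <- function(counts, threshold = 100) {
  rownames(counts)[apply(counts, 1, max) >= threshold]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues numeric vector in `[0, 1]`; `NA`s are propagated and do not
#'   count towards the family size.
#' @return adjusted p-values, clamped to `[0, 1]`, monotone in p-rank.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  m <- length(p)
  adj <- rep(NA_real_, length(pvalues))
  if (m) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj[ok] <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  }
  adj
}

#' Stand-in negative-binomial differential expression
#'
#' Computes per-feature log2 fold changes (group means of library-size
#' normalized counts with a 0.5-count prior) and two-sided p-values from a
#' conditional exact-style test of the group sums under a common
#' negative-binomial dispersion estimated by moments (binomial conditional
#' test in the Poisson limit when the dispersion estimate is <= 0), followed
#' by Benjamini-Hochberg adjustment.
#'
#' @param counts feature x sample count matrix.
#' @param groups factor/character vector over columns with exactly two
#'   levels; fold changes are `second level vs first level` (order of
#'   `levels(factor(groups))` unless `groups` is already a factor).
#' @param normalization `"total"` (total-count scaling, default) or
#'   `"median_ratio"` (median-of-ratios, DESeq-style).
#' @param dispersion optional known common dispersion; bypasses the moment
#'   estimate.
#' @return `data.table` with `feature`, `log2fc`, `pvalue`, `adj_p`;
#'   attribute `dispersion` holds the common dispersion used. All-zero
#'   features get `p = 1`, `log2fc = 0`.
#' @export
differential_expression <- function(counts, groups,
                                    normalization = c("total", "median_ratio"),
                                    dispersion = NULL) {
  normalization <- match.arg(normalization)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (length(groups) != ncol(counts)) stop("groups must match columns")
  sf <- size_factors(counts, normalization)
  norm <- sweep(counts, 2, sf, "/")
  g2 <- groups == levels(groups)[2]
  m1 <- rowMeans(norm[, !g2, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  if (is.null(dispersion)) dispersion <- common_dispersion(norm, g2)
  # conditional test on rounded normalized group sums
  s1 <- round(rowSums(norm[, !g2, drop = FALSE]))
  s2 <- round(rowSums(norm[, g2, drop = FALSE]))
  n1 <- sum(!g2); n2 <- sum(g2)
  pv <- vapply(seq_len(nrow(counts)), function(i)
    conditional_nb_test(s2[i], s1[i], n2, n1, dispersion), 0)
  zero <- (s1 + s2) == 0
  pv[zero] <- 1; log2fc[zero] <- 0
  res <- data.table(feature = rownames(counts), log2fc = log2fc,
                    pvalue = pv, adj_p = benjamini_hochberg(pv))
  setattr(res, "dispersion", dispersion)
  res[]
}

size_factors <- function(counts, normalization) {
  if (normalization == "total") {
    tot <- colSums(counts)
    return(tot / mean(tot))
  }
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use)) return(rep(1, ncol(counts)))
  apply(counts[use, , drop = FALSE], 2,
        function(cc) exp(median(log(cc) - lg[use])))
}

# pooled moment estimator of the common NB dispersion phi (var = mu + phi mu^2)
# from within-group means/variances of normalized counts
common_dispersion <- function(norm, g2) {
  num <- 0; den <- 0
  for (idx in list(!g2, g2)) {
    x <- norm[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# two-sided exact-style conditional test of S2 against S1 given S1 + S2 = t.
# Group sums are modelled NB(n_g mu, size n_g/phi) with equal per-sample means
# under the null; p is the minimum-likelihood two-sided tail. phi <= 0 falls
# back to the Poisson limit, where the conditional law is binomial.
conditional_nb_test <- function(s2, s1, n2, n1, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  pr <- n2 / (n1 + n2)
  # very large totals: evaluate only a wide window around the conditional
  # mean (mass outside is negligible at 30 sd)
  if (t > 20000) {
    mu2 <- t * pr
    sd2 <- sqrt(t * pr * (1 - pr) * (1 + max(phi, 0) * t / (n1 + n2)))
    k <- max(0, floor(mu2 - 30 * sd2)):min(t, ceiling(mu2 + 30 * sd2))
    if (!(s2 %in% k)) return(0)
  } else {
    k <- 0:t
  }
  if (phi <= 0) {
    f <- stats::dbinom(k, t, pr)
  } else {
    mu <- t / (n1 + n2)
    f <- stats::dnbinom(k, size = n2 / phi, mu = n2 * mu) *
      stats::dnbinom(t - k, size = n1 / phi, mu = n1 * mu)
  }
  tot <- sum(f)
  if (tot <= 0 || !is.finite(tot)) return(1)
  f <- f / tot
  min(1, sum(f[f <= f[match(s2, k)] * (1 + 1e-7)]))
}

#' Integrate supported target sites with differential expression
#'
#' Emits a (gene, piRNA) regulated pair for every degradome-supported site
#' whose gene is up-regulated and whose targeting piRNA is down-regulated at
#' the given thresholds. Tightening any threshold can only shrink the output.
#'
#' @param sites site table from [degradome_support()] (needs `pirna`,
#'   `transcript`, `cut`, `supported`); `gene` column optional (defaults to
#'   `transcript`).
#' @param gene_de,pirna_de DE tables with `feature`, `log2fc`, `adj_p`
#'   (as from [differential_expression()] or externally computed). Every
#'   gene/piRNA referenced by a supported site must be present.
#' @param gene_adj_p,gene_log2fc gene thresholds: `adj_p < gene_adj_p` and
#'   `log2fc > gene_log2fc` (defaults 0.1 and 0: up-regulated).
#' @param pirna_adj_p,pirna_log2fc piRNA thresholds: `adj_p < pirna_adj_p`
#'   and `log2fc < pirna_log2fc` (defaults 0.25 and 0: down-regulated).
#' @return list with `pairs` (site rows passing all three conditions, plus
#'   gene/piRNA DE columns, sorted by gene then cut), `n_genes`, `n_pirnas`.
#' @export
integrate_regulated_targets <- function(sites, gene_de, pirna_de,
                                        gene_adj_p = 0.1, gene_log2fc = 0,
                                        pirna_adj_p = 0.25, pirna_log2fc = 0) {
  sites <- as.data.table(sites)
  if (!"gene" %in% names(sites)) sites[, gene := transcript]
  sup <- sites[supported == TRUE]
  if (nrow(sup)) {
    gd <- as.data.table(gene_de)
    pd <- as.data.table(pirna_de)
    miss_g <- setdiff(sup$gene, gd$feature)
    if (length(miss_g)) stop("no gene DE entry for: ", miss_g[1])
    miss_p <- setdiff(sup$pirna, pd$feature)
    if (length(miss_p)) stop("no piRNA DE entry for: ", miss_p[1])
    sup <- merge(sup, gd[, .(gene = feature, gene_log2fc = log2fc,
                             gene_adj_p = adj_p)], by = "gene", sort = FALSE)
    sup <- merge(sup, pd[, .(pirna = feature, pirna_log2fc = log2fc,
                             pirna_adj_p = adj_p)], by = "pirna", sort = FALSE)
    th_ga <- gene_adj_p; th_gf <- gene_log2fc
    th_pa <- pirna_adj_p; th_pf <- pirna_log2fc
    sup <- sup[sup$gene_adj_p < th_ga & sup$gene_log2fc > th_gf &
               sup$pirna_adj_p < th_pa & sup$pirna_log2fc < th_pf]
    setorder(sup, gene, transcript, cut)
  } else {
    sup[, c("gene_log2fc", "gene_adj_p", "pirna_log2fc", "pirna_adj_p") :=
          list(numeric(), numeric(), numeric(), numeric())]
  }
  list(pairs = sup[], n_genes = uniqueN(sup$gene), n_pirnas = uniqueN(sup$pirna))
}
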