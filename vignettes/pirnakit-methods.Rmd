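---
title: "pirnakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirnakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

# Scope

pirnakit analyses aligned PIWI-interacting RNA (piRNA) libraries. It covers
the ping-pong amplification signature, 3′-end trimming comparison,
nucleotide composition and genomic origin, piRNA target prediction on
transcripts with degradome-seq (PARE) validation, a stand-in
differential-expression (DE) test, and the integration step that nominates
piRNA-regulated genes. It deliberately consumes *aligned* records (BED6 or
SAM): adapter trimming, alignment, and UMI deduplication are upstream
concerns, and the package assumes its inputs are already deduplicated and
uniquely mapped (SAM multimappers can be dropped on read via the `NH` tag
and secondary/supplementary flags).

All internal coordinates are 0-based, half-open. The 5′ end of a plus-strand
read is its `start`; of a minus-strand read, `end − 1`. Copy numbers of
collapsed reads travel in the BED score column (a `name_xN` suffix dialect
is also parsed).

# The ping-pong signature

Ping-pong amplification produces piRNA pairs on opposite genomic strands
whose 5′ ends overlap by exactly 10 nt. For a plus-strand read with 5′ end
$p$ and a minus-strand read with 5′ end $m$ on the same chromosome we define
the overlap distance

$$d = m - p + 1,$$

so the canonical configuration scores $d = 10$. The literature rarely writes
this arithmetic out; this convention makes a 10-nt overlap score exactly 10
and excludes non-overlapping geometries ($d \le 0$). Weights $w(d)$ are
accumulated over all opposite-strand pairs within a 30-nt window, either as
the product of copy numbers (default — an abundant pair contributes
proportionally) or as unit weight per read pair (`weighting = "unique"`);
published analyses generally do not state their weighting, so both are
exposed. In homotypic mode each unordered pair is counted once; in
heterotypic mode (e.g. MILI versus MIWI libraries) both orientations are
accumulated, which makes the histogram symmetric in its arguments.

The z-score standardises the weight at $d = 10$ against the other 29 bins:

$$z = \frac{w(r_{10}) - \operatorname{mean}(w(r_{\neq 10}))}
           {\sqrt{\operatorname{var}(w(r_{\neq 10})) / n}},\qquad n = 29,$$

with the unbiased ($n-1$) sample variance; the variance flavour is a
convention choice and is documented rather than hidden. Degenerate inputs
are flagged instead of silently returning numbers: zero background variance
with an excess at 10 yields `z = NA` with `degenerate = TRUE`, while a
perfectly flat histogram (including all-zero) yields $z = 0$ by symmetry.

The pair fraction is the copy-weighted fraction of reads with at least one
opposite-strand partner at $d = 10$; in heterotypic mode it is reported per
library and pooled.

# Length profiles and 3′ trimming

3′-end comparisons group reads by (chromosome, strand, 5′ position),
restricted to 24–40 nt, and compute the copy-weighted median length per
group. For even total weight the *lower* median is used by default: it is
integer-valued, reproducible, and direction-consistent when detecting
truncation; a mid-point rule (which can yield half-integers) is offered.
The per-5′-end difference $\Delta = \mathrm{median}_b - \mathrm{median}_a$
over shared keys is the trimming readout; a uniform $k$-nt truncation of
library b shifts every shared key by exactly $-k$. The grouping is by
genomic position (the literal reading of "per 5′ start position"), not by
5′ sequence identity.

Genomic-origin assignment gives every read exactly one category, walking a
precedence list (default cluster > gene > repeat) and requiring at least
50% of the read's span to overlap the feature; unmatched reads are
intergenic. Precedence plus single assignment guarantee the categories
partition the read set — a conservation property the tests assert on random
inputs. Published pipelines delegate this step to external tools without
stating precedence; the default here is explicit and configurable.

Nucleotide composition extracts read sequences 5′→3′ (reverse complement on
the minus strand), reports T as U, and normalises each position over the
reads that reach it, so every row is a probability vector; the position-1 U
fraction (1U bias) is reported separately.

# Target prediction and degradome validation

A piRNA *representative* is the 25 genomic nucleotides downstream of the
mapped 5′ end in the read's orientation; length variants sharing those 25 nt
collapse into a single identity whose abundance is the copy-weighted sum per
sample. Reads within 25 nt of a contig edge on their 3′ side are skipped
with a warning count.

The scanner slides the 25-mer antisense along the transcript sense sequence,
ungapped, every register. Pairing geometry: piRNA nt $i$ faces transcript
position $s + 25 - i$ for a site starting at $s$, so nt 1 faces the
3′-most base of the site. A register passes when

* positions 2–6 pair perfectly (the published rule allows a mismatch only
  "at the first position" and constrains 7–25, leaving 2–6 implicitly
  exact; a switch relaxes this),
* position 1 is free,
* positions 7–25 contain ≥ 14 Watson–Crick pairs.

G:U wobble counts as a mismatch and there are no indels — the rules are
stated as ungapped complementarity with a match count. The predicted cut is
the transcript base paired to piRNA nt 10: slicing occurs across the
nt 10–11 junction and the degradome fragment's 5′ base is that coordinate.
All passing registers are reported unmerged with distinct coordinates.

Degradome validation is per replicate: a replicate supports a site when a
degradome 5′ end lies within `tolerance` nt of the cut (default 0, exact
coincidence); the verdict requires *all* replicates, and with fewer than two
replicates no site can be supported (flagged). Matching is done in
transcript space. Theoretical targeting (no degradome) and supported
targeting are separate stages; only transcripts passing the expression
filter (≥ 100 reads in at least one sample) enter the scan.

The production scanner anchors candidate registers on the exact 2–6 seed
(a hash join on the corresponding transcript 5-mer) before running the full
check; this is an exact optimisation — a register with a perfect 2–6
pairing necessarily contains that 5-mer — and the test suite verifies
equality against a dense every-register oracle on 10⁴ random pairs.

Region assignment places each cut in 5′UTR/CDS/3′UTR by coordinate, with
`meta_position` the fractional position within the region; transcripts
without a CDS are noncoding. Repeat classes are `sense`/`antisense` by
strand agreement between the feature (e.g. the piRNA's 25-nt origin
interval) and the repeat annotation, ties resolved by largest overlap.

# Differential expression and integration

The DE test is an explicit stand-in, not a re-implementation of a GLM
framework: library-size normalisation (total-count scaling by default,
median-of-ratios offered), log2 fold change of normalised group means with
a 0.5-count prior, and a two-sided conditional exact-style test of the
normalised group sums under a common negative-binomial dispersion estimated
by moments ($\widehat{\phi} = \sum_f (v_f - m_f) / \sum_f m_f^2$ pooled
within groups; the Poisson limit, a conditional binomial test, when the
estimate is ≤ 0). Two-sided p-values use the minimum-likelihood tail.
Benjamini–Hochberg step-up adjustment follows, implemented directly and
tested against `stats::p.adjust`. Externally computed DE tables can be fed
straight into the integration step, which is the part that carries the
scientific logic.

Total-count scaling is composition-sensitive: when a large fraction of the
library is regulated in one direction, fold changes of the regulated
features are shrunk toward the null (at 25% of features up 4-fold, the
apparent log2 fold change drops from 2 to about 1.2). The tests document
this and use the composition-robust median-of-ratios normalisation where a
calibrated effect-size estimate is asserted.

Integration emits a (gene, piRNA) pair for every degradome-supported site
whose gene is up-regulated (default `adj_p < 0.1`, `log2fc > 0`) and whose
targeting piRNA is down-regulated (default `adj_p < 0.25`, `log2fc < 0`).
The defaults mirror the integration thresholds used in the analyses this
package generalises; a stricter preset (`adj_p < 0.05`, fold change ≥ 2,
i.e. `log2fc ≥ 1`) is what those analyses use for standalone gene/TE DE
calls, and "fold change > 0"/"< 0" is interpreted on the log2 scale as
up/down. Integration is a pure filter — tightening any threshold can only
shrink the output — and this invariant is tested.

# The synthetic world

The generator states one explicit world and the tests live in it:

* one chromosome (default 100 kb); non-overlapping piRNA clusters in the
  first half, plus-strand unspliced genes with fixed 100/600/300 nt
  5′UTR/CDS/3′UTR structure in the second; 40-nt repeats embedded in every
  other 3′UTR.
* per-protein read-length models: MIWI-like peaked at 29–31 nt, MILI-like
  at 26–27 nt, supported on 24–40 nt — standard piRNA biology; the source
  study shows size profiles only in supplementary material, so the defaults
  are field-typical rather than fitted.
* copy numbers log-normal (meanlog 1, sdlog 1.2), rounded up: piRNA
  abundance is heavy-tailed.
* half of each library are plus-strand primaries with a 1U bias of 0.85
  (positions snapped to the nearest genomic T); the other half are
  responders, each planted on the minus strand at exactly $d = 10$ against
  a random primary with probability `pingpong_fraction`, otherwise placed
  uniformly. Planted pairs are recorded in the ground truth.
* planted target sites are constructed by forcing a cluster 25-mer to start
  with T (so targeting piRNAs are 1U), then writing its reverse complement
  into a gene's 3′UTR. Because transcripts are genome slices, this is a
  genome edit: `simulate_pirna_libraries()` therefore returns the edited
  genome, which downstream stages must use. Every planted site is a perfect
  antisense complement and passes the scanner by construction — a closure
  property the tests assert on every generated dataset.
* degradome records place exactly `degradome_depth` 5′ ends on each planted
  cut in every replicate (deterministic depth, so closure at depth ≥ 1 is
  exact), plus Poisson background at `degradome_background_rate` per
  transcript base.
* counts are negative-binomial (dispersion 0.05 by default; 0 gives the
  Poisson limit) across two genotypes — "Het" control and "RK" mutant —
  with regulated genes scaled by `target_effect` and targeting piRNAs by
  `1/pirna_effect` in the mutant. Default effects are 4-fold with 3
  replicates: chosen for statistical power of the end-to-end recovery
  tests, not to match any reported fraction (the source study reports no
  numerical ping-pong pair fractions at all).

Determinism: each generator stage seeds its own stream from
`seed + <stage offset>`, so identical configurations give byte-identical
outputs and stages can be rerun standalone.

What the world does **not** emulate: sequencing errors, multimapping, UMI
artefacts, spliced transcripts, minus-strand genes, batch effects, and
realistic repeat families. A green end-to-end test therefore establishes
that the pipeline's logic recovers planted signals under stated noise — not
that it reproduces any real dataset's headline numbers, which depend on
deposited sequencing data far beyond desk scale.

Two fields were added to the configuration beyond the obvious ones:
`n_reads_per_library` and `count_mean`, because library size and sequencing
depth are part of any stated world even when a specification leaves them
implicit.

# Numerical choices and edge cases

* Even-weight medians: lower-median default (see above).
* BH adjustment propagates `NA` p-values without counting them in the
  family size.
* All-zero count features get `p = 1`, `log2fc = 0`.
* Exact-test totals above 20 000 are evaluated on a ±30-standard-deviation
  window around the conditional mean; the truncated mass is far below
  p-value resolution.
* Empty inputs yield empty (flagged) results, not errors: empty read files,
  empty histograms, transcripts shorter than 25 nt.
* Non-ACGT characters never match in the scanner.

# Known limitations

* The stand-in DE test is calibrated (type-I error ≈ 0.05 in the tests'
  null world) but is not a replacement for edgeR/DESeq2 on real data; use
  the external-DE-table port for publication work.
* Degradome matching is transcript-space; genome-space projection of
  degradome records is the caller's responsibility.
* The scanner reports all passing registers unmerged; overlapping-register
  deduplication, if wanted, is downstream.
* `run_pipeline()` orchestrates the simulated world end to end; for real
  data the stage functions are called individually on files read through
  the `read_*` functions.
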