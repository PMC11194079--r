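# pirnakit

Analysis toolkit for PIWI-interacting RNA (piRNA) sequencing libraries, for
researchers studying germline small-RNA silencing: the ping-pong
amplification signature, 3′-end trimming, piRNA target prediction with
degradome-seq (PARE) cleavage validation, and the differential-expression
integration that nominates piRNA-regulated genes. A deterministic
synthetic-data generator with a machine-readable ground truth makes every
stage verifiable without access to real sequencing data.

## The statistics at the core

**Ping-pong z-score.** Ping-pong amplification produces piRNA pairs on
opposite genomic strands whose 5′ ends overlap by exactly 10 nt. With
overlap distance *d* = (5′ of minus read) − (5′ of plus read) + 1 and
weights *w(d)* accumulated over all opposite-strand read pairs in a 30-nt
window,

    z = ( w(r10) − mean(w(r≠10)) ) / sqrt( var(w(r≠10)) / n ),   n = 29.

**Target scan.** A piRNA representative is the 25 genomic nt downstream of
the mapped 5′ end. A transcript register is a target candidate when piRNA
positions 2–6 pair perfectly, position 1 is free, and positions 7–25
contain ≥ 14 Watson–Crick pairs (ungapped; G:U counts as a mismatch). The
predicted cut is the transcript base paired to piRNA nt 10 (slicing across
the nt 10–11 junction); a site is *supported* when a degradome 5′ end
coincides with the cut in **every** replicate.

**Integration.** A gene is nominated as piRNA-regulated when it carries a
supported site, is up-regulated (adj. P < 0.1, log2FC > 0) and its
targeting piRNA is down-regulated (adj. P < 0.25, log2FC < 0).

## Worked example

```r
library(pirnakit)

cfg <- simulation_config(seed = 1)     # the default synthetic world
sim <- simulate_dataset(cfg)

lib <- sim$reads[grepl("^MIWI_Het_", sample)]
h <- five_prime_distance_histogram(lib)
h$w[8:12]
#>     8     9    10    11    12
#>  3594  3874 41545  5215  3104
pingpong_zscore(h)
#> ping-pong z-score: 170.5316 (w10 = 41545, bg mean = 4821, bg var = 1.34489e+06, n = 29)
pingpong_pair_fraction(lib)$fraction
#> [1] 0.528

out <- run_pipeline(sim)
```

The histogram shows the planted ping-pong structure: the weight at distance
10 (41,545 copy-weighted pairs) towers over the ~4,800 background mean, and
about half of the library's copies sit in a d = 10 pair — the world was
simulated with `pingpong_fraction = 0.5`. The pipeline report for this run:

```
theoretical sites: 14 | supported: 8 | regulated genes: 8 | regulated piRNAs: 8
    5'UTR       CDS     3'UTR noncoding
        0         1        13         0
```

All 8 planted target sites are degradome-supported and recovered as
regulated (gene up, targeting piRNA down); predicted sites concentrate in
3′UTRs, where the generator plants them. Theoretical sites include
chance-complementarity candidates that lack degradome support.

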