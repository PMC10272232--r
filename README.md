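# cisray

Discovery of candidate cis-regulatory elements in the promoters of
treatment-responsive genes, with the statistical machinery needed to do it
reproducibly: reverse-complement-collapsed k-mer enrichment by the
hypergeometric test, expression-based gene classification, TSS-anchored
promoter extraction, and normalization of DNase I footprinting peak tables
with protection calling. The package was built around the auxin (IAA)
response of the charophyte alga *Klebsormidium nitens*, where this style of
analysis points at the RY motif (5′-TGCATG-3′ / 5′-GCATGC-3′, the binding
site of B3-domain transcription factors), but every stage is generic.

## Who it is for

Researchers with (1) a genome and gene annotation, (2) a per-gene table of
differential-expression statistics, and optionally (3) capillary
electrophoresis peak tables from a DNase I footprinting assay, who want to
ask: *which short sequence elements are over-represented in the promoters
of the genes that responded, and does a candidate protein protect them in
vitro?*

## The statistics at the core

**Gene groups.** From a table of per-gene p-values at two timepoints and
normalized read counts, genes are classified with strict cutoffs:
*upregulated* iff P < 0.01 at both timepoints; *non-responsive* iff
P > 0.9 at both timepoints **and** mean normalized counts > 100 (so "no
change" is backed by real expression); everything else is unclassified.

**Promoter windows.** For each gene the window −900..+100 relative to the
TSS (the annotated 5′ end of the gene) is extracted, reverse-complemented
for minus-strand genes, clipped and flagged at contig edges.

**k-mer class enrichment.** A k-mer and its reverse complement describe the
same double-stranded site, so the 4⁶ = 4096 hexamers collapse into
(4⁶ + 4³)/2 = **2080** classes. Each class is scored present/absent per
promoter, and its over-representation in a gene group is tested with the
upper-tail hypergeometric probability

  P(X ≥ x),  X ~ Hypergeom(N, K, n),

where N = all genes with windows, K = windows containing the class,
n = group size, x = containing windows in the group. Raw p-values are
reported for both groups (optionally BH-adjusted), plus a scatter export of
(−log10 p_up, −log10 p_nr) per class.

**Footprint normalization.** For replicate peak tables (3 × protein-free
"0 µM" vs 3 × protein-bound "3 µM"), the per-position log2 ratio of
condition means is ranked and the lowest/highest 30% discarded; per-sample
factors are then fitted so that each sample's log2 ratios to the reference
profile sum to exactly zero over the kept positions. Protected ("lost") and
hypersensitive ("gained") positions are called from the normalized heights
by effect size and Welch t-test.

All of this is testable end to end because the package ships a synthetic
data generator: genomes with a motif planted at known positions and
frequencies, statistics tables that satisfy the cutoffs by construction,
and peak tables with a known depleted interval.

## Worked example

Simulate a 500-gene genome with TGCATG planted in 60% of the 60 foreground
promoters (10% elsewhere), then run every stage:

```r
library(cisray)
cfg <- pipeline_config(outdir = "demo", simulate = TRUE, seed = 1,
                       sim_n_genes = 500, sim_n_foreground = 60,
                       sim_n_nonresponsive = 50)
res <- run_pipeline(cfg)
head(res$enrichment[, c("canonical","N","K","n_up","x_up","p_up","x_nr","p_nr")], 5)
```

```
[cisray] simulating genome (500 genes) and tables
[cisray] extracting promoter windows (-900..+100)
[cisray] 500 windows (0 clipped)
[cisray] classifying genes (p_up<0.01, p_nr>0.9, counts>100)
[cisray] 60 upregulated, 50 non-responsive
[cisray] testing 6-mer class enrichment
[cisray] top class: CATGCA (p_up = 3.04e-05)
[cisray] normalizing footprint peaks and calling protection
[cisray] 10 lost, 0 gained positions
  canonical   N   K n_up x_up         p_up x_nr      p_nr
1    CATGCA 500 234   60   43 3.039005e-05   17 0.9812128
2    GTAGAA 500 185   60   34 7.667763e-04   16 0.8224033
3    ATGCAT 500 126   60   26 8.127818e-04    8 0.9650708
4    CTCATC 500 191   60   34 1.555201e-03   17 0.7863121
5    GGGTTA 500 192   60   34 1.741327e-03   17 0.7950668
```

Reading the top row: 234 of 500 promoters contain the CATGCA class
(canonical form of TGCATG/CATGCA) somewhere, but 43 of the 60 upregulated
genes do — an excess with hypergeometric probability 3 × 10⁻⁵ — while the
non-responsive group shows no excess (p ≈ 0.98). That is the planted motif
ranking first, with the distinction between the two groups that makes it a
plausible response element rather than a generic promoter feature. The
footprint stage recovered all 10 positions of the simulated protected
interval with no false calls.

Each stage is also available on its own (`extract_promoter_windows()`,
`classify_genes()`, `kmer_enrichment()`, `normalize_peaks()`,
`call_protection()`, the `simulate_*()` generators), and
`inst/scripts/cisray.R` exposes them as shell subcommands
(`simulate`, `extract-promoters`, `classify`, `enrich`, `footprint`,
`report`).

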