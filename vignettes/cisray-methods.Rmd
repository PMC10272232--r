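---
title: "Methods: promoter k-mer enrichment and footprint normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter k-mer enrichment and footprint normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisray)
```

# Scope

cisray asks which short DNA elements are over-represented in the promoters
of genes that respond to a treatment, and whether a candidate DNA-binding
protein protects such elements from DNase I digestion in vitro. It was
designed around the auxin response of *Klebsormidium nitens*, where the
analysis highlights the RY motif (TGCATG/GCATGC, the B3-domain binding
site), but nothing in the code is organism-specific. The package consumes
the *outputs* of upstream pipelines — a per-gene differential-expression
statistics table and electropherogram peak tables — and deliberately does
not reimplement read mapping, count normalization, differential testing,
or raw capillary-trace processing.

# Gene classification

The two gene groups contrasted in the enrichment test come from strict
cutoffs on a per-gene table with p-values at two timepoints (10 h and 3 d
of treatment) and normalized read counts:

* **upregulated**: p < `p_up` at *both* timepoints (default 0.01);
* **non-responsive**: p > `p_nr` at both timepoints (default 0.9) *and*
  summarized normalized counts > `min_count` (default 100);
* everything else **unclassified**.

All inequalities are strict, so a gene sitting exactly on a cutoff is
unclassified. The count floor is what makes "non-responsive" an active
statement — a gene with no reads also shows no change. The table does not
say which samples the floor refers to, so the summary is configurable
(`count_summary = "mean"` by default; `"min"` is stricter). No
multiple-testing correction is applied to these screening cutoffs: they
select gene *sets*, they are not themselves inference. The p-values are
taken as given; if they are two-sided, direction of change must have been
encoded upstream (the synthetic generator sidesteps this by construction).

# Promoter windows

Windows span −`upstream`..+`downstream` around the TSS (defaults 900 and
100 bp, i.e. the common 1-kb promoter scan). The TSS is the annotated 5′
end of the gene feature: `start` for + strand genes, `end` for − strand
genes. Minus-strand sequences are reverse-complemented so every window
reads 5′→3′ relative to its gene. Design choices where conventions differ:

* **Internal coordinates** are 0-based half-open at the BED boundary;
  GFF3 input and the `GRanges` container use 1-based inclusive. The
  half-open sliding-window scan convention is documented rather than
  knowable from upstream tools.
* **Contig edges**: windows that would run off a contig are clipped, kept
  and flagged, not dropped. Dropping them would silently shrink the
  all-gene universe that serves as the enrichment background; a truncated
  window still contributes the presence information it has.
* **Soft-masking**: lowercase bases are uppercased before scanning; a
  masked-out analysis is not attempted.

# k-mer classes and the enrichment test

A k-mer and its reverse complement are the same double-stranded site, so
k-mers are collapsed into equivalence classes; the canonical
representative is the lexicographic minimum of the pair, a deterministic
choice that is invisible to the statistics. For even k there are
(4^k + 4^(k/2))/2 classes — 2080 hexamer classes, 64 of them palindromic —
and 4^k/2 for odd k.

Scoring is **presence/absence per promoter**, not occurrence counts: the
contingency table for a class is built from how many windows contain it at
least once. Windows containing ambiguous bases contribute nothing at those
positions. For each class, enrichment in a gene group of size n is the
inclusive upper tail P(X ≥ x) of the hypergeometric distribution with
universe N (all genes with windows, *including* the groups themselves —
the background is "all genes", not "all other genes"), K marked (windows
containing the class), and x observed. The tail is computed with
`stats::phyper`; the test suite checks it against literal enumeration of
every possible draw for all universes up to N = 12.

Both groups are tested against the same background, giving each class a
(p_up, p_nr) pair; a response element should be extreme in the first
coordinate and unremarkable in the second. The primary output is raw
p-values, with Benjamini–Hochberg q-values available behind a flag
(`with_q`), and a −log10 scatter export for plotting. The scatter export
is a generic paired transform; no claim is made about replicating any
specific figure's styling.

# Footprint normalization and protection calling

Replicate capillary electrophoresis runs differ in loading and detection
efficiency, so peak heights must be put on a common scale before the
protein-bound (3 µM) and protein-free (0 µM) conditions can be compared.
The procedure:

1. Per position p, compute r(p), the difference in mean log2 height
   between the reference and treatment conditions.
2. Rank positions by r(p) and discard the `floor(trim_frac * P)` lowest
   and highest (default `trim_frac = 0.3`). The extremes carry the
   candidate footprint/hypersensitivity signal plus outliers — exactly
   what must not drive the scaling. `floor` is used because no rounding
   rule is forced by the definition of a "lowest/highest 30%"; ties are
   broken by ascending position for determinism.
3. For each sample s, set log2 f_s = −mean over kept p of
   (log2 h(s,p) − mean0(p)), where mean0(p) is the mean log2 height of
   the reference samples. Each sample's log2 ratios to the reference
   profile then sum to exactly zero over the kept set.

**Why the reference profile is a log-space (geometric) mean.** The whole
procedure — the trim ratio, the zero-sum constraint, the calling statistic
— operates on log2 heights, and taking the within-condition average in the
same space buys exactness properties an arithmetic mean cannot provide:
renormalizing an already-normalized table returns factors of exactly 1
(the reference factors multiply to 1, so the reference profile is a fixed
point), and rescaling any single sample by c > 0 shifts every r(p) by the
same constant, leaving the trim ranking, the kept set, every normalized
ratio and every protection call bit-identical (for treatment samples even
the normalized heights are unchanged; for reference samples they pick up
one global factor c^(1/3), which cancels in every contrast). With an
arithmetic raw-height reference profile, both properties fail: the
product of reference factors exceeds 1 by the AM–GM gap, and rescaling a
reference sample perturbs r(p) non-uniformly. No normalization pinned to
the raw reference profile can leave heights fully invariant, so ratio
invariance is the strongest guarantee available, and the package attains
it exactly.

**Protection calls.** Per position, the effect is the difference in mean
log2 normalized height (treatment − reference) and the evidence a
two-sided Welch t-test on the log2 normalized heights; *lost* (protected)
requires effect < −`min_abs_effect` and p < `alpha`, *gained*
(hypersensitive) the mirror image. Defaults are `alpha = 0.05` and
`min_abs_effect = 1` (a two-fold floor). The effect floor is deliberate:
with 3-vs-3 replicates a pure t-test at α = 0.05 mislabels ~2.5% of null
positions per tail, which on a 50-position electropherogram means a false
"lost" call every other run; a two-fold floor removes those while leaving
a genuine five-fold protection (effect ≈ −2.3) untouched. Both knobs are
exposed, and the raw effect and p-value columns are always emitted so any
other decision rule can be applied downstream. Positions missing in some
sample are excluded, with a warning, from both factor fitting and calling:
the zero-sum contract needs complete rows.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth without external accessions.

* **Genome**: one contig, i.i.d. nucleotides with configurable GC content
  (default 0.5), genes placed in equal non-overlapping slots on random
  strands so each promoter window fits inside its slot. The default study
  design is 1997 genes: 90 foreground, 157 non-responsive, 1750 other,
  with TGCATG planted in 60% of foreground and 10% of other promoters —
  a planted-truth analogue of an 87/157-gene screening design against a
  ~2000-gene background. Planting *replaces* k bases at a uniform-random
  offset on a uniform-random strand (no coordinate shifts), at most once
  per window (so plantings cannot destroy each other), and every
  insertion is recorded in both window-relative and genomic coordinates.
* **Expression statistics**: cutoff satisfaction by construction —
  foreground p-values drawn in (0, 0.0099), non-responsive in (0.9001, 1)
  with all counts strictly above the floor, "other" genes drawn from three
  violation modes (intermediate p-values; good p-values but low counts;
  single-timepoint response). Counts are log-normal around 500 with CV
  0.5, a plausible scale for normalized RNA-seq counts of expressed genes.
* **Peak tables**: 3+3 replicates, log-normal per-position baselines
  (median 1000, log-sd 0.5 — a typical fluorescence-unit scale),
  multiplicative replicate noise at CV 0.05 (capillary runs are
  precise), a per-sample loading scale (log-sd 0.25) that the
  normalization is designed to remove, and a protected interval where
  treatment heights are multiplied by `depletion_factor` (default 0.2;
  values > 1 model hypersensitivity).

What the generator does *not* emulate — promoter grammar, dinucleotide or
positional composition, transcript isoforms, read-level noise, peak-width
and sizing artifacts of real electropherograms — bounds what passing tests
show: they validate the statistics and bookkeeping of the pipeline, not
the biological discovery rate on real genomes, where background motif
frequency is not i.i.d. and expression statistics are not generated under
the cutoffs' own model.

# Determinism and numerical choices

All generators take explicit seeds, and one master seed derives fixed
per-stage streams, so a pipeline configuration reproduces byte-identical
output tables on rerun (checked by hashing in the test suite). Enrichment
output is sorted by ascending p_up with the canonical string as
tie-breaker. Hypergeometric tails are computed by `phyper` directly
(`phyper(x - 1, K, N - K, n, lower.tail = FALSE)`), never by summing
densities. Degenerate inputs have defined behavior: x = 0 gives p = 1;
k longer than a window gives an empty profile; a constant-height position
under a zero-variance comparison is "unchanged" with p = 1; trimming that
would empty the position set is an error.

Problem sizes in the test suite were chosen to make the statistical
checks sharp but quick: the planted-motif recovery property uses 100
seeded 1997-gene genomes (the full default design), the permutation null
check uses 100 label permutations on a 250-gene genome, footprint
calling is verified over 20 seeded peak tables, and the exhaustive
hypergeometric cross-check covers every (N ≤ 12, K, n, x).

# Known limitations

* The background model for enrichment is the all-gene universe only; no
  composition-matched or shuffled backgrounds are offered.
* Presence/absence scoring cannot distinguish one occurrence from many;
  dosage effects are invisible by design.
* TSS choice is annotation-driven (5′ gene end); no isoform-aware or
  experimentally refined TSS selection.
* The protection caller assumes log-normal replicate noise and ≥ 2
  replicates per condition; with exactly 3+3 its power comes mostly from
  the effect floor.
* Peak tables must already be position-assigned; mapping electropherogram
  peaks to promoter coordinates is upstream of this package.
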