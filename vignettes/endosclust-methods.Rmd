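---
title: "Methods: spatio-temporal transcriptome analysis of the maize endosperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal transcriptome analysis of the maize endosperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

endosclust analyses bulk RNA-Seq expression of the developing maize
endosperm across three cell types — the basal endosperm transfer layer
(BETL), the aleurone (AL) and the starchy endosperm (SE) — at 8, 12 and
16 days after pollination (DAP). The design is nine libraries (one per
tissue × stage combination, no replicates), summarised as an FPKM matrix
over transcripts. From that matrix plus an annotation, transcript
sequences, H3K27me3 peak intervals and catalogue lists, the package

1. identifies novel long noncoding RNAs (lncRNAs) by a five-stage filter
   chain,
2. calls spatially and temporally regulated transcripts by a 4-fold rule
   and partitions them into a Venn of spatial-only / temporal-only / both,
3. clusters the regulated transcripts with a self-organizing map (SOM) and
   labels each cluster's tissue/stage specificity,
4. tests clusters for GO-term and catalogue enrichment
   (hypergeometric + Benjamini–Hochberg),
5. associates regulated lncRNA loci with H3K27me3 peaks (interval overlap
   + chi-square), and
6. correlates each lncRNA with coding genes within 10 kb of its locus.

Every stage is exercised end to end on synthetic bundles with planted
structure, so the whole pipeline is testable without any external
download.

## Coordinate and data conventions

All genomic intervals inside the package are **0-based half-open**; GTF's
1-based closed coordinates are converted at the reading boundary
(`read_gtf()`), and BED files already use the internal convention.
Abutting intervals (`[100,200)`, `[200,300)`) do not overlap. Expression
tables are tibbles with a `transcript_id` column plus exactly the nine
sample columns `BETL08 … SE16`; FPKM values are read verbatim and never
re-normalized. Strand `"."` is permitted for novel transcripts because
assembler output is frequently unstranded, and all overlap operations are
strand-agnostic.

## The lncRNA filter chain

`run_lncrna_pipeline()` applies five stages in a fixed order to the novel
transcripts and audits the funnel (each stage's input, removals and
survivors; the audit telescopes by construction):

| stage | rule | default |
|---|---|---|
| expression | max FPKM over the 9 samples strictly > threshold | 0.1 FPKM |
| annotation overlap | ≥ 1 bp exonic overlap with any annotated coding transcript removes | 1 bp |
| length | spliced length must be ≥ threshold | 200 nt |
| coding potential | longest ORF ≥ threshold removes | 100 aa |
| blacklist | ≥ 50% exonic coverage by a blacklist interval, or an exact shared substring ≥ 50 nt with a blacklist sequence, removes | 0.5 / 50 nt |

Choices made where the procedure leaves room:

* **Expression** uses the maximum over samples: a transcript expressed
  anywhere in the design was genuinely sequenced, and a per-sample mean
  would penalize tissue-specific transcripts — the very objects of
  interest.
* **Annotation overlap** is exon-resolved: a novel transcript wholly
  contained in an intron of a coding gene is kept, since it is not a
  plausible splice variant of that gene.
* **ORF boundary**: "long ORF" is ambiguous exactly at 100 amino acids;
  the package removes at ≥ 100 aa and exposes the bound in
  `filter_thresholds()`. The ORF definition requires an in-frame stop
  (an open-ended reading frame does not count), scans all six frames, and
  treats any codon containing `N` as a plain residue that matches neither
  `ATG` nor a stop. The explicit ORF rule replaces an external
  coding-potential predictor so the filter is self-contained and exactly
  testable against a brute-force oracle.
* **Blacklist matching** (small-RNA precursors, transposable elements) is
  defined operationally — 50% interval coverage or a shared exact 50-mer —
  because alignment-tool settings for this step are conventionally
  unstated; both criteria are configurable and both are exercised by the
  synthetic bundles.

## 4-fold spatial and temporal regulation calls

For each transcript, tissue means are the averages of the three samples
per tissue computed on FPKM + ε (ε = 0.1 by default, preventing division
by zero at unexpressed transcripts), and stage means pool the three
tissues at each DAP. Tissue *t* is called **up** when

mean(t) ≥ fold × max(other tissue means),

and **down** when mean(t) ≤ min(other means) / fold, with fold = 4.
"Specific to a single cell type" is thus operationalized as
one-vs-max-of-rest; at most one tissue can be up and one down, which
matches the intended reading of tissue specificity. The boundary is
inclusive by default (`fold_params(inclusive = FALSE)` gives the strict
reading). Only transcripts whose maximum raw FPKM clears an expression
floor are eligible: 1.0 FPKM for coding transcripts, 0.1 for noncoding.
Temporal calls are the exact mirror over stages. The calls are invariant
to transcript order, to sample-column order, and to global rescaling of
the matrix when ε is scaled along (ratios only).

`venn_partition()` splits spatially ∪ temporally regulated transcripts
into `both`, `spatial_only` and `temporal_only`; `venn_counts()` does the
same arithmetic directly from set sizes (|both| = |S| + |T| − |S∪T|).
Percentages are rounded half away from zero.

## SOM co-expression clustering

Profiles are normalized per transcript to z-scores of
log10(FPKM + ε) across the nine samples (`normalize_profiles()`); rows
with zero variance map to the zero vector, so clustering sees shape, not
level. `train_som()` implements online Kohonen training: prototypes are
initialized by a seeded random sample of the data; at each step one
profile is drawn, its best-matching unit (BMU) found by Euclidean
distance (ties to the lowest unit index), and every prototype moved
toward the profile by α·exp(−d²/2σ²) with d the grid distance to the BMU.
α decays exponentially from 0.5 to 0.005 and σ from half the larger grid
dimension to 0.3 over the run. Training is repeated `n_restarts = 5`
times and the model with the lowest quantization error (mean distance to
the BMU) is kept — restarts-with-best-selection is the standard way to
stabilize an online SOM. Everything is deterministic given the seed, and
the caller's RNG state is left untouched.

Grid sizes are configuration: 3×7 = 21 units for coding transcripts and
2×7 = 14 for lncRNAs reproduce the study-scale cluster counts (the
published cluster counts are treated as grid sizes, the natural reading
for a SOM). The default iteration count (20,000) is sized for the
synthetic bundles shipped here; the study-scale 4,200,000 is a legal
configuration value and changes nothing but run time.

`label_specificity()` calls a cluster tissue-specific when one tissue's
prototype mean stands clear of both others by a margin (default 1 z-unit,
the same one-vs-rest logic as the 4-fold caller transposed to prototype
space), with the direction read off the sign of the deviation; stage
specificity is symmetric. Empty clusters are skipped.
`order_for_heatmap()` provides the display ordering: average-linkage
agglomerative clustering on 1 − Pearson r, rows pre-sorted by id so ties
break deterministically.

## Enrichment statistics

`hypergeom_upper(k, K, n, N)` is the upper tail P(X ≥ k) of the
hypergeometric distribution, evaluated through the distribution's
log-space tail so small p-values keep precision. `enrich_clusters()`
tests every (cluster, category) pair, adjusting by Benjamini–Hochberg
within each cluster (one BH family per cluster across its categories) and
flagging q < 0.05. The universe defaults in the pipeline to all
transcripts passing the relevant expression floor — a background of
detected transcripts, the common choice when the assay itself defines
detectability; it is a parameter because the alternative (all annotated
genes) is also defensible. Categories smaller than `k_min = 2` in the
universe are not tested.

`chi_square_2x2()` is Pearson's chi-square without continuity correction
(the margin closed form N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)), df = 1); a zero
margin is an error rather than a silent NaN. `catalog_representation()`
reports |catalog ∩ detected| as a percentage rounded half away from zero.

## Peak overlap and neighbour correlation

For chromatin questions a transcript's **locus** is its genomic span
(leftmost exon start to rightmost exon end) — a repressive domain over
the locus does not care about splicing — while the annotation filter
above is exon-resolved; the two resolutions answer different biological
questions. `overlap_loci()` counts a locus as overlapping when it shares
≥ 1 bp with any peak; `overlap_association()` builds the 2×2 table
(group × overlap) against a background group and applies the chi-square.
The pipeline's group is the spatio-temporally regulated lncRNA loci and
the background is every other transcript locus in the annotation.

`neighbour_pairs()` pairs each lncRNA with coding genes whose span lies
within 10 kb edge-to-edge on the same chromosome, inclusive at exactly
10 kb, with signed distance (positive downstream in genome coordinates,
0 when overlapping). The window is measured span-edge to span-edge
because anchoring at a TSS would require strand-reliable novel models,
which assemblers do not guarantee. `pair_correlation()` computes Pearson
r between the two normalized profiles and calls pairs positive at
r ≥ 0.8, negative at r ≤ −0.8 — operational thresholds for a
qualitative correlated/anticorrelated/neither distinction, configurable.
Flat profiles yield r = NA and call `none`.

## qPCR arithmetic

ChIP enrichment relative to input is
`input_dilution × efficiency^(Ct_input − Ct_ip)`; expression relative to
a reference transcript (thioredoxin in the assays this models) is
`efficiency^(Ct_ref − Ct_target)`. Efficiency defaults to perfect
doubling (2.0) since no per-primer calibration is modelled; technical
replicates are averaged on the Ct scale before transformation
(`mean_ct()`). `relative_to_reference()` maps the reference to exactly 1.

## The synthetic-data generator

`generate_bundle()` emulates the full study design with planted, fully
recorded structure; `simulation_config()` holds the knobs. The defaults
are the package's model of the study conditions, chosen once:

* **Expression model**: FPKM = baseline × pattern × 10^N(0, noise_sd).
  Lognormal noise keeps FPKM non-negative and matches the log10 scale on
  which profiles are analysed; noise_sd defaults to 0.3 log10 units, a
  realistic spread for bulk FPKM without replicates. One library per
  sample, as in the design — statistical power comes from effect size,
  not replication.
* **Planted patterns** (default 6): BETL-up, AL-up, SE-up, 8-DAP-up,
  12-DAP-up, and a BETL-at-8-DAP point pattern whose tissue and stage
  factors multiply, so it is called on both axes. fold_strength defaults
  to 8, comfortably above the 4-fold threshold, so planted calls are
  unambiguous at the noiseless limit. Two thirds of coding transcripts
  and 85% of true lncRNAs carry a pattern (the latter mirrors the
  spatio-temporal share reported for endosperm lncRNAs).
* **Novel-transcript classes**: 50% true lncRNAs plus four
  single-violation confounder classes (10% each: shorter than 200 nt,
  ORF ≥ 100 aa, blacklist match, exonic overlap with a coding gene) and a
  10% never-expressed remainder. Each confounder violates exactly one
  filter, so per-stage precision and recall are both testable and equal
  1 on a correct implementation.
* **Lengths**: lognormal(log 2000, 0.5) for coding (≈ 89% ≥ 1.1 kb) and
  lognormal(log 500, 0.5) for lncRNAs (≈ 5% ≥ 1.1 kb), reproducing the
  qualitative size contrast between the two classes.
* **Geometry**: transcripts occupy 50-kb slots across five chromosomes,
  so nothing overlaps or neighbours by accident; half the true lncRNAs
  are placed within 0.5–8 kb of a coding gene (half of those copying the
  gene's expression pattern), planting known neighbour pairs and known
  positive correlations. Blacklist elements exist both as intervals and
  as sequences so either matching mode is exercised.
* **Peaks**: H3K27me3 intervals are planted over regulated lncRNA loci
  with probability 0.8 and over any other locus with probability 0.1,
  giving the overlap-association test a known signal.

The truth table records, per transcript, its class, planted cluster,
intended spatial/temporal calls, peak status and neighbour. The same seed
yields a byte-identical bundle. What the generator deliberately does
**not** model: read-level artefacts, mapping bias, replicate structure,
correlated noise between neighbouring loci, and real TE sequence
families. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative model, not performance on real
maize data.

## Numerical choices and degenerate inputs

* BMU ties resolve to the lowest unit index; heatmap ordering pre-sorts
  by id; both make reruns bit-identical.
* The specificity margin comparison uses a 1e-9 slack so exactly-at-margin
  prototypes are inclusive under floating point.
* Zero-variance profiles normalize to the zero vector and are `none` /
  NA in correlation calls; empty SOM clusters are allowed and skipped in
  labelling; an empty novel set runs the filter chain to an all-zero
  audit; a zero margin in a 2×2 table and an empty locus group are
  errors, not warnings.
* Problem sizes in the shipped tests (bundles of 300–1,000 coding and
  80–200 novel transcripts, SOMs of 6 units, 20,000 iterations × 5
  restarts) were chosen so the full suite both exercises every stage and
  stays comfortably interactive.

## Known limitations

* No replicate-aware differential expression: with one library per
  condition, fold thresholds are the honest instrument; shrinkage or
  dispersion estimation would be theatre.
* Whether the original 4-fold comparison used means, maxima or
  within-tissue contrasts is not documented; one-vs-max-of-rest on group
  means is this package's documented convention, and results at other
  conventions can differ near the threshold.
* The GO universe question (all annotated vs all expressed) is a
  parameter, not a resolved fact.
* The SOM schedule of the original GenePattern module is not public;
  this package's schedule is a standard Kohonen formulation and will not
  reproduce the original cluster memberships transcript-for-transcript.
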