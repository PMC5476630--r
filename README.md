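# endosclust

Spatio-temporal transcriptome analysis of the developing maize endosperm.

The maize endosperm differentiates into functionally distinct cell types —
the basal endosperm transfer layer (**BETL**) at the maternal interface,
the **aleurone** (AL) at the surface, and the bulk storage **starchy
endosperm** (SE) — over a developmental window conventionally sampled at
8, 12 and 16 days after pollination (DAP). Profiling each tissue at each
stage gives a nine-library FPKM matrix in which both novel long noncoding
RNAs (lncRNAs) and spatio-temporally regulated coding transcripts can be
identified and clustered into co-expression modules. endosclust is a
tested, reusable implementation of that analysis for anyone working with
this (or any comparable tissue × stage) design.

## What it computes

Starting from an annotation (GTF), transcript sequences (FASTA), an FPKM
matrix (TSV), H3K27me3 peak intervals (BED) and catalogue lists:

* **lncRNA discovery** — a five-stage filter chain over novel
  transcripts: max FPKM > 0.1, no exonic overlap with annotated coding
  transcripts, spliced length ≥ 200 nt, longest ORF < 100 aa (ATG to
  in-frame stop, six frames), and no blacklist match (small-RNA
  precursors / transposable elements; ≥ 50% interval coverage or a shared
  exact ≥ 50-mer). Every stage is audited (n in, removed, out).
* **4-fold regulation calls** — tissue *t* is spatially up for a
  transcript when mean_t ≥ 4 × max(other tissue means) on
  pseudocount-shifted FPKM (down symmetric, stages analogous), with
  expression floors of 1.0 FPKM (coding) and 0.1 (noncoding); regulated
  transcripts are partitioned into spatial-only / temporal-only / both.
* **SOM clustering** — from-scratch online Kohonen training (Gaussian
  neighbourhood, exponential decay, 5 restarts, best by quantization
  error, fully seeded) over z-scored log10 profiles, with automatic
  tissue/stage specificity labels per cluster.
* **Enrichment** — upper-tail hypergeometric tests of GO terms and
  TF/MEG/PEG catalogues per cluster with Benjamini–Hochberg correction
  (q < 0.05), plus catalogue representation percentages.
* **Chromatin association** — interval overlap of regulated lncRNA loci
  with H3K27me3 peaks and a 2×2 chi-square association test.
* **Neighbour correlation** — Pearson correlation of each lncRNA with
  coding genes within 10 kb of its locus.
* **qPCR arithmetic** — percent-input ChIP enrichment and delta-Ct
  relative expression.

A synthetic-data generator (`generate_bundle()`) emulates the whole
design with planted clusters, planted lncRNAs, single-violation filter
confounders, peak associations and neighbour pairs — every downstream
stage is testable against recorded ground truth without any download.

## Worked example

```r
library(endosclust)

bundle <- generate_bundle(simulation_config(seed = 1,
                                            n_coding = 300, n_novel = 150))
report <- run_endosperm_pipeline(bundle,
                                 coding_som = som_config(2, 3, seed = 11),
                                 lnc_som = som_config(2, 3, seed = 12))
report
#> Spatio-temporal endosperm analysis
#> # A tibble: 9 × 2
#>   stage                n
#>   <chr>            <int>
#> 1 transcripts        450
#> 2 annotated_coding   300
#> 3 novel              150
#> 4 lncrna              75
#> 5 coding_spatial     103
#> 6 coding_temporal     79
#> 7 coding_regulated   165
#> 8 lncrna_regulated    51
#> 9 neighbour_pairs     30
```

Of 150 novel transcripts, the filter chain keeps 75 lncRNAs, removing 15
at each stage — exactly the planted confounder classes:

```r
dplyr::select(report$audit, -removed)
#> # A tibble: 5 × 4
#>   stage               n_in n_removed n_out
#>   <chr>              <int>     <int> <int>
#> 1 expression           150        15   135
#> 2 annotation_overlap   135        15   120
#> 3 length               120        15   105
#> 4 coding_potential     105        15    90
#> 5 blacklist             90        15    75
```

The regulated lncRNA loci carry planted H3K27me3 peaks at 80% versus 10%
background, and the chi-square confirms the association:

```r
report$overlap
#> # A tibble: 2 × 4
#>   group      n_loci n_overlapping fraction
#>   <chr>       <int>         <int>    <dbl>
#> 1 group          51            41    0.804
#> 2 background    399            51    0.128
#> chi-square = 127.1, df = 1, p = 1.78e-29
```

The SOM's six clusters recover the six planted patterns, and the
specificity labels read the planted tissue/stage structure directly off
the prototypes:

```r
head(report$labels_coding, 6)
#> # A tibble: 6 × 6
#>   cluster     n tissue tissue_direction dap   dap_direction
#>     <int> <int> <chr>  <chr>            <chr> <chr>
#> 1       1    27 BETL   up               <NA>  <NA>
#> 2       2    25 AL     up               <NA>  <NA>
#> 3       3    25 <NA>   <NA>             12    up
#> 4       4    32 BETL   up               8     up
#> 5       5    28 <NA>   <NA>             8     up
#> 6       6    28 SE     up               <NA>  <NA>
```

`autoplot(report$som_coding)` draws the prototype curves per cluster;
`tidy()` / `glance()` give the assignment table and a one-row model
summary. For study-scale grids use
`som_config(3, 7)` (21 coding clusters) and `som_config(2, 7)`
(14 lncRNA clusters).

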