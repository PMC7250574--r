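# regenatac

Integrative chromatin accessibility and regulatory circuit analysis for
regeneration time courses.

## The problem

During appendage regeneration, neural progenitor cells re-enter a
developmental program in which the chromatin landscape shifts stage by
stage: regions open transiently, the transcription factors (TFs) whose
motifs sit in those regions become active, and their targets — some of them
TFs themselves — carry the program into the next stage. `regenatac`
implements the computational arc of that study design for ATAC-seq of a
sorted progenitor population profiled at an uninjured baseline and several
hours-post-amputation (hpa) timepoints, together with matched bulk and
single-cell RNA-seq:

1. **Differential accessibility.** Peak fragment counts are modelled as
   negative binomial. After the one-CPM-in-(n−1)-samples filter and TMM
   normalization, a common dispersion φ is estimated by conditional maximum
   likelihood and each peak is tested with the exact conditional test:
   given the total *t* of two group sums that are NB with sizes *n·φ⁻¹*,
   the two-sided p-value sums the conditional probabilities of every split
   as or less probable than the observed one (a negative-hypergeometric
   law, free of the unknown mean). Benjamini–Hochberg FDR at α = 0.05 calls
   direction.
2. **Peak annotation.** Each peak is assigned the gene whose TSS is nearest
   to the peak midpoint, with distances signed by gene strand
   (upstream < 0), plus distance-to-TSS profiles and peak-set Venn
   partitions.
3. **Motif scanning.** Position weight matrices are scored as log₂ odds
   with a background-proportional pseudocount,
   `score[i,b] = log2((p[i,b] + 0.01·bg[b]) / (1.01·bg[b]))`, slid over
   both strands; the default detection threshold is 0.8 of each motif's
   maximum score.
4. **Term enrichment with semantic reduction.** Upper-tail hypergeometric
   tests over a propagated gene-to-term ontology, then SimRel redundancy
   reduction: with `IC(t) = −ln p(t)` and MICA the common ancestor of
   maximal IC, `simrel(a,b) = (2·IC(MICA)/(IC(a)+IC(b)))·(1 − p(MICA))`;
   terms are swept in ascending p and join the most similar representative
   unless all similarities are ≤ 0.4.
5. **Single-cell statistics.** Log-normalization (`ln(1 + 10⁴·x/libsize)`),
   cluster/phase composition tables, Wilcoxon rank-sum marker and DE tests
   (min.pct = 0.3, Bonferroni), and cell-cycle scoring: per-cell mean
   expression of an S or G2M signature minus that of expression-matched
   control genes, with G1 assigned when both scores are ≤ 0.
6. **Circuit chaining.** Per-stage regulator tables join accessible peaks,
   their motif content and nearest genes; rows are vetted by bulk
   expression (CPM ≥ 1 for TF and target); chains link stages where one
   edge's target encodes the next edge's TF, with the earliest timepoint
   contributing TF-activity evidence; circuits are finally filtered by
   single-cell differential expression between uninjured and 24hpa cells.

Because the study's deposited sequencing data are not required, the package
ships a seed-reproducible synthetic study generator
([`generate_dataset()`]) with a planted ground-truth ledger — planted
accessibility shifts, motif instances, markers, cell-cycle signatures, a
regulatory circuit, and 200 decoy genes that each violate exactly one
circuit criterion — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(regenatac)

cfg    <- synthetic_config(seed = 1)
ledger <- generate_dataset(cfg, "study")          # writes all input files
res    <- run_pipeline("study", out_dir = "study_results")

glance(res$da[["24hpa"]])
#> # A tibble: 1 × 9
#>   group1 group2 n_tested n_up_in_1 n_up_in_2 pct_up_in_1 pct_up_in_2 dispersion
#>   <chr>  <chr>     <int>     <int>     <int>       <dbl>       <dbl>      <dbl>
#> 1 6hpa   24hpa       600        84       157        34.9        65.1     0.0988
```

157 peaks gain accessibility from 6hpa to 24hpa (65.1% of the
differentially accessible peaks in that contrast), and the common NB
dispersion is estimated at 0.0988 — the generator's truth is 0.1.

```r
res$circuits
#> Circuit set: 3 circuit(s), 6 edge row(s)
#> # A tibble: 6 × 12
#>   circuit_id  step stage tf_name tf_gene target_gene peak     motif_id hit_score
#>        <int> <int> <chr> <chr>   <chr>   <chr>       <chr>    <chr>        <dbl>
#> 1          1     1 24hpa TF.g001 g001    g002        peak_01… M.g001        25.7
#> 2          1     2 72hpa TF.g002 g002    g013        peak_00… M.g002        25.7
#> ...
```

The three recovered circuits are exactly the planted chains: TF g001
(active from 6hpa) opens a 24hpa peak at the TF gene g002, and g002 in turn
sits on 72hpa peaks at its three targets — and nothing else survives the
decoys' single-criterion failures. The single-cell side reports per-phase
composition:

```r
res$composition_phase
#> # A tibble: 6 × 4
#>   timepoint phase     n fraction
#>   <chr>     <chr> <int>    <dbl>
#> 1 24hpa     G1      259    0.648
#> 2 24hpa     G2M      53    0.132
#> 3 24hpa     S        88    0.22
#> ...
```

`autoplot()` / `plot_*()` helpers draw the MDS embedding of samples, the
TSS distance profile, direction counts per contrast, and composition bars;
`tidy()`/`glance()` methods make every fitted object pipeline-friendly.

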