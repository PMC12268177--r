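# dhsdyn

Chromatin accessibility and expression dynamics in differentiating
cortical neurons — a tested R pipeline for DNase-seq / RNA-seq time
courses, validated end to end on synthetic data with a planted ground
truth.

## The problem

During corticogenesis, neural precursor cells (NPCs) of the ventricular
zone produce deep-layer excitatory neurons whose chromatin and
transcriptome reorganise within days: promoters of neuronal genes become
DNase-hypersensitive, bivalent (H3K4me3⁺ H3K27me3⁺) loci resolve, and
thousands of genes change expression. Analysing such a time course takes a
chain of small but error-prone computational steps — peak calling on cut
sites, replicate reconciliation, genomic-feature bookkeeping, time-course
testing, and overlap statistics — each of which this package implements as
a tested, reusable function.

For a four-stage design (E12 NPCs → E13/E14/E16 neurons, two replicates
per stage) the pipeline provides:

* **Peak calling** — Gaussian KDE of cut sites (`kde_profile`), an
  analytic uniform-background null with a skew-corrected far-tail quantile
  (`background_threshold`), peaks at *P* < 10⁻⁶ (`call_peaks`), and the
  both-replicate DHS rule (`reproducible_dhs`). For a track of *n* cuts on
  *L* bp the null height at a point has mean μ = *n/L* and variance
  σ² = *n/(L·2b√π)*; the default threshold adds a Cornish–Fisher
  third-cumulant correction to the normal quantile z(1−p).
* **Feature annotation** — strand-aware priority partition of the genome
  (promoter > exon > intron > downstream > distal, promoter = 1 kb
  up / 0.5 kb down of the TSS), DHS feature fractions, enhancer–gene
  overlap counts.
* **Chromatin-state dynamics** — per-gene stage patterns of promoter DHS
  presence (the 15 pattern gene sets of a 4-stage course), endpoint
  opening/closing calls, and bivalent-promoter classification from
  H3K4me3/H3K27me3 ChIP tracks.
* **Expression dynamics** — TMM-style normalisation to length-normalised
  expression values, a maSigPro-style polynomial time-course F-test
  (DEGs at FDR < 0.05), nine-profile k-means clustering, a two-group
  t-test and a twofold rule for single-replicate contrasts.
* **Set statistics** — Fisher's exact overlap tests and overlap matrices
  with joint BH correction, and preranked GSEA (weighted KS running sum,
  gene-permutation null).
* **Synthetic data** — `sim_config()` / `simulate_bundle()` generate a
  miniature genome with planted accessibility classes, histone marks,
  Dmrt binding and expression trajectories, so every claim above is
  checked against a known truth.

## Worked example

```r
library(dhsdyn)

cfg <- sim_config(n_chroms = 1, chrom_length = 2e6, n_genes = 200,
                  n_enhancers = 40, seed = 42)
bundle <- simulate_bundle(cfg)      # genome + tracks + counts + truth
res <- analyze_bundle(bundle)       # peaks -> DHSs -> patterns -> marks

round(res$metrics[c("opening_precision", "opening_recall",
                    "bivalent_precision", "bivalent_recall")], 3)
#>  opening_precision     opening_recall bivalent_precision    bivalent_recall
#>                  1                  1                  1                  1

lengths(res$pattern_sets)
#> 1111 1110 1100 1000 0111 0011 0001
#>   80   20   10   10   10   10   20

expr <- expression_values(bundle$counts)
deg <- timecourse_deg(expr, stage_times(bundle$counts$samples$stage))
sum(deg$is_deg)
#> [1] 86

opening <- res$dynamics$genes$gene_id[res$dynamics$genes$class == "opening"]
biv <- res$marks$gene_id[res$marks$category == "bivalent"]
tab <- overlap_table(biv, opening, bundle$truth$gene_id)
fisher_exact(tab["a"], tab["b"], tab["c"], tab["d"])
#> [1] 1.064327e-09
```

Every planted opening and bivalent gene is recovered exactly; the seven
observed stage patterns are the monotone ones the generator plants
(`1111` = open at all four stages, `0001` = open only at E16, ...); 86 of
200 genes are significant in the time-course test (the generator plants
120 non-flat trajectories, the weakest of which sit below the power of an
8-sample design); and the planted enrichment of bivalent promoters among
opening genes is detected at *P* ≈ 10⁻⁹.

The `analysis/` directory decomposes the same flow into numbered scripts
(`01_simulate.R` … `06_overlap_enrichment.R`) that write their tables
under `results/`.

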