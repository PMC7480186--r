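# transmeta

Cross-platform meta-analysis of differential gene expression, built around
the two-study design common in age-related macular degeneration (AMD)
transcriptomics: one microarray study and one RNA-seq study of the same
AMD-vs-control contrast in RPE/choroid tissue, analyzed separately and then
combined gene by gene.

## The statistical problem

Individual expression studies of AMD RPE/choroid are underpowered: at a
conventional FDR threshold each platform alone calls only a handful of
genes. Combining evidence across platforms is not a simple union, because
the platforms measure on different scales (fluorescence intensities vs
read counts), carry different noise models, and differ systematically as a
batch. `transmeta` implements the full chain needed to combine them
honestly:

1. **Harmonization** — map probes/transcripts to genes (max-mean collapse),
   intersect the two universes, and remove genes absent (zero or at the
   intensity floor) in more than a configurable fraction of pooled samples.
2. **Normalization** — generalized-log (`glog2`) transform plus quantile
   normalization for array intensities; log2 counts-per-million with a
   prior count for RNA-seq.
3. **Per-study inference** — two-group moderated t-statistics: per-gene
   variances are shrunk toward an empirical-Bayes prior `(d0, s0²)`
   estimated from all genes by closed-form moment matching on `log s²`.
4. **Batch diagnosis and adjustment** — parametric empirical-Bayes
   location/scale batch correction (ComBat-style) across the merged
   studies, protecting the case/control contrast, with PCA silhouette
   diagnostics before and after.
5. **Meta-analysis** — Fisher's method per gene, `|F_g| = −2 Σ ln p`,
   referred to χ²(4) for two studies; Benjamini–Hochberg step-up
   adjustment; a signed statistic (negative = up-regulated) and a
   consensus direction (the study with the smaller p wins disagreements).
6. **Interpretation** — hypergeometric over-representation analysis against
   GMT gene-set collections, and hub ranking (degree, exact betweenness,
   random-walk-with-restart scores) in zero- or first-order subnetworks of
   a protein–protein interaction reference.

A dual-platform synthetic-data generator with known differential-expression
truth supports calibration and power experiments at the sample sizes
typical of AMD RPE/choroid cohorts, and an end-to-end pipeline driver runs
the whole chain from TSV inputs to a reproducible output directory.

## Worked example

Simulate a paired microarray + RNA-seq experiment with 5% true DE genes,
run both per-study analyses, and combine them:

```r
library(transmeta)

cfg <- simulation_config(n_genes = 4000, group_sizes = c(20, 25, 15, 30),
                         seed = 7)
sim <- generate_dual_study(cfg)
sim$array
#> ExpressionStudy (microarray): 4000 genes x 45 samples
#>   groups: case=20, control=25

flt  <- filter_absent(sim$array, sim$rnaseq)
norm_array  <- vst_array(flt$a)
norm_rnaseq <- log_cpm(flt$b)

de_array  <- run_de(norm_array)
de_rnaseq <- run_de(norm_rnaseq)
attr(de_array, "prior")$d0     # estimated prior degrees of freedom
#> [1] 46.12791

meta <- meta_records(de_array, de_rnaseq)
sig  <- call_meta_genes(meta, alpha = 0.05)
head(sig[, c("gene", "F_g", "p_comb", "p_comb_adj", "effect")])
#>        gene       F_g       p_comb   p_comb_adj         effect
#> 836  G00846 -191.9490 2.020560e-40 8.001418e-37   Up-regulated
#> 2878 G02907 -181.7451 3.145885e-38 6.228852e-35   Up-regulated
#> 294  G00298  180.4855 5.865035e-38 7.741846e-35 Down-regulated
#> 248  G00252  173.3900 1.958048e-36 1.938468e-33 Down-regulated
#> 487  G00494  171.7384 4.429334e-36 3.508032e-33 Down-regulated
#> 3788 G03826 -155.5772 1.298079e-32 8.567318e-30   Up-regulated
```

The meta-gene set dominates either single-study set while staying mostly
inside the simulated truth:

```r
truth_de <- sim$truth$gene[sim$truth$is_de]
c(meta_called = nrow(sig), true_positives = sum(sig$gene %in% truth_de),
  array_only = sum(de_array$p_adj < 0.05),
  rnaseq_only = sum(de_rnaseq$p_adj < 0.05))
#>    meta_called true_positives     array_only    rnaseq_only
#>            195            183            172            180
```

Batch structure between the two platforms is visible in PCA and removed by
the empirical-Bayes adjustment:

```r
merged <- merge_studies(norm_array, norm_rnaseq)
before <- pca_report(merged$values, merged$samples$study)$silhouette
after  <- pca_report(combat_adjust(merged)$adjusted$values,
                     merged$samples$study)$silhouette
round(c(before = before, after = after), 3)
#> before  after
#>  0.961  0.131
```

## Published-table consistency

The package bundles the printed top-20 AMD RPE/choroid meta-gene tables
(macular and non-macular contrasts) as extdata. Because BH step-up values
are `m · p_raw / rank`, the unprinted effective test count `m` can be
recovered from the printed (rank, |F_g|, adjusted-p) triples alone — a
strong internal-consistency check of the Fisher + χ²(4) + BH arithmetic:

```r
mac <- published_meta_top20("macular")
fit <- infer_effective_tests(mac$F_abs, mac$p_printed)
c(m = fit$m, rows_matched = fit$n_matched)
#>            m rows_matched
#>        18125           20
```

All 20 printed macular rows (and the top non-macular rows, at the same
`m`) are reproduced to within one unit of their last printed digit.

## Pipeline driver and CLI

```r
cfg <- pipeline_config(
  array_expression  = "array_expression.tsv",
  rnaseq_expression = "rnaseq_counts.tsv",
  metadata          = "sample_metadata.tsv",
  gmt               = "gene_sets.gmt",      # optional
  edges             = "ppi_edges.tsv",      # optional
  outdir            = "transmeta_out", seed = 1)
run_pipeline(cfg)
```

This writes normalized matrices, per-study DE tables, the adjusted merged
matrix, PCA and Venn summaries, the full and significant meta-gene tables,
ORA results, ranked node statistics, a JSON manifest (with a configuration
hash for provenance) and a plain-text report. The same driver is exposed
as a command-line script:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "transmeta.R", package = "transmeta"))')" \
  run --config config.yaml
```

Subcommands: `simulate` (write a synthetic dataset), `run` (execute a YAML
configuration), `config --defaults` (print a template configuration).

## Vignette

See `vignettes/cross-platform-meta-analysis.Rmd` for the methods
derivation: the glog/quantile and log-CPM transforms, moment-matched
variance priors, the ComBat estimation equations, Fisher/BH arithmetic,
and the identifiability bound behind the batch-shift recovery experiment.
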