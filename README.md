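# ribotagr

Downstream analysis of **RiboTag / TRAP translatome immunoprecipitation (IP)
experiments in mixed-species co-cultures**, plus a generative simulator that
makes every stage of the analysis testable without external data.

## The problem

Cell-type-restricted expression of an epitope-tagged ribosomal protein
(RPL22-HA in one cell type, RPL22-V5 in the other) lets you pull down
ribosome-bound mRNA from one cell type out of a mixed culture. When the two
cell types come from different species (e.g. human neurons on mouse
astrocytes), every uniquely mapped read in a hybrid human+mouse reference is
attributable to one species, so cross-contamination of the IP can be measured
empirically. `ribotagr` implements that measurement:

- **Composition**: per-chromosome and per-species percent of uniquely mapped
  reads, from gene-level (featureCounts-style) or chromosome-level
  (samtools-idxstats-style) counts.
- **Depletion efficiency**: for each IP with matched co-culture input,
  regress the per-chromosome change in percent of library,
  Δ = %IP − %input, on the input percent over *off-target* chromosomes
  (the species not carrying the immunoprecipitated tag). Under uniform
  proportional retention of contaminating RNA the relation is linear, and

  efficiency = −slope of the OLS fit, with maximum 1

  attained when every off-target chromosome loses exactly its initial share
  (a chromosome at 5% of the input that is fully depleted changes by −5
  percentage points). Slope, intercept, R², and the two-sided t-test
  p-value of the slope are reported per IP and target class.
- **Gene-set enrichment**: genes ranked by log2 fold change of CPM (IP vs
  input); a permutation GSEA (weighted Kolmogorov–Smirnov running sum,
  random same-size gene sets as the null, BH adjustment) over Ensembl
  biotypes and over chromosomes of the protein-coding universe.
- **Reporter quantification**: Poisson inversion of digital-PCR partition
  counts (λ = −ln(1 − f), concentration = λ/volume, Clopper–Pearson
  interval), mCherry/GFP ratios, and between-IP fold differences.
- **Simulator**: a two-cell-type, two-species generative model — log-normal
  per-gene expression, biotype-dependent ribosome capture, zero capture of
  mitochondrial transcripts, uniform off-target retention *k*, multinomial
  read sampling — with a truth record carrying the analytic expectation of
  the depletion statistic, `D = 1 − k/Z`.

## Worked example

```r
library(ribotagr)

cfg <- sim_config(seed = 101, offtarget_retain = 0.2)   # 28% human / 72% mouse
sim <- simulate_experiment(cfg)

props <- chrom_proportions(sim$counts, sim$gene_table, "coculture_input")
species_composition(props, sim$gene_table)
#>   sample_id       species percent
#> 1 coculture_input   human   28.06
#> 2 coculture_input   mouse   71.94

depletion_report(sim$counts, sim$gene_table, sim$sample_sheet,
                 include_mito_off = FALSE, on_target_fit = FALSE)
#>   ip_sample  slope r_squared depletion_efficiency
#> 1     IP_HA -0.353     0.999                0.353
#> 2     IP_V5 -0.615     1.000                0.615
```

The fitted efficiencies match the simulator's analytic expectations (0.352
and 0.610 for this configuration) and the near-unity R² reflects the
linearity that uniform retention predicts. With the default
`include_mito_off = TRUE` the fully-depleted off-target mitochondrial
chromosome is also in the fit and pulls the efficiency up (0.601 / 0.795
here); see the vignette for when each choice is appropriate. Reporter read
counts tell the same story from one number per library:

```r
reporter_ratio_from_counts(sim$counts, "IP_HA")$ratio   # 0.512 (mCherry/GFP)
reporter_ratio_from_counts(sim$counts, "IP_V5")$ratio   # 12.49
# fold difference between the two IP fractions: 24.4
```

`run_pipeline(run_config(outdir = "run1", seed = 1))` executes all stages,
writes every table (TSV/JSON), figures, and a manifest with checksums.

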