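# mtlineage

Lineage tracing of B cell clones with single-cell mitochondrial DNA (mtDNA)
mutations.

Chronic lymphocytic leukemia (CLL) emerges from physiologic B cells through
monoclonal B cell lymphocytosis (MBL), and the central question about that
transition — new subclones, or proliferation of what is already there? — is a
question about lineage. Somatic mtDNA mutations act as endogenous cellular
barcodes: each cell carries many mtDNA copies, mutations arise ~10x faster
than in nuclear DNA, and single-cell chromatin assays that retain
mitochondrial fragments (mtscATAC-seq) read them out in thousands of cells at
once. The fraction of a cell's mtDNA copies carrying a mutation — its
**heteroplasmy** h = alt reads / total reads at the position — is heritable
but drifts by stochastic segregation, so heteroplasmy profiles resolve
clones, their dynamics between timepoints, and shared ancestry between cell
compartments.

`mtlineage` implements the full analysis chain as composable R functions:

| stage | functions |
|---|---|
| ground-truthed simulation | `sim_config()`, `simulate_population()`, `simulate_paired_timepoints()` |
| variant calling & filtering | `compute_heteroplasmy()`, `variant_statistics()`, `filter_variants()` |
| burden, recurrence, genotyping | `mutation_burden()`, `recurrence_table()`, `genotype_cells()` |
| clonotypes & stability | `call_clonotypes()`, `downsample_stability()`, `clone_dynamics()`, `subclone_summary()` |
| heteroplasmy shifts | `mean_shift_screen()`, `ks_shift_test()`, `shift_tests()`, `qq_curve()`, `compartment_enrichment()` |
| copy number from fragments | `make_bins()`, `bin_fragments()`, `cnv_deviation()` |
| trees, repertoires, concordance | `nj_tree()`, `repertoire_summary()`, `clone_concordance()` |
| pipeline & I/O | `run_pipeline()`, `read_base_counts()`, `write_het_matrix()`, ... |

High-confidence variants must be seen in **> 4 cells**, show a
variance-to-mean ratio of per-cell heteroplasmy **> 0.01** (genuine clonal
variants vary between cells), and have strand concordance **> 0.65** (the
Pearson correlation of plus- vs minus-strand alternate read counts;
sequencing artifacts concentrate on one strand), with blacklisted and
homoplasmic-appearing variants excluded. Shift detection combines a Wilcoxon
rank-sum screen on mean heteroplasmy (BH-corrected, flagged only beyond an
absolute 1.5-fold change) with a Kolmogorov–Smirnov screen on the full
per-cell distribution (gated at ≥ 100 cells per sample, BH q ≤ 0.05). Copy
number is inferred from fragment counts in overlapping 10 Mb bins (2 Mb
step) as a standardized deviation of the target population from a
copy-neutral reference. See `vignettes/mtdna-lineage-tracing.Rmd` for the
models, the parameter defaults and the reasoning behind every numerical
choice.

## Worked example

Simulate a paired-timepoint sample (4 clones, 500 cells per timepoint) with
one marker mutation whose founding heteroplasmy triples between timepoints,
then run the chain:

```r
library(mtlineage)

cfg <- sim_config(n_cells = 500, n_clones = 4, seed = 42, fragment_depth = 0,
                  injected_shifts = list(list(variant = 1, multiplier = 3)))
pair <- simulate_paired_timepoints(cfg)

stats <- variant_statistics(pair$A$tensor, pair$truth$variants$id)
calls <- filter_variants(stats)
calls
#> <mt_variant_stats> 18 variants (12 pass)
#>         id n_cells_detected      vmr strand_concordance  pass       fail_reasons
#> 1   174A>C               72 0.478737              0.930  TRUE
#> 2  1208G>A              110 0.329613              0.942  TRUE
#> ...
#> 4  2319T>C              415 0.044966              0.454 FALSE strand_concordance
#> 7  3611A>C              497 0.000179              0.956 FALSE    vmr,homoplasmic
```

All 12 planted clone markers pass; the strand-biased artifact fails the
concordance filter and the homoplasmic germline variants fail the VMR and
homoplasmy rules. Clonotyping recovers the planted clones and the polyclonal
background (label 0):

```r
het_a <- compute_heteroplasmy(pair$A$tensor, calls$id[calls$pass])
het_b <- compute_heteroplasmy(pair$B$tensor, calls$id[calls$pass])
clones <- call_clonotypes(het_a, seed = 42)
clones
#> <mt_clones> 500 cells in 4 clones (+96 background)
#>   0   1   2   3   4
#>  96 111 110 110  73
```

The shift screens flag exactly the injected variant — its mean heteroplasmy
rose from 0.078 to 0.18 (2.3-fold, above the 1.5-fold threshold) and its
full distribution moved (KS q = 2.4e-07):

```r
res <- shift_tests(het_a, het_b)
subset(as.data.frame(res), class != "stable")
#>       id mean_a mean_b fold_change wilcoxon_q    ks_q        class
#> 1 174A>C  0.078   0.18         2.3      0.019 2.4e-07 shifted_both
```

mtDNA clones align with the simulated B cell receptor clonotypes (every
clone maps onto one BCR lineage with purity 1; the background is a mix of
singleton clonotypes):

```r
clone_concordance(clones, pair$A$bcr)
#> <mt_concordance> 500 shared cells, ARI = 0.879
#>  mt_clone   n majority_bcr purity
#>         0  96    IGH.A0011 0.0104
#>         1 111  IGH.clone02 1.0000
#>         2 110  IGH.clone01 1.0000
#>         3 110  IGH.clone04 1.0000
#>         4  73  IGH.clone03 1.0000
```

`run_pipeline(out_dir, cfg)` chains every stage (including CNV inference
against a simulated copy-neutral reference when `fragment_depth > 0`), writes
all artifacts in standard text formats, and records an MD5 manifest;
re-running with the same config is byte-identical.

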