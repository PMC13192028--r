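---
title: "Tracing B cell clones with single-cell mtDNA mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing B cell clones with single-cell mtDNA mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlineage)
```

## The problem

Chronic lymphocytic leukemia (CLL) develops from physiologic B cells through
low- and high-count monoclonal B cell lymphocytosis (LC-/HC-MBL). Whether that
transition is driven by the outgrowth of new subclones or simply by
proliferation of an already-established clone is a question about *lineage*:
one needs a heritable, cell-intrinsic barcode that can be read out in
thousands of single cells alongside their phenotypes.

Mitochondrial DNA provides such a barcode. Each cell carries hundreds to
thousands of mtDNA copies, the mitochondrial mutation rate is roughly ten
times the nuclear one, and the 16.6 kb genome is small enough to be sequenced
deeply in single-cell chromatin assays that retain mitochondrial fragments.
A somatic mtDNA mutation is present in a *fraction* of a cell's genome copies
— its **heteroplasmy** — estimated per cell as alternate reads over total
reads at the position. Heteroplasmy profiles are heritable but drift by
stochastic segregation at each division, which makes them informative about
clonal structure at several scales: which cells belong to the same clone,
whether a clone's composition shifts between two timepoints, and whether two
cell compartments share an ancestor.

`mtlineage` implements that analysis chain end-to-end: variant calling from
per-cell per-strand base counts, heteroplasmy quantification, clonotype
assignment with stability quantification, mean- and distribution-level shift
testing between paired samples, compartment enrichment, sliding-window
copy-number inference from chromatin fragments, neighbor-joining clone trees,
and concordance between mtDNA clones and B cell receptor (BCR) clonotypes.
Because every stage is statistical, the package ships a ground-truthed
synthetic-data generator so each stage can be validated against known truth
without any sequencing data.

## The generative model behind the simulator

The generator mirrors the data-generating process the downstream statistics
assume:

* **Clonal structure.** `n_clones` expanded clones, each owning
  `markers_per_clone` private marker mutations with founding heteroplasmies
  drawn uniformly from `founding_heteroplasmy_range`; a `polyclonal_fraction`
  of cells forms a marker-free background. BCR clonotypes follow the clone
  for clonal cells and are unique singletons for background cells.
* **Segregation drift.** A cell of a clone with founding heteroplasmy $h$
  draws its latent heteroplasmy from $\mathrm{Beta}(hc, (1-h)c)$. The single
  concentration parameter $c$ (`dispersion_c`) stands in for the compounded
  binomial sampling of genome copies over the cell's divisional history; an
  explicit per-division genealogy would cost far more and the analysis only
  consumes the marginal per-cell dispersion. Large $c$ collapses the
  distribution onto $h$; $c \approx 1$ produces the U-shaped, near-fixed-or-
  lost patterns seen in old clones.
* **Counts.** Position coverage is negative binomial (`mean_depth`,
  size `depth_dispersion`), alternate reads binomial in the latent
  heteroplasmy, and alternate reads split across strands binomially — with
  probability 0.5 for genuine variants and `strand_bias_artifact` for
  artifact variants. This is what makes the strand-concordance filter
  testable *by construction*: genuine and artifactual variants differ only
  in the strand split.
* **Germline variants** are near-fixed ($h = 0.995$) in every cell; they
  carry no lineage information and must be removed by the homoplasmy rule.
* **Fragments and CNVs.** Nuclear fragments per copy-number segment are
  Poisson with rate proportional to segment length times copy/2, against a
  diploid baseline; planted events use copy 1 or 3.

Defaults are chosen to emulate a (pre)malignant mtscATAC-seq sample: 1,000
cells, 5 clones with 3 markers each, founding heteroplasmies in (0.1, 0.6)
(subclone-defining mutations sit well above the 1% detection floor but below
fixation), $c = 50$, mean depth 100x with negative-binomial size 2 — per-cell
mtDNA coverage in droplet assays is highly dispersed, and that dispersion is
what gives strand-concordance its discriminating power on count data — 20%
polyclonal background, and a 300 Mb three-contig genome for fragment
simulation (a full-size genome adds nothing statistically and would dominate
runtime).

What the simulator deliberately does **not** model: read-level errors and
alignment, chimeric reads, doublets, nuclear-mitochondrial segments (nuMTs),
per-position coverage unevenness (a hook exists via the depth draw but is
position-independent by default), and any transcriptional or epigenetic
signal. Passing tests therefore demonstrate that the statistics behave
correctly *given* counts with this structure — not that upstream alignment
or barcode handling is sound.

## Variant calling and filtering

A variant's per-cell heteroplasmy is $(alt^+ + alt^-)/(total^+ + total^-)$,
and is *missing* (not zero) below `min_coverage` (default 5 reads): absence
of evidence and evidence of absence propagate differently downstream. Three
statistics gate high-confidence variants, all strict inequalities:

* detected in **> 4 cells** (detection = covered and heteroplasmy ≥ 1%);
* **variance-to-mean ratio (VMR) > 0.01** of per-cell heteroplasmy —
  genuine clonal variants vary between cells, uniform low-level noise does
  not. VMR uses the n−1 sample variance on heteroplasmy fractions, the scale
  on which the 0.01 cutoff is meaningful;
* **strand concordance > 0.65** — Pearson correlation of per-cell plus- and
  minus-strand alternate read counts over detected cells. Undefined
  correlations (fewer than two detected cells, or a constant strand) fail
  conservatively.

Two exclusion rules complete the filter: an explicit blacklist (default the
recurrent artifact `310T>C`), and a general homoplasmy rule — variants whose
mean heteroplasmy is ≥ `homoplasmy_cutoff` (0.9) in *every* compartment look
germline and obscure subclones. The rule generalizes a cohort-specific
exclusion list; which criterion produced the original list is not stated, so
the cutoff is exposed. Whether per-cell "presence" should use a heteroplasmy
floor or a raw alt-read count is likewise unstated upstream; both knobs
(`detection_threshold`, `min_coverage`) are configurable. Filter statistics
are computed on cells pooled across a donor's longitudinal samples;
per-sample recomputation is a matter of calling `variant_statistics()` per
tensor.

## Clonotype assignment

`call_clonotypes()` square-root transforms heteroplasmy (variance
stabilization for fractions near 0), builds a k-nearest-neighbor graph
(k = 20) on cosine distance, and partitions it with seeded Louvain community
detection (resolution 1). Missing entries count as 0 for clustering but are
excluded from per-clone mean profiles, so coverage gaps cannot manufacture
pseudo-clones. Two post-processing steps matter in practice:

* **Profile merging.** Community detection on a kNN graph always finds
  communities, even in a homogeneous population. Clusters whose mean
  sqrt-heteroplasmy profiles have cosine similarity ≥ 0.9 are therefore
  merged iteratively — clones with disjoint markers are untouched (cosine
  ≈ 0) while noise-split halves of one clone (cosine ≈ 1) are rejoined.
  Without this step a single simulated clone fractures into several labels.
* **Background collapse.** Clusters whose profile reaches `min_marker_het`
  (0.02) on no variant carry no clonal signal and collapse to label 0.

The upstream ecosystem calls a packaged clustering function whose internals
are not described; this module is an explicit, seeded stand-in, and
cluster-level results — not any particular algorithm — are the target.
Stability is quantified by re-calling clonotypes on random subsets (75% and
50% retention, 25 replicates by default) and scoring the adjusted Rand index
against the full-data labels on retained cells; a sample is "stable" at a
fraction when the median ARI reaches 0.7. ARI, the median, and the 0.7
threshold are stand-ins for an unstated stability metric — ARI is the
standard chance-corrected partition agreement, and medians resist the
occasional degenerate replicate.

Between timepoints, clones are matched by greedy best-first cosine similarity
of profiles (deterministic label tie-break), and each matched clone's
frequency change is tested with a two-sided Fisher exact test on the
(clone, other) × (A, B) table, BH-corrected. "Dynamic" requires both q ≤ 0.05
and a frequency fold change ≥ 1.5 (mirroring the variant-level 1.5-fold
convention); clones under 10 cells in both samples are not testable. The
stable/dynamic criterion behind the published clone-stability counts is not
stated; this definition is this package's choice.

## Heteroplasmy shift testing

Two complementary screens compare a variant's per-cell heteroplasmies
between paired samples:

* **Mean screen** — two-sided Wilcoxon rank-sum, BH across all variants
  present in both samples, flagged only when the mean fold change is also
  ≥ 1.5 (or ≤ 1/1.5; a pseudocount of $10^{-4}$ on means keeps the ratio
  finite). Exact Wilcoxon p-values are used only for small untied samples;
  heteroplasmy vectors are heavily tied at 0, so the tie-corrected normal
  approximation is the workhorse.
* **Distribution screen** — two-sample Kolmogorov–Smirnov with asymptotic
  p-values (the exact ones are unavailable under ties anyway; whether the
  original analysis used exact or asymptotic p is unstated), BH across
  *gated* variants only. The cell-count gate ("≥ 100 cells in either
  sample") is ambiguous between *at least one* and *each*; the default
  requires **both** samples to have ≥ 100 non-missing cells, because a
  one-sided KS against a tiny sample is underpowered and unstable, and
  `gate = "any"` implements the literal reading. Keeping the two BH families
  separate (all-tested vs gated) matches the differing denominators the
  two screens naturally have.

"Integrated mean heteroplasmy" is read as the per-sample mean over cells
with non-missing values. Q-Q curves pair type-7 empirical quantiles on a
shared probability grid; a variant skewing toward higher or lower
heteroplasmy departs from the x = y line, and the maximum vertical deviation
summarizes the curve. Compartment enrichment applies the Wilcoxon + 1.5-fold
machinery to physiologic-vs-monoclonal compartments, labelling variants
enriched, depleted, or shared; underpowered variants (< 10 covered cells in
a compartment) are reported shared with a `powered = FALSE` flag.

## Copy-number inference from fragments

The genome is tiled with overlapping 10 Mb bins at a 2 Mb step. Each fragment
is assigned by its **midpoint** to every bin covering it — the upstream
description does not fix the assignment rule, and midpoint assignment avoids
double-length bias at bin edges while keeping each fragment's contribution
independent of its length. Terminal short bins are kept, flagged, and
length-normalized.

After scaling each cell to the cohort-median total depth, the deviation of a
target population from a copy-neutral reference (e.g. T cells) in bin $b$ is

$$ z_b = \frac{\bar x_{t,b} - \bar x_{r,b}}
            {s_{r,b}\sqrt{1/n_t + 1/n_r}} $$

with reference bins of zero variance masked. Two numerical choices deserve
justification, since the published deviation score is only sketched:

* the **two-sample standard error** — the reference mean is an estimate too;
  dividing by $s_r/\sqrt{n_t}$ alone inflates null z-scores by
  $\sqrt{1 + n_t/n_r}$ and produces spurious segments;
* **median centering** of the z vector — per-cell depth normalization couples
  a large planted event to every other bin (a gained contig depresses all
  other bins after total-depth scaling); subtracting the across-bin median z
  removes that global offset as long as altered bins are a minority.

Segments are maximal runs of ≥ 5 consecutive bins with $|z| \ge 3$ and
consistent sign. Note that overlapping bins are strongly autocorrelated
(adjacent bins share 8 of 10 Mb), so the run requirement suppresses isolated
noise but a run of 5 spans only ~18 Mb of genome; events near that scale are
at the resolution limit. Allele-specific inference and breakpoint refinement
below bin resolution are out of scope.

## Trees, repertoires, concordance

Clone trees use Saitou–Nei neighbor joining on Euclidean distances between
square-root mean heteroplasmy profiles (whether published trees were built
on cells or clones, and with what distance, is unstated — clone-level
profiles with the same sqrt stabilization used everywhere else is this
package's choice; per-cell trees subsample to ≤ 500 cells, seeded). Negative
branch estimates, possible on non-additive input, are clamped to zero with
the deficit donated to the sibling edge so total tree length is preserved.
On additive matrices neighbor joining is exact, which the tests verify
against randomly generated trees.

Repertoire summaries define the dominant clonotype as the largest heavy-chain
clonotype per sample and the polyclonal fraction as the proportion of cells
outside it; cells without a clonotype are excluded from denominators (their
handling upstream is unstated). mtDNA/BCR concordance cross-tabulates the two
partitions over shared cells and reports the adjusted Rand index and
per-clone majority purity, plus a long-format flow table for alluvial plots.

## Problem sizes and test design

The test-suite experiments run at sizes chosen so the full suite completes
in a few minutes while keeping every rate estimate meaningful: filter
performance over 100 simulations of 1,000 cells; FDR control over 20 paired
null simulations of 500 variants × 300 cells; KS power over 100 replicates
of a Beta(2,38) → Beta(6,34) shift at n = 300 per arm embedded in a
20-variant null family; clonotype recovery over 20 seeds; stability ordering
over a 20-sample cohort with segregation noise graded from c = 200 down to
c = 1; CNV recovery over 20 seeds of a whole-contig gain plus a 40 Mb
terminal loss at 500 target cells and 5,000 fragments per cell; neighbor
joining over 50 random additive matrices of 4–8 taxa. `scripts/acceptance.R`
recomputes the same quantities from scratch at slightly reduced replicate
counts and writes them as JSON.

## Known limitations

* Clonotype labels depend on a seeded community detection; different seeds
  can relabel or occasionally re-cut borderline cells, which is why
  stability under downsampling is part of the standard output rather than
  an afterthought.
* The shift screens assume exchangeable cells within a sample; batch or
  covariate structure within a timepoint is not modeled (no mixed-effects
  heteroplasmy models, no >2-sample trajectories).
* CNV calls are population-level (pseudobulk); per-cell z-scores are emitted
  for inspection but single-cell CNV genotyping is out of scope.
* The simulator's BCR truth ties one clonotype to each mtDNA clone; in real
  malignancies all subclones of one tumor share the BCR, so
  BCR-vs-mtDNA concordance on simulated data is an upper bound on what a
  real sample would show at subclone resolution, and the polyclonal-fraction
  estimator is consistent when the monoclonal population is one BCR lineage
  (`n_clones = 1`).
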