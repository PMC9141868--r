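---
title: "Methods: predictive binding positions and cluster conservation in receptor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predictive binding positions and cluster conservation in receptor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfam)
```

## The problem

Insect odorant receptors (ORs) form one of the largest and fastest-evolving
protein families: thousands of paralogues across species, with ligands known
for only a handful. orfam implements a transfer-of-function strategy for such
families: learn which alignment positions predict chemical response from the
few functionally characterized members, then study how those positions evolve
across the orthologous clusters of the whole family — in particular whether
lineage-specific expansions (for example in social insects) keep their binding
sites conserved ("finely tuned" receptors recognizing similar odorants) or
diversify them (broadly tuned radiations).

The pipeline consumes four inputs: a master multiple sequence alignment
(columns are the shared coordinate system, numbered 1-based), a
sequence-to-cluster table from an orthology inference, a nested species
taxonomy with sociality flags, and one or more protein-by-chemical response
panels. Everything downstream is tabular and tidyverse-shaped: functions take
tibbles and return tibbles.

## Models and procedures

### Response binarization

Electrophysiology panels report continuous responses in heterogeneous units.
Within each (dataset, chemical), values strictly greater than the 75th
percentile of that chemical's tested values become responders (1), other
tested values non-responders (0); untested cells stay missing. Binarization is
never pooled across datasets, so units cannot leak between panels. The
percentile uses linear interpolation between order statistics
(`stats::quantile()` type 7); a nearest-rank alternative is available via
`method = "nearest"` because the estimator choice is a convention, not part of
the model. Ties at the threshold are non-responders by the strict inequality.
Training chemicals are those with more than `min_values = 100` tested values
over the union of datasets.

### Importance models

The alignment becomes a design table: one row per protein, one column per
alignment position, each cell a residue character, with the gap `"-"` as a
first-class category (indel presence can be predictive) and `"X"` treated as
missing. Near-zero-variance positions are filtered within each training
subset with the conventional 95/5 rule (`freq_cut = 19`, `unique_cut = 10`,
via `caret::nearZeroVar()`).

For each (dataset, chemical) pair, residues are one-hot encoded so that
importances exist per (position, residue) feature, and a random forest
(`n_trees = 500`) is fitted with `caret::train()`; `mtry` is chosen from the
grid {20, 50, 100} by repeated stratified cross-validation (10 folds, 10
repeats by default). Two numerical choices deserve note:

* **Minimum indicator support.** A residue observed in fewer than
  `min_support = 5` training sequences (or absent from fewer than 5) gets no
  indicator column. A singleton indicator cannot support a split that
  generalizes beyond its one carrier; empirically such columns inject a long
  tail of spurious impurity importance that drowns genuine binding-site
  signal at realistic training sizes (tens of labeled proteins against
  hundreds of candidate features). The floor is capped at a quarter of the
  training rows so small tables are never emptied.
* **AUC direction.** The per-resample AUC is computed with a fixed direction
  (responders score higher); the "best class" convention
  `max(AUC, 1 - AUC)` is applied once to the resample mean, not per fold.
  Applying it per fold would bias small-fold AUCs upward and make the
  null-model AUC uninterpretable.

Feature importances are the final forest's mean decrease in impurity,
min-max scaled to [0, 100] per model (so every model's strongest feature
scores 100). Cross-validated sensitivity, precision and F1 of the hard
predictions are reported alongside; with the 1:3 class imbalance produced by
quartile labeling, forests often predict no positives at small n, so AUC is
the primary metric and the selection gate below uses it. No class
reweighting is applied by default.

### Predictive positions

A (position, residue, chemical) feature is *kept* when its scaled importance
exceeds 10 and its model's best-class AUC exceeds 0.7 (both strict). The
`times_predictive` count of a position within a dataset is the number of kept
(residue, chemical) features at that position — the same position counts once
per predictive residue per chemical, which is why counts can exceed the
number of chemicals. Rankings sort by `times_predictive`, breaking ties by
the maximum importance at the position and then by ascending position index
(deterministic; the tie rule is a package choice). The predictive position
set for conservation analysis is the union of each dataset's top
`k = 10` positions.

### Conservation

Within a cluster, a column's conservation is the frequency of its modal
residue among the cluster's members. Gaps and `"X"` are not residues: by
default they are excluded from both the modal count and the denominator, and
columns where no member has a residue receive no score (and do not enter any
mean). A `gap_as_state = TRUE` switch treats the gap as a 21st state, since
the convention is not universal. Background conservation `c_bg` is the mean
score over all scored columns — a per-column mean across the cluster, which
keeps it commensurable with the predictive mean `c_pred` over the predictive
position set. The ratio `R = c_pred / c_bg` is the quantity of interest:
above 1, a binding site more conserved than the rest of the protein. Only
clusters with at least `min_size = 5` members are scored.

### Cluster evolution

Taxon enrichment is `log2(n_seqs / n_species)` per (cluster, taxon); a taxon
with no sequences in a cluster is reported absent (`NA`), never `-Inf`.
Clusters are annotated with expansion (members per represented species) and
social fraction (members from social-flagged species). Median-split tests
compare `R` between clusters strictly above the median of a criterion
(social fraction, expansion, or both jointly) and the rest, with a two-sided
Wilcoxon rank-sum test (`stats::wilcox.test`: exact for small tie-free
groups, normal approximation with continuity correction otherwise).
"Strictly above" sends clusters at the median to the low group. The
species-specific comparison contrasts `R` between clusters *specifically
expanded* in two focal species; a cluster is specifically expanded in a
species when all of its members (fraction threshold 1.0, configurable) come
from that species and it meets the minimum size.

### Structure mapping

Alignment columns map to a reference (linking) sequence by counting its
non-gap characters, and onward to a template sequence — e.g. the one family
member with a solved structure — by global pairwise alignment
(`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10 / extend 0.5, all
configurable and recorded in the result). Mappings are partial and strictly
monotone; unmapped coordinates print as `"-"`. A numbering offset
accommodates structures whose residue numbering does not start at 1. No
structure files are parsed: the template enters as a sequence plus offset.

## The synthetic generator

`simulate_family()` generates the statistical structure the analysis assumes,
so the whole pipeline is testable without downloads. Per cluster a consensus
is drawn from the background residue frequencies; each member copies the
consensus at each column with probability `theta_bind` (planted binding
columns) or `theta_bg` (elsewhere), otherwise draws from the background; gaps
are inserted i.i.d. per cell (`gap_rate = 0.05`). Gene counts per
(species, cluster) are zero-inflated geometric (`p_absent`, `mean_genes`),
giving the skewed cluster-size spectrum real OR families show. The taxonomy
is a two-clade tree (social clade, solitary clade) with per-species leaves.

`simulate_responses()` links sequence to function: each chemical engages
`n_active = 2` of the planted positions; a protein's response is `beta` per
engaged position carrying a *responsive* residue, plus Gaussian noise
`sigma`. The responsive set at a column is the frequency-ranked subset of
observed residues whose cumulative frequency is closest to
`responsive_target = 0.25`. That target mirrors the upper-quartile labeling
rule: the planted effect then splits the family near the binarization
threshold, which is what makes a position *learnable* — a responsive set
carried by nearly everyone (or no one) produces labels dominated by noise no
matter how large `beta` is. Letting chemicals engage different position
subsets emulates different odorants contacting different pocket residues and
is what makes the `times_predictive` aggregation concentrate on planted
positions.

Default scale: 12 species (6 social), 20 clusters, 100 columns, uniform
background frequencies, `theta_bg = 0.5`, `theta_bind = 0.85`, 5 planted
columns, 8 chemicals, `beta/sigma = 1/0.3`, 20% untested cells. These are
moderate sizes a desk benchmark can afford while keeping the qualitative
features — clustered conservation, skewed cluster sizes, quartile-imbalanced
labels, planted signal-to-noise about 3.

What the generator does **not** emulate: phylogenetic correlation along a
gene tree (members are conditionally independent given the consensus), indel
evolution (gaps are i.i.d. noise, not ancestral events), heterogeneous
per-column substitution processes, and the shared ancestry between
responders that real panels show. Consequently, passing the synthetic
benchmarks demonstrates that the machinery recovers planted residue-level
signal under the stated noise model — not that real OR panels contain such
signal, nor that phylogenetic confounding (paralogues sharing both response
and many unrelated residues) is controlled. On real data the models'
importance may partly reflect relatedness; the published analyses this
package reimplements share that caveat.

## Benchmark problem sizes

The packaged checks use these scales, chosen to exercise every code path at
desk scale:

* **Planted-position recovery**: one cluster of about 120 proteins over 10
  species, 80 columns, 5 planted positions, `theta_bind = 0.35` (moderate
  conservation, so planted columns segregate), 70 labeled proteins, 8
  chemicals, `beta/sigma = 3.3`, forests of 500 trees with the full mtry
  grid and 3-fold cross-validation, 10 generator seeds. The single-cluster
  design isolates residue-level signal: with strong cluster structure in the
  labeled set, any cluster-discriminating column predicts a cluster-level
  response equally well, and position recovery is no longer identifiable —
  a genuine property of the method, not of the implementation.
* **Conservation-ratio recovery**: two groups of 25 clusters generated with
  `theta_bind` of 0.85 versus 0.25 against `theta_bg = 0.5`, scored on the
  planted positions.
* **Null calibration**: permuted labels, same training conditions, 10 seeds.

## End-to-end use

```r
cfg <- pipeline_config(
  out_dir = "run1", seed = 1,
  sim = sim_config(seed = 1),
  min_values = 50,
  model = model_spec(cv_folds = 5, cv_repeats = 2)
)
manifest <- run_pipeline(cfg)
```

writes every stage artifact (family, binarized panels, model metrics,
importances, kept features, rankings, conservation, enrichment, annotations,
split tests) as TSV plus a `manifest.json` with the seed, thresholds and an
MD5 checksum per artifact; the same configuration reproduces identical
checksums. `run_pipeline(cfg, stages = c("conserve", "evolve"))` recomputes
only those stages from the artifacts already on disk.

## Known limitations

* The importance measure is impurity-based and inherits its bias towards
  features with more balanced splits; permutation importance is not yet
  wired through `caret` in this package.
* Class imbalance from quartile labeling is left unweighted, matching the
  published setup; sensitivity at small n is accordingly low.
* Curation is declarative only (flag files); the package never detects
  pseudogenes or fragments itself.
* The real OR alignment, clusters and response panels are not shipped (they
  are a multi-megabyte download); functions that reproduce the published
  cluster statistics run on them unchanged when the files are provided.
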