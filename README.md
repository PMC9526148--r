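# isletXmap

Cross-species analysis of pancreatic islet single-cell RNA-seq data.

Pancreatic islet cells — insulin-secreting β-cells, glucagon-secreting
α-cells, δ- and PP-cells — are studied mostly in mouse and, increasingly,
pig models, yet it is unclear how much of the human endocrine expression
program those models actually share. `isletXmap` implements a pipeline for
answering that question quantitatively from per-species cell×gene count
matrices with cell-type (and optionally cell-state) labels:

* **Preprocessing** — QC filtering, total-count normalization that excludes
  highly expressed genes (> 5% of a cell's counts) from the size factor,
  `log(1+x)` transform, and ComBat empirical-Bayes batch adjustment with
  zeros pinned to zero.
* **Ortholog mapping** — resolution of one-to-many ortholog records by
  keeping, per ambiguity group, the partner with maximal mean expression in
  its own species; renaming of matrices into a shared gene namespace; the
  fraction of per-gene expression variance the mappable subset retains.
* **Markers & conservation** — enriched markers per cell type
  (expressed in ≥ 5% of the type's cells, log₂ fold change > 0.5 against the
  cell-count-weighted rest), classified in each other species as
  *conserved* (enriched in the same cell type), *switch* (enriched in a
  different type), *loss* (expressed but not enriched), *absent*
  (undetected), or *gain* (expressed in the target but not the reference);
  per-cell-type Venn overlap counts across species.
* **Pattern correlation** — Pearson correlation of expression patterns
  across cell types using the harmonic average
  `h = 2·m·f′/(m + f′)` of mean expression `m` and the group-mean-normalized
  expressing fraction `f′`, so both magnitude and penetrance inform the
  comparison; plus PCA-space cell-type correlation after dropping the top
  two (species-driven) variance components.
* **Gene sets** — de-novo gene modules from Ward clustering of the
  gene–gene correlation matrix of the top variable genes (sets with mean
  intra-set correlation < 0.005 are discarded); per-cell activation scores
  against expression-bin-matched background genes; Welch-t signature
  ranking.
* **Reference projection** — a reference state map in gene-set score space
  (z-scaling + PCA fitted on reference cells) onto which query cells of any
  species are projected; labels transfer by majority vote among the k = 15
  nearest reference cells.
* **Synthetic panels** — a negative-binomial multi-species generator with
  planted markers, conservation categories, correlated gene modules,
  states, batch shifts and dropout, so every stage can be validated against
  known ground truth.

## Worked example

```r
library(isletXmap)

cfg <- simConfig(species = c("human", "pig"),
                 cell_types = c(alpha = 300, beta = 300,
                                delta = 300, pp = 300),
                 n_genes = 1500, n_markers = 30, marker_log2fc = 2,
                 seed = 1)
sim <- simulatePanel(cfg)
sim$matrices$human
#> CellExperiment: 1500 genes x 1200 cells
#>   species: human
#>   cell types: alpha, beta, delta, pp
#>   assays: counts

norm <- lapply(sim$matrices, normalizeLog)
tab  <- resolveOrthologs(sim$ortholog, norm)
tab
#> OrthologTable: 1500 records across human/pig (resolved)
mapped <- lapply(names(norm), function(sp)
    applyMapping(norm[[sp]], tab, species = sp))
names(mapped) <- names(norm)
explainedVarianceFraction(norm$human, geneIds(mapped$human))
#> [1] 0.998

prof <- lapply(mapped, computeGroupProfile)
mk   <- lapply(prof, findEnrichedMarkers)
table(subset(mk$human, is_enriched)$cell_type)
#> alpha  beta delta    pp
#>    44    43    45    47

calls <- classifyMarkerConservation(mk$human, mk$pig, prof$pig)
round(prop.table(table(calls$category)), 2)
#>    absent conserved      loss    switch
#>      0.11      0.34      0.32      0.23

patternCorrelation(harmonicProfile(prof$human),
                   harmonicProfile(prof$pig))
#> [1] 0.947
```

The simulated panel plants 30 enriched markers per cell type; the marker
table recovers them (plus a small tail of borderline noise genes near the
thresholds, visible as 43–47 calls per type). The conservation table
classifies every human marker in pig; the proportions reflect the planted
category mixture, diluted by the noise calls, which mostly land in `loss`.
The harmonic-profile correlation of 0.95 summarizes how similar the two
species' cell-type expression patterns are over the mapped gene space.

The same stages run end-to-end from a JSON configuration:

```r
runPipeline(defaultPipelineConfig(seed = 1, out_dir = "run1"))
```

or from the shell via `Rscript inst/scripts/isletxmap.R --config cfg.json
--seed 1 --out run1`.

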