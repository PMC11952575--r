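# linkseg

Cell segmentation for imaging-based spatial transcriptomics (Xenium, CosMx,
MERFISH, ...) by **transcript-to-cell link prediction** on a heterogeneous
graph.

## The problem

Platforms that detect single transcript molecules in situ deliver points
with subcellular coordinates plus nucleus (DAPI) or membrane staining. The
bottleneck for all downstream analysis is deciding which molecule belongs to
which cell: nucleus-only assignment discards the cytoplasmic majority of the
signal, while boundary expansion contaminates cells with their neighbours'
transcripts — and some cells have no detectable nucleus at all.

`linkseg` is for analysts of such data who want transcript-level assignments
with controllable precision/recall behaviour, plus the evaluation metrics to
audit them.

## The method

The data become a heterogeneous graph with two node types:

* transcripts \(t\), with a gene embedding as features (scRNA-seq-informed
  PCA of `log1p` type profiles, or a learned table);
* cells \(c\), with boundary geometry features (area, perimeter, circularity
  \(4\pi A/P^2\), elongation, convexity, log counts).

Edges are spatial transcript-transcript kNN links and candidate
transcript-cell links to nearby nuclei. Training labels come from the
staining itself: a transcript inside nucleus \(c\) gives a positive edge
\((t, c)\) and negative edges to the other nuclei near \(t\). A multi-head
attention GNN (with a learned distance bias on attention logits)
message-passes over both edge types and is trained with binary cross-entropy
so that the joint latent space scores each candidate link:

$$P(t \in c) = \sigma(z_t^\top z_c)$$

Each transcript then takes its argmax-scoring cell above a threshold
(default 0.5); unassigned transcripts are grouped into *fragments* —
connected components under a spatial gate and a latent-similarity gate —
reported as entities distinct from cells. Adaptive tiling with
receptive-field margins makes slide-scale segmentation exact: a 1-tile and a
4-tile run produce identical assignments.

Evaluation ships with the package: **PMP** (positive marker purity, a
true-positive proxy from cell-type markers), **MECR** (mutually exclusive
co-expression rate over gene pairs with <1% reference codetection, a
contamination proxy), summary statistics after a minimum-counts filter
(default 5), and precision/recall/F1 against the bundled simulator's ground
truth. A fully seeded synthetic-tissue generator (Voronoi territories,
interior nuclei, type-exclusive markers, diffusion noise, nucleus-free
cells) makes every stage testable offline.

## Worked example

```r
library(linkseg)

# 1. simulate a ground-truthed tissue patch (100 cells, 150x150 um)
sim <- simulate_tissue(tissue_params(seed = 42))
nrow(sim$transcripts)
#> [1] 5077

# 2. reference-informed gene embedding (capped by the 4 reference types)
emb <- reference_embedding(sim$reference, d = 4)
cfg <- linkseg_config(list(embedding = list(d = 4), model = list(seed = 42)))

# 3. build the heterogeneous graph and train the link-prediction model
graph <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
model <- train_model(list(graph), cfg, emb)
model$val_auroc
#> [1] 0.9994934

# 4. segment and inspect the run report
res <- segment_dataset(sim$transcripts, sim$nuclei, model, cfg)
str(attr(res, "report"))
#> List of 8
#>  $ n_transcripts      : int 5077
#>  $ n_assigned         : int 4425
#>  $ n_fragment         : int 532
#>  $ n_unassigned       : int 120
#>  $ n_cells            : int 89
#>  $ n_fragments        : int 16
#>  $ median_per_cell    : num 48
#>  $ median_per_fragment: num 12.5

# 5. evaluate against the simulator's ground truth
mr <- metrics_report(res, sim$transcripts, ref = sim$reference,
                     cell_type = sim$truth$type, truth = sim$truth)
round(unlist(mr[c("n_cells", "median_counts_per_cell", "mean_pmp",
                  "mean_mecr", "precision", "recall", "f1")]), 3)
#>                n_cells median_counts_per_cell               mean_pmp
#>                 89.000                 48.000                  0.951
#>              mean_mecr              precision                 recall
#>                  0.068                  0.895                  0.780
#>                     f1
#>                  0.834
```

Reading the numbers: held-out link AUROC of 0.999 says nucleus-overlap
labels are recovered almost perfectly; 87% of transcripts get a cell, 10%
form fragments (mostly over nucleus-free cells — fragments are smaller than
cells, median 12.5 vs 48 transcripts), and the mean marker purity of 0.95
with MECR 0.07 quantifies how little cross-cell contamination the assignments
carry under 5% diffusion noise.

Persist results with `write_segmentation()` (CSV),
`write_cell_matrix()` (MatrixMarket cell×gene counts, cells under 5 counts
dropped), and `write_model()` (JSON archive). Real data loads through
`read_transcripts()` / `read_boundaries()` / `read_reference()`, which
accept generic or Xenium column names (`x_location`, `feature_name`, `qv`,
...), CSV or parquet, vertex-list or GeoJSON boundaries.

A thin command-line front end with `simulate`, `validate-inputs`, `embed`,
`train`, `segment` and `benchmark` subcommands is installed at
`inst/cli/linkseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/linkseg.R", package="linkseg"))')" \
    simulate --out-dir demo --seed 1
```

## Documentation

Every exported function carries roxygen documentation; the methods vignette
(`vignettes/linkseg-methods.Rmd`) explains the model, its assumptions, the
defaults and their rationale, what the simulator does and does not emulate,
and known limitations.
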