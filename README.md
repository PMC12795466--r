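# dagformer

Single-cell cancer drug-response prediction by graph-based unsupervised
domain adaptation: `dagformer` transfers drug sensitivity labels from bulk
RNA-seq cell-line panels (e.g. GDSC-style data, where response labels
exist) to unlabeled single-cell RNA-seq profiles (where they do not).

## The method

Each domain is a network 𝒩 = (G, X, Y): a cellular neighbor graph *G*
over samples (Spearman- or Pearson-thresholded, or cosine-KNN with K = 15,
symmetrized and normalized as D<sup>−1/2</sup>AD<sup>−1/2</sup>), a
z-scored expression matrix *X* over the genes shared by both domains, and —
in the source only — binary labels *Y* (1 = sensitive, 0 = resistant).

Both domains are encoded twice by graph transformers whose multi-head
attention is sparsified by the graph (per head,
attn<sub>ij</sub> = Ĝ<sub>ij</sub>·(Q<sub>i</sub>·K<sub>j</sub>) with the
softmax over each node's neighbor set): a **private** encoder per domain
captures modality-specific structure, while one weight-tied **shared**
encoder captures domain-invariant signal. Five losses shape the
representation:

* **L**<sub>cls</sub> — cross-entropy of the predictor ψ on labeled source samples;
* **L**<sub>dom</sub> — a domain discriminator trained through a gradient
  reversal layer, so minimizing one objective plays the adversarial
  min–max that renders shared features domain-invariant (weight λ<sub>d</sub> = 0.5);
* **L**<sub>ent</sub> — Bernoulli entropy of target predictions, ramped in
  linearly, sharpening the unlabeled decision boundary;
* **L**<sub>diff</sub> — ‖H<sub>sh</sub>ᵀH<sub>pr</sub>‖²<sub>F</sub> per
  domain, keeping shared and private subspaces orthogonal (λ<sub>f</sub> = 10⁻⁴);
* **L**<sub>rec</sub> — inner-product decoders reconstruct each binary
  adjacency from [H<sub>pr</sub>, H<sub>sh</sub>] (λ<sub>r</sub> = 0.3).

Training is full-batch Adam on the weighted sum; all forward/backward
passes are written in the package (edge-sparse C++ attention kernels,
gradients verified against finite differences in the test suite). Because
the published benchmark inputs are external downloads, the package ships a
two-domain synthetic generator reproducing the method's premises — shared
class signal, bulk-like smoothing in the source, a detectable domain shift
in the target — so everything runs self-contained; see the methods
vignette (`vignettes/dagformer-methods.Rmd`).

## Worked example

```r
library(dagformer)

ds  <- generate_synthetic(synth_preset("separable", seed = 1))
src <- standardize_source(ds$source$x)
tgt <- standardize_source(ds$target$x)

bal <- balance_classes(src, ds$source$y, balance_params(seed = 1))
table(bal$y)
#>  0  1
#> 75 75

gs <- build_cell_graph(bal$x, "knn", k = 15)
gt <- build_cell_graph(tgt,   "knn", k = 15)
gs
#> <cell_graph> 150 nodes, 1462 undirected edges [method=knn, normalized=TRUE]

fit <- train_dagformer(list(x = bal$x, y = bal$y, graph = gs),
                       list(x = tgt, graph = gt))
fit
#> <dagformer_fit> 300 epochs; final total loss 1.1961 (cls 0.0727, disc acc 0.727)

pred <- predict_dagformer(fit, list(x = tgt, graph = gt), y_true = ds$truth)
pred
#> <prediction_result> 300 cells, 137 called sensitive
#>   ACC 0.990  AUC 1.000  AUPR 1.000

head(data.frame(cell_id = pred$cell_id, psi = round(pred$psi, 3),
                label = pred$label), 5)
#>     cell_id   psi label
#> 1 cell_0001 0.318     0
#> 2 cell_0002 0.030     0
#> 3 cell_0003 0.962     1
#> 4 cell_0004 0.808     1
#> 5 cell_0005 0.029     0
```

The balancing step turns the 25%-minority source into exactly 75/75 via
SMOTE plus undersampling; after 300 full-batch epochs the source
classification loss has fallen to 0.07, and the per-cell sensitivity
probabilities ψ recover the hidden target labels (ACC 0.990 against the
evaluation-only truth). `ds$truth` exists only for scoring — training never
sees it.

The same run is available as a one-liner:

```r
run_pipeline(list(out_dir = "run1", seed = 1,
                  simulate = list(preset = "separable")))
```

which writes `manifest.json`, per-epoch `losses.jsonl`, `predictions.tsv`
and `metrics.json` under `run1/`. A thin command-line wrapper with
`simulate` / `preprocess` / `build-graph` / `run` / `ablate` / `evaluate`
subcommands lives at `inst/cli/dagformer.R`.

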