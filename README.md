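# kmerattn

Three-class RNA sequence classification — circRNA vs. lncRNA vs. mRNA —
from multi-scale k-mer composition with a multi-head attention network,
plus the full workflow around it: FASTA curation, descriptor baselines,
multi-class metrics, GC/ORF variability analyses, a 2-D UMAP view of the
feature space, and a seeded synthetic-sequence generator that makes the
whole pipeline testable end to end.

## Who this is for

Transcriptomics practitioners who need to assign class labels (circular,
long non-coding, or messenger RNA) to transcript sequences, and method
developers who want a compact, fully reproducible reference implementation
of composition-based multi-class RNA classification.

## The model

Each sequence is represented by its 3-, 4- and 5-mer frequency vectors
(64 + 256 + 1024 = 1344 dimensions; windows containing `N` are skipped and
each scale is normalized to sum to 1). Each scale is projected to a learned
token; the three tokens interact through multi-head scaled dot-product
attention

    Attention(Q, K, V) = softmax(Q K' / sqrt(d_h)) V

and the attended tokens are fused by an MLP ending in a class softmax.
Training is SGD (lr 1e-4, weight decay 1e-4, momentum 0.9) minimizing
cross-entropy; model selection keeps the first epoch maximizing validation
weighted F1,

    F1_weighted = sum_i (TP_i + FN_i)/N * F1_i ,

the headline metric under class imbalance. Curation before training:
exact deduplication, removal of sequences `< 200` nt, greedy redundancy
reduction at 80 % identity (k-mer containment estimate), inter-group
deduplication (shared sequences dropped from **all** classes), stratified
70/15/15 split.

## Worked example

```r
library(kmerattn)

# three synthetic classes emulating circRNA/lncRNA/mRNA contrasts
full <- generate_dataset(generator_spec(default_profiles(),
                                        n_per_class = 500, seed = 7))
ds <- stratified_split(full, split_spec(seed = 8))

fm <- featurize(ds)                         # 1500 x 1344 multi-scale k-mers
state <- train_classifier(split_features(fm, "train"),
                          split_features(fm, "val"),
                          mcfg = model_config(),
                          tcfg = train_config(epochs = 200, seed = 9))
evaluate_classifier(state, split_features(fm, "test"))

# or run the whole pipeline (simulate -> curate -> train -> report) in one call:
cfg <- default_config(out_dir = "demo_run", seed = 7)
cfg$simulate$n_per_class <- 500
cfg$train$epochs <- 200
res <- run_pipeline(cfg)
res$report_test
```

The one-call pipeline prints, among other stage logs:

```
featurize: 1500 x 1344 (train 1050 / val 225 / test 225)
train: best epoch 172 (val F1w 0.8633)
evaluate: val F1w 0.8633 | test F1w 0.8924
analyze: KW H = 177.78 (p = 2.48e-39)
```

and `res$report_test` shows the per-class table:

```
Per-class metrics:
        class support precision recall     f1
 circRNA_like      75    0.8780 0.9600 0.9172
  lncRNA_like      75    0.9189 0.9067 0.9128
    mRNA_like      75    0.8841 0.8133 0.8472
precision  macro 0.8937 | weighted 0.8937 (eq3 0.8933)
recall     macro 0.8933 | weighted 0.8933
F1         macro 0.8924 | weighted 0.8924
accuracy   0.8933
```

Reading: with 500 sequences per class and 200 training epochs the attention
classifier recovers ~89 % weighted F1 on held-out data; `KW H` is the
Kruskal–Wallis statistic confirming the planted between-class GC
differences (tiny p-value). At 1000 sequences per class the same
configuration exceeds 0.92 test weighted F1 (that run is the acceptance
suite's main fixture).

The GC/ORF analyses and embedding are available directly:

```r
rep <- class_feature_report(ds)   # per-class GC/ORF summaries + KW test
emb <- embed_2d(fm, n_neighbors = 80, min_dist = 0.005, seed = 1)
out <- find_outlier_members(emb, attr(fm, "labels"), target_class = "mRNA_like")
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/kmerattn.R simulate --n 300 --seed 7 --out sim/
Rscript inst/cli/kmerattn.R run --out run1 --n 300 --seed 7
```

## Scope notes

The package classifies linear sequence content only: no secondary
structure, no back-splice junction modelling, no genome extraction. The
synthetic generator emulates composition-level class contrasts (GC laws,
ORF structure, motif enrichments) and is not a transcript simulator. See
`vignettes/methods.Rmd` for the model, every tunable parameter, and known
limitations.
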