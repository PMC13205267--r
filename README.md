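# mhsgtr

Integrative clustering of multi-omics tumour cohorts with **M**otif
**h**igh-order **s**imilarity **g**raphs and **t**ensor
**r**egularization. Given several omics layers measured on the same
samples (e.g. mRNA expression, DNA methylation beta values, miRNA
expression), `mhsgtr` learns one affinity graph per layer, fuses them into
a consensus graph, and partitions the cohort into molecular subtypes whose
quality can be scored against survival and clinical annotations. It is
aimed at researchers doing cancer-subtype discovery on cohorts of roughly
80–600 patients.

## Method

For each omics view `v` with sample-by-feature matrix `X^v`:

1. **Sparse autoencoder + self-expression.** A three-layer encoder
   (hidden widths 1024/512 at cohort scale) maps `X^v` to latent codes
   `Z^v`; an L2,1 penalty on the first-layer weights `W(1)` performs
   feature-level selection. A linear self-expressive layer between encoder
   and decoder writes each code as a combination of the others,
   `Z^v ≈ C^v Z^v`, so the coefficient matrix `C^v` doubles as an affinity
   graph (its diagonal is constrained to zero). The per-view loss is

   ```
   (1/2n)‖X^v − X̃^v‖²_F + α‖W(1)‖₂,₁ + λ₁‖Z^v − C^v Z^v‖²_F + λ₂‖C^v‖²_F
   ```

2. **Motif high-order similarity.** A Gaussian-kernel similarity
   `s_ij = exp(−‖x_i−x_j‖²/2σ²)` is thresholded at its median to give a
   binary graph `W⁰¹` and weighted graph `W`; the triangle-motif matrix
   `(W_M)_ij` counts the triangles each adjacent pair closes
   (`(W⁰¹·W⁰¹) ∘ W⁰¹`), and the motif similarity is `M = W_M ∘ W`
   (min–max rescaled). The hybrid graph `A^v = ηS^v + (1−η)M^v` blends
   first-order and high-order structure and anchors the learned graph
   through `λ₃‖A^v − C^v‖²_F`.

3. **Tensor + attention fusion.** The symmetrized `C^v` are stacked into
   an `N×N×V` tensor, rotated to `N×V×N`, and regularized by the t-SVD
   tensor nuclear norm (mean of Fourier-slice nuclear norms along the
   third mode), applied through its exact proximal operator
   (singular-value soft-thresholding in the Fourier domain). A per-sample
   attention module — `softmax(LeakyReLU(CW))` over the `V` omics — fuses
   the graphs into a consensus `CF`, which is row-normalized (`f1`),
   sharpened into a self-training target (`f2`), and refined by a KL term
   `β·KL(P‖S)`.

4. **Spectral clustering** of the consensus graph (symmetric-normalized
   Laplacian, k-means on the embedding) yields the subtypes; `k` is either
   fixed or chosen by the largest Laplacian eigengap in 2–6.

Subtypes are evaluated by the multi-group **log-rank test** (reported as
−log10 p) and by **clinical-label enrichment**: chi-square for categorical
and Kruskal–Wallis for numeric covariates, Benjamini–Hochberg adjusted,
counting labels with adjusted p < 0.05.

A synthetic-cohort generator (`synthetic_spec()` / `generate_dataset()`)
plants cluster-structured Gaussian views, cluster-specific exponential
survival and cluster-linked clinical labels, so the whole pipeline is
testable without any data download.

## Worked example

```r
library(mhsgtr)

spec <- synthetic_spec(n_samples = 120, n_clusters = 3, seed = 5)
gen  <- generate_dataset(spec)
cfg  <- train_config(p1 = 64, p2 = 32, pretrain_epochs = 50,
                     train_epochs = 100, seed = 5)
res  <- run_pipeline(gen$dataset, k = NULL, config = cfg)
res
#> <mhsgtr_result: 120 samples in 3 subtypes>
#> subtype
#>  1  2  3
#> 42 37 41
#> log-rank: chi2 = 21.655, p = 1.98e-05 (-log10 p = 4.70)
#> enriched clinical labels: 1

adjusted_rand_index(gen$labels, res$labels)
#> [1] 1

round(head(res$fit$attention, 3), 3)
#>       [,1]  [,2]  [,3]
#> s001 0.004 0.994 0.002
#> s002 0.002 0.997 0.001
#> s003 0.007 0.992 0.001
```

The three planted subtypes are recovered exactly (ARI = 1); the log-rank
test confirms the planted survival separation (hazards 1.0/0.5/0.25), and
the cluster-associated clinical control column is flagged as enriched
while the independent control is not. The attention rows show per-sample
omics weights on the simplex — here the model concentrates on the second
view for these samples.

Real cohorts enter through `read_omics_matrix()` (TSV/CSV, either
orientation), `read_survival_table()` (`sample`, `time`, `event`) and
`read_clinical_table()`; expression layers are preprocessed with
`filter_expression_features()` (drops features with missing values or
>30% zeros, then zero-variance features) and `log2_transform()`, and
methylation layers with `filter_variance()` (duplicate-probe averaging).
`run_ablation()` reruns the pipeline with the anchor graph replaced by
pure first-order or pure motif similarity, reproducing the similarity
ablation. A command-line wrapper with `simulate`, `preprocess`, `run`,
`evaluate` and `ablate` subcommands is installed under
`inst/cli/mhsgtr.R`.

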