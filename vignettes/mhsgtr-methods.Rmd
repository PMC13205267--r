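---
title: "Motif high-order similarity graphs and tensor-regularized fusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif high-order similarity graphs and tensor-regularized fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhsgtr)
```

## The model

`mhsgtr` clusters a cohort of N samples observed in V omics layers. Its
working assumption is the subspace-clustering one: after a nonlinear
per-view embedding, samples of the same subtype lie near a common
low-dimensional subspace, so each latent code can be written as a linear
combination of its peers, `Z^v ≈ C^v Z^v`, and the coefficient matrix
`C^v` is an affinity graph. Three mechanisms regularize these graphs:

* a **high-order anchor**: a hybrid of the Gaussian-kernel similarity and
  a triangle-motif similarity, pulling `C^v` toward pairs that not only
  look alike but share closed triplets of strong neighbours — the
  motif signal is more robust to spurious edges than first-order
  similarity alone;
* a **tensor nuclear norm** over the stacked, rotated graph tensor,
  encouraging the per-omics graphs to share low-rank structure (the
  complementarity across omics);
* a **self-training KL term** that sharpens the attention-fused consensus
  graph toward its own high-confidence assignments.

The full objective per view sums reconstruction `(1/2n)‖X−X̃‖²_F`,
feature sparsity `α‖W(1)‖₂,₁`, self-expression
`λ₁‖Z−CZ‖²_F + λ₂‖C‖²_F` and alignment `λ₃‖A−C‖²_F`; across views it adds
the tensor nuclear norm of the rotated stack and `β·KL(P‖S)` on the
consensus. Final subtypes come from spectral clustering of the consensus
graph.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` | 0.01 | L2,1 feature-selection strength; small, since views are pre-filtered |
| `lambda1`, `lambda2` | 1, 1 | self-expression residual and ridge on C |
| `lambda3` | 1 | pull of C toward the hybrid anchor A |
| `beta` | 0.1 | KL self-training weight; kept modest so the target cannot run away from the data terms |
| `tnn_weight` | 0.1 | threshold of the tensor prox and strength of the quadratic pull toward its output |
| `eta` | 0.5 | hybrid trade-off: 1 = first-order only, 0 = motif only |
| `sigma` | `"auto"` | Gaussian bandwidth = median pairwise distance (scale-free, consistent with the median edge threshold) |
| `p1`, `p2` | 1024, 512 | encoder widths for cohort-scale feature counts; desk-scale analyses in this package use 64/32 (and 16/8 in the unit tests) |
| `pretrain_lr`, `train_lr` | 1e-4, 1e-3 | Adam step sizes of the two phases |
| `prox_every`, `target_refresh` | 10, 10 | epochs between tensor-prox refresh and between target-P refreshes |
| `leaky_slope` | 0.01 | LeakyReLU negative slope in the attention scores |

The loss weights are exposed as configuration rather than fixed: their
balance is cohort-dependent and should be treated as tuning parameters.

## Numerical and design choices

Where the construction leaves genuine freedom, the package fixes it as
follows (each choice is configurable or isolated behind one function):

* **Edge threshold.** The median is taken over the off-diagonal
  upper-triangle entries of S; the unit diagonal is not an inter-sample
  similarity and would inflate the threshold. Ties at the threshold are
  kept (`≥`).
* **Motif scale.** Raw triangle counts are unbounded, so M is min–max
  rescaled to [0, 1] before blending; η is then a genuine convex weight.
* **Self-expressive diagonal.** `diag(C) = 0` is enforced throughout —
  without it `C = I` solves the self-expression term trivially. The
  anchor graph's diagonal is likewise zeroed before the alignment term.
* **Affinity symmetrization.** Graph consumers (fusion, tensor,
  clustering) receive `(|C| + |Cᵀ|)/2`; the raw, possibly signed C is
  kept for the losses.
* **Tensor convention.** The rotation maps entry (i, j, v) to (i, v, j),
  so the omics mode becomes a matrix dimension of the Fourier slices and
  low-rankness couples the layers. The nuclear norm carries a 1/n₃
  factor, which makes it coincide with the matrix nuclear norm at n₃ = 1;
  under this convention (and Parseval for the unnormalized DFT) the exact
  proximal map soft-thresholds each Fourier slice's singular values by τ
  itself. The prox-optimality property test verifies this directly.
* **Handling the nonsmooth norm.** No closed optimization scheme is
  prescribed for the tensor term, so it is realized by inexact proximal
  regularization: every `prox_every` epochs the stacked symmetrized
  graphs pass through the prox, and each `C^v` is pulled quadratically
  toward its low-rank slice between refreshes.
* **KL conventions.** The printed target-distribution transform is
  degenerate as a formula, so the standard self-training target
  `p_ij ∝ s_ij²/f_j` (column-mass normalized, rows renormalized) is used.
  The divergence is computed against the row-renormalized f1 output, with
  `0·log 0 := 0`; the ratio `p/q` is taken as 0 where both vanish (the
  correct limit of the summand), and `p > 0` where `q = 0` is a hard
  error rather than a silent infinity.
* **Decoder input.** During pretraining the decoder reconstructs from Z;
  during joint training from `CZ`, so the reconstruction path exercises
  the self-expressive layer. Both appear in the literature; the choice is
  localized in `encode_decode()`.
* **Attention.** The weight matrix is initialized all-ones and trained
  jointly by gradient — an adaptive weighting needs trainable
  parameters. Softmax runs across the V omics per sample, making each row
  of the weight matrix a point on the V-simplex. With identical views and
  identical per-view initial weights the objective is exactly symmetric
  under view exchange, and the learned weights stay uniform; per-view
  encoder weights are therefore drawn from the same seeded stream.
* **Initialization of C.** When the alignment term is active (`λ₃ > 0`),
  C^v starts at the zero-diagonal anchor A^v (a warm start consistent
  with the term it is pulled toward); with `λ₃ = 0` it starts at zero,
  the usual cold start of pure self-expressive training.
* **Optimizer.** Full-batch Adam. Cohorts in the intended range
  (N ≤ ~600) fit in memory, and full-batch gradients make runs exactly
  reproducible from the seed.
* **k selection.** When k is not fixed, the largest eigengap of the
  symmetric-normalized Laplacian within 2–6 is used; any externally
  chosen k can be passed instead. Which rule produced a given published
  k is generally not recoverable, so both modes are provided.
* **Degenerate inputs.** Duplicate IDs, empty sample intersections,
  all-features-filtered matrices, zero off-diagonal consensus rows, and
  support violations in the KL all raise errors naming the offender;
  fewer than three samples (no triangles) and more graph components than
  clusters raise warnings.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` plants k subtypes with mixing proportions on the
simplex. Each view draws informative features (a configurable fraction)
with cluster-specific means of magnitude `separation·noise_sd/2` and
random sign per cluster, plus pure-noise features; survival times are
exponential with cluster-specific hazards under independent exponential
censoring; the clinical table carries one cluster-associated categorical
column (80% concordant) and one independent column, giving the
enrichment counter a positive and a negative control.

The defaults — 150 samples, 3 balanced subtypes, views of 120/100/80
features, separation 3, hazards 1.0/0.5/0.25, 20% censoring — are the
package's reference study conditions: a cohort size in the range of the
smaller TCGA cohorts and a separation at which subtypes are recoverable
but not trivial at the feature level.

The generator is deliberately Gaussian. It does not emulate count
overdispersion, methylation beta-value bimodality, batch effects, or
feature-feature correlation beyond the planted means. Passing tests
therefore demonstrate correctness of the machinery and recoverability
under the model's own assumptions — not performance on real cohorts. One
consequence worth knowing: on well-separated Gaussian views, the
first-order kernel graph is already excellent, so the motif term's
denoising advantage is not visible there. That advantage is exercised on
its natural substrate, noisy stochastic-block graphs
(`generate_block_graph()`), where spurious between-block edges close few
triangles; the ablation fixture uses 3 blocks of 30 nodes with edge
probabilities 0.7 within and 0.3 between — a regime chosen once, where
first-order recovery is imperfect (mean ARI below 1) and the high-order
signal is informative.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
unit tests at N = 36–60 with encoder widths 16/8 and 10–25 epochs; the
end-to-end recovery benchmark at N = 150, widths 64/32, 50 + 100 epochs,
five seeds; oracle comparisons on 100 random graphs (N ≤ 60) and random
tensors up to 20×20×5. Every stochastic step — generation, weight
initialization, k-means restarts — is seeded, and two runs with the same
configuration and seed produce bit-identical traces and labels. The
per-epoch trace records every objective term; the final row is
recomputable from the returned state via `loss_terms()`, which the tests
assert.

## Known limitations

* The joint objective is nonconvex; different seeds can reach different
  local optima. The package reports the seed in every manifest rather
  than pretending otherwise.
* The tensor term enters through inexact proximal regularization, not an
  exact ADMM splitting; with `prox_every = 1` and a small learning rate
  it approaches a proximal-gradient scheme, but no convergence guarantee
  is claimed.
* The L2,1 subgradient at zero rows is taken as 0; rows that hit exactly
  zero stay zero under this convention.
* Attention weights are per-sample and per-omics; no per-feature
  weighting is attempted.
* Preprocessing assumes the methylation input is already a QC'd numeric
  matrix; array-level normalization is upstream of this package.
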