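---
title: "Co-supervised graph-attention clustering of scRNA-seq counts: model and methods"
author: "zigacl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-supervised graph-attention clustering of scRNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-cell RNA-seq count matrices are sparse, overdispersed and noisy:
many observed zeros are technical dropout events rather than biological
absence, and library sizes vary by orders of magnitude between cells.
Clustering cells into types on such data benefits from (i) a noise model
that separates technical zeros from true expression, and (ii) structural
information about which cells resemble which. `zigacl` combines both: a
denoising autoencoder whose decoder parameterises a zero-inflated negative
binomial (ZINB) likelihood over the raw counts, and a graph attention
network (GAT) over a cell-cell similarity graph, trained jointly under a
co-supervised clustering objective.

## Preprocessing

Genes expressed in no cell are removed. Size factors are each cell's
library size divided by the median library size; expression is depth
normalised by these factors. Per gene, a dispersion coefficient is computed
as the variance-to-mean ratio of the normalised expression, and the
`nTop = 2500` genes with the highest dispersion are kept (ties broken by
original gene order for determinism). Two views of the kept genes are
carried forward:

* the **raw counts** `E` — the observation matrix of the ZINB likelihood;
* the **model input** `X` — the per-gene z-score of `log1p` normalised
  expression.

Dispersion is computed on the normalised scale by default (removing
depth-driven variance); `dispersionOn = "raw"` is available because the
scale on which dispersion should be ranked is a genuinely open choice.

## Cell graph

Cosine distances `d_ij` between the rows of `X` feed a Gaussian kernel
`A_ij = exp(-d_ij^2 / (2 r^2))`. The bandwidth `r` defaults to the median
pairwise cosine distance (`"auto"`), which adapts the kernel to the
dataset's scale. The dense kernel is sparsified to each cell's
`kNeighbors = 15` highest-kernel neighbours, symmetrised by union — finite
neighbourhoods are required by the attention softmax and keep the cost
O(nk). The transition matrix `B` puts `1/m_i` on each retained edge
(`m_i` = degree), and the topological correlation

```
R = (B + B^2 + ... + B^t) / t,   t = 2 by default
```

summarises multi-hop proximity. `t = 2` is the smallest order that looks
beyond first neighbours; larger orders smooth the graph further and are
configurable. Cells whose feature rows are all zero have undefined cosine
direction; their distances are set to the maximum (2) and reported.

## ZINB denoising autoencoder

The encoder maps `X` through fully connected layers of widths 256 and 64
(each followed by batch normalisation and ReLU) into a 16-dimensional
latent code `H`; a Gaussian noise layer (`noiseSigma = 1` on the z-scored
input) makes it a denoising autoencoder. The decoder mirrors the encoder
(16 → 64 → 256, ReLU), and three linear heads on the 256-dimensional
decoder output `D` produce the ZINB parameters per cell and gene:

```
pi    = sigmoid(W_pi D)          dropout probability
mu    = s_i * exp(W_mu D)        NB mean, scaled by the cell size factor
theta = exp(W_th D)              NB dispersion
```

The pretraining loss is the negative ZINB log-likelihood of the raw counts,

```
ZINB(x) = pi * I[x = 0] + (1 - pi) * NB(x | mu, theta)
```

computed in log space (log-gamma, log-sum-exp for the zero branch) and
reduced to a mean per entry so its magnitude is comparable across dataset
sizes. Numerical guards clamp `pi` to `[1e-8, 1 - 1e-8]` and `mu`, `theta`
to `[1e-4, 1e4]`; clamped entries carry no gradient. The dispersion is one
value per (cell, gene) as the head parameterisation implies. Optimisation
is full-batch Adam (learning rate 0.001) with the global L2 gradient norm
clipped to 3; gradients of every layer are hand-derived and verified
against central finite differences in the test suite.

## Graph attention with higher-order weighting

Three attention layers mirror the encoder widths (input → 256 → 64 → 16).
In each layer, with `P = input %*% t(W)`, edge scores are
`c_ij = a1·P_i + a2·P_j` (the concatenation form `a^T [W x_i || W x_j]`),
and the attention coefficients are a neighbourhood softmax of
`R_ij * LeakyReLU(c_ij)` — the topological correlation weights multi-hop
neighbours into the attention. Self-loops are added to every neighbour
set (standard GAT practice; it also covers isolated nodes). The layer
output is `LeakyReLU(A_alpha %*% P)` with negative slope 0.2 and a single
attention head.

At every layer the GAT input is fused with the matching encoder layer
output:

```
zbar = (1 - lambda) * z + lambda * H_enc,   lambda = 0.4 by default
```

so the structural view is continuously anchored to the denoised view.
`lambda = 0` is a pure GAT, `lambda = 1` reduces the pipeline exactly to
the autoencoder path (a tested wiring invariant). A final linear layer and
row softmax over the fused 16-dimensional embedding give the k-way head
distribution `Z`.

## Co-supervised objective

Cluster centres `u_k` are initialised by k-means (20 restarts, seeded) on
the pretrained latent code. The soft assignment uses a Student-t kernel
with `v = 1` degree of freedom (the standard deep-embedded-clustering
choice):

```
q_ik ∝ (1 + ||h_i - u_k||^2 / v)^-(v+1)/2
```

The sharpened target squares the assignment and normalises by the soft
cluster frequency `F_k = sum_i q_ik`:

```
p_ik ∝ q_ik^2 / F_k
```

and is recomputed every `pUpdateInterval = 5` epochs for a stable moving
target (it is treated as a constant in the gradients, as usual for
self-training). The joint loss is

```
L = L_ZINB + alpha * KL(P || Q) + beta * KL(P || Z),  alpha = 0.1, beta = 0.01
```

with the KL terms reduced to a mean per cell, matching the mean-per-entry
ZINB reduction so the weights act on size-independent quantities. One
shared noisy forward pass feeds all three terms; labels and the target are
taken from a deterministic (noise-free, running-statistics) forward pass.
Training stops at `maxEpochs = 300` or as soon as fewer than 0.1% of the
cells change their argmax-Q label between consecutive target updates.
Hard labels are the row argmax of Q with ties broken toward the lowest
cluster index. The GAT head is trained from scratch during fine-tuning; Z
acts purely as a co-supervision signal, and the reported clusters always
come from Q.

## Synthetic data

`simulateCounts()` implements a splat-style groups simulation so the whole
pipeline can be exercised without downloads: gene means from
Gamma(shape 0.6, rate 0.3); per-group differential-expression factors
applied with probability 0.1 per gene, magnitudes log-normal(0.1, 0.4) and
inverted with probability 0.5; library sizes log-normal(11, 0.2); a
biological-coefficient-of-variation layer (bcv 0.18) giving gamma-Poisson
counts with variance `mu + bcv^2 mu^2`; and optional logistic dropout.
Group proportions are drawn from a symmetric Dirichlet(1) — i.e. uniformly
at random from the simplex. The default scenario is 5000 cells, 10 000
genes, five groups.

`injectDropout(rate)` zeroes a uniform sample of `round(rate * nnz)`
currently non-zero entries, emulating increasing technical dropout on
observed data; this masking definition (rather than the simulator's
logistic dropout) is what the bundled robustness experiment uses.

What the simulation does *not* emulate: batch effects, trajectories,
ambient RNA, doublets, or the gene-gene correlation structure of real
tissues. Passing the recovery tests therefore demonstrates correctness of
the machinery on well-specified generative data, not performance on any
real dataset.

## Problem sizes and schedules used by the bundled experiments

The package defaults are 200 pretraining and up to 300 fine-tuning epochs.
The bundled experiments and the acceptance script run a reduced scenario —
1000 cells × 2000 genes, five groups with splat-default parameters, the
1000 most dispersed genes, 80 pretraining epochs and a short fine-tuning
cap (40–60 epochs; the label-change criterion usually halts far
earlier) — chosen so a complete dropout-robustness series runs on a
single CPU in minutes. On this scenario plain k-means on the top
principal components of the preprocessed input separates the five groups
exactly at zero dropout, and the pipeline recovers the generating labels
essentially perfectly on most seeds (on unlucky initialisation seeds a
split/merge optimum with ARI around 0.65 persists; see the limitations).

The dropout-masking series behaves differently at this reduced scale than
at full scale, and the vignette is explicit about why. Reducing the gene
count five-fold while keeping the splat-default library size (`e^11`)
concentrates the same sequencing depth on 2000 genes, giving ≈30 counts
per entry; masking an observed entry then moves the `log1p` scale by
about 3.4 — an extremely strong per-entry perturbation. Measured on these
data, even a PCA + k-means baseline on the preprocessed input falls from
ARI 1.0 (no masking) to ≈0.07 at 20 % masking, i.e. the recoverable group
signal itself is destroyed, independently of any model. Consequently the
fitted embeddings at masking rates ≥20 % are degenerate, and their
silhouette widths measure the compactness of arbitrary partitions rather
than of real structure: the silhouette-vs-dropout series is not expected
to be monotone at this scale, although its large drop from the unmasked
fit is. A variant of the reduction that preserves the full-scale count
per entry (library-size location lowered by `log 5`) makes the baseline
degrade gracefully (1.0 → 0.3 → 0.01 across 0/20/40 % masking) but
weakens the zero-dropout signal enough that latent k-means recovery
becomes unreliable; the bundled experiments therefore stay with the
splat-default conditions.

## Numerical and design notes

* The attention softmax treats the topological weight `R_ij` as a
  multiplicative factor inside the exponent, normalised over each
  neighbourhood — the only reading of the weighted-attention formula that
  yields a normalised distribution.
* Empty clusters (a column of Q summing to 0) are dropped from the target
  normalisation with a warning; k-means initialisation re-seeds on
  degenerate restarts.
* All randomness (simulation, weight initialisation, input noise, k-means,
  dropout masks) derives from one root seed through fixed named
  sub-streams, so stages are independently reproducible and two runs with
  the same seed are bit-identical.
* The dense kernel, transition and topological-correlation matrices are
  kept dense; at the intended desk scale (a few thousand cells) this is
  faster and simpler than sparse bookkeeping. Memory grows as n^2.
* HDF5 containers are not read or written; counts move through dense
  CSV/TSV or MatrixMarket-with-sidecars files, and preprocessing persists
  to a plain-text directory bundle (`writeBundle()`/`readBundle()`).

## Known limitations

* Full-batch training bounds the practical size to tens of thousands of
  cells; no minibatching is implemented.
* k is required; the method does not select the number of clusters.
* The fine-tuned solution inherits the k-means initialisation's basin: on
  unlucky seeds a split/merge local optimum can persist (visible as high
  NMI with lower ARI). The majority-over-seeds framing of the recovery
  experiment reflects this.
* Evaluation silhouettes use the predicted labels in the 16-dimensional
  latent space (Euclidean); ground-truth labels can be supplied instead.
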