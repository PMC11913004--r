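---
title: "Signed multi-view graph attention with cross-view transformer fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed multi-view graph attention with cross-view transformer fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvgat)
```

## The problem

Resting-state fMRI connectomics summarizes a subject's brain as a symmetric
region-by-region correlation matrix (functional connectivity, FC). Group
differences between diagnostic classes — here a binary case/control label
such as autism spectrum disorder versus typical controls — express
themselves as small, distributed shifts in that matrix. `mvgat` classifies
subjects directly from FC matrices with a graph neural architecture that
treats positive and negative correlations as separate signed edge channels
and looks at each channel at several graph densities ("views") before
fusing everything with cross-attention.

## The model

**Signed views.** `signed_split()` writes the off-diagonal part of the FC
matrix as `pos - neg` with both channels nonnegative; strong
anti-correlations are information, not noise, so they get their own graphs.
For each sign channel, view `v` keeps the `ceiling(rho_v * P)`
largest-magnitude edges, where `P` is the number of candidate edges of that
sign and the retention fractions `rho_v` increase across views (defaults
`(1:V)/(V+1)`). Because all views rank the same edge list once, the
retained edge sets are nested: sparse views see only the network's
strongest backbone, denser views add context. How multiple FC views ought
to differ is a genuinely open design choice; graded sparsification is the
convention of the multi-view FC literature this package sits in, and both
`V` and the densities are configurable.

**Graph attention branch.** Every view graph passes through two graph
attention (GAT) layers. A GAT layer transforms node features with a shared
map `W`, scores each edge with the canonical single-layer scorer
`e_ij = LeakyReLU(a^T [W h_i || W h_j])` (slope 0.2), masks scores to the
retained neighborhood plus the node itself, normalizes with a softmax, and
aggregates `out_i = sum_j alpha_ij W h_j`. Self-loops guarantee the softmax
is defined even for isolated nodes. Retained edge *weights* only define the
mask — the score is feature-based, which is the strict reading of the
attention formulation we implement; a weighted variant would be a different
scorer, not a different mask. GAT-1 is followed by an ELU and a residual
skip from the raw features (a learned bias-free projection when the feature
width differs from the GAT width, identity otherwise); GAT-2 is linear.

**Per-view heads and tokens.** The GAT-2 outputs of the two sign channels
are mean-pooled over nodes and concatenated — 64 + 64 = 128 wide by default
— and classified by a per-view head `Linear(128,16) -> ReLU ->
Linear(16,2)`. In parallel, each channel's GAT-2 output is projected from
64 to the transformer width 96 and run through one pre-norm transformer
encoder block (`R1 = x + MHA(LN(x), LN(x)); out = R1 + FFN(LN(R1))`, 4
heads, feed-forward width `2 d`). Node tokens carry no positional encoding:
brain regions are an unordered set, and positions would break the
relabeling behavior discussed below.

**Cross-view fusion.** The fusion block takes two token matrices: both are
layer normalized, multi-head attention draws queries and keys from the
first and values from the second, the attention output is added back onto
the first input, and a layer-normalized two-layer MLP with a second
residual finishes the block. The encoder block above is exactly this block
applied to `(x, x)` with shared parameters — one implementation serves
both. Because queries *and* keys come from the first input, the attention
matrix is square in the first input's token count and the value matrix must
match it row-for-row: the two inputs must have equal token counts, and the
block is equivariant only under a *joint* permutation of both inputs'
tokens. (Permuting the value source alone re-pairs attention weights with
values and changes the output; a variant drawing keys from the value source
would behave differently, but is not the architecture implemented here.)

Per sign branch, the per-view encoder outputs `T_1 .. T_V` are folded left:
`X_1 = block(T_1, T_2)`, `X_k = block(X_{k-1}, T_{k+1})`. With three views
this produces exactly two intermediates per branch; the generalization to
any `V` is the same left fold, with `V = 1` bypassing fusion and `V = 2`
re-using its single output twice so the classifier width stays fixed.

**Readout and classifier.** The last two fold outputs of each branch are
mean-pooled over tokens to 96-vectors. Pooling *before* flattening is a
deliberate reconciliation: flattening raw `N x d` token matrices would make
the classifier width depend on the parcellation size `N`, whereas the
architecture's fixed head `Linear(384,32) -> Linear(32,16) -> Linear(16,2)`
requires a 384-long input — exactly four pooled 96-vectors (two per sign
branch). Mean pooling is also what makes the readout independent of token
order. ReLUs sit between the three affine maps; the final 2-vector is the
logit pair.

**Loss.** Training minimizes the fusion head's cross-entropy plus
`lambda = 0.5` times the summed per-view head cross-entropies. The
architecture gives every view its own classifier output as well as a fused
one; treating the per-view outputs as auxiliary losses regularizes each
branch while keeping prediction unambiguous — `predicted_label` always
comes from the fusion head. `lambda` is configurable, `lambda = 0` recovers
a pure fusion objective.

## Width bookkeeping

The two fixed head widths — 128 into the per-view head and 384 into the
fusion head — cannot both be realized at a single constant embedding width:
128 forces 64 per sign channel after GAT-2, while 384 forces 96 per pooled
fusion tensor. The token projection (64 to 96) between GAT-2 and the
encoder stage is the explicit bridge that makes both hold simultaneously.
`model_config()` derives both widths and the constructors refuse
inconsistent settings; a wrong fusion input width raises an error naming
both the actual and the expected length.

## Gradients and optimization

No deep-learning framework is involved: forward and backward passes are
written in base R matrix algebra, with analytic gradients for every
parameter group (GAT maps and scorers, skip projections, token projections,
attention projections, feed-forward and layer-norm parameters, and all
classifier heads). The test suite verifies the full gradient against
central finite differences on a 5-node toy model at relative error below
`1e-4`. Training uses mini-batch Adam (`lr = 1e-3`, weight decay `5e-4`,
batch 16, 100 epochs by default), Glorot-uniform initialization, and is
fully seeded: weight draws, batch shuffles and fold assignments all derive
deterministically from integer seeds, so identical seeds reproduce
parameters, metrics and simulation files exactly.

Numerical choices: all softmaxes subtract the row maximum before
exponentiation; cross-entropies go through log-sum-exp; layer norm uses the
population variance per token row with `eps = 1e-5`; top-k edge retention
breaks ties by (weight desc, smaller index, larger index) so view
construction is reproducible across platforms.

## The synthetic cohort

`simulate_cohort()` draws each subject's "time series" as `T = 200`
multivariate normal samples from a modular block covariance over `N = 32`
regions (three modules of 11/11/10), and returns the sample Pearson
correlation. Within-module correlation is 0.6; one designated inter-module
block sits at 0.45 for controls and `0.45 - delta` for cases
(`delta = 0.3` by default); one block is anti-correlated at -0.2 so the
negative-edge channel is non-trivial; remaining blocks sit at 0.1.
Per-subject block-level jitter (sd 0.02) adds heterogeneity, with a
positive-definiteness check and bounded retries. Both class covariances are
verified positive semi-definite at construction.

This emulates the *structure* of FC cohorts — correlation-valued symmetric
matrices, unit diagonal, modular organization, a localized group
difference, signed edges — and deliberately not their harder features: no
hemodynamics, no site or scanner effects, no motion artifacts, no global
signal confounds, and a single known discriminative block rather than
distributed subtle effects. Passing tests on this generator shows the
pipeline can learn planted connectivity differences end-to-end; it says
nothing about accuracy on real multi-site clinical data.

## Node features and relabeling

Three node-feature modes exist. `fc_row` (default) attaches each node's row
of its signed channel matrix — the only subject-specific per-node signal
available at matrix level, and the most informative choice for
classification. Its cost is that the feature axis is itself indexed by node
labels, so relabeling regions changes each node's feature *vector* (a
column permutation), and the network's output is not exactly
relabeling-invariant. `degree` (weighted degree) transforms covariantly, so
with it the whole pipeline — view construction, GAT layers, encoder,
fusion, pooled readout — is exactly invariant to node relabeling, which the
tests assert end-to-end at `1e-5`. `identity` (one-hot) is provided for
experiments with purely structural inputs. In practice a fixed atlas fixes
the labeling, so `fc_row`'s label dependence is harmless; the invariance
tests use `degree` because that is the mode for which the property is
mathematically true.

## Problem sizes used by the test suite

Unit tests run on 5-12 node toys. The cross-validated learning check uses
the full default cohort (100 subjects, 32 regions) with the default
architecture and 12 Adam epochs per fold — chosen because the training loss
plateaus and a held-out split is already perfectly separated well before
that at the strong effect size; the package default of 100 epochs is meant
for weaker, real-data-scale signals. At `delta = 0.4` the stratified 5-fold
accuracy is at ceiling, and it degrades toward chance as `delta` shrinks,
which is the qualitative behavior a planted-effect recovery check needs.

## Known limitations

- The per-view branches, encoder and fusion blocks do not share weights
  across views; with many views the parameter count grows linearly.
- Graph coarsening (merging regions into super-nodes) is exposed only as a
  `coarsen` hook in `build_views()`; no coarsening scheme ships with the
  package.
- The fusion fold is ordered by view index; view order matters to the fold
  even though each block's token mixing is order-free.
- Pure-R training is practical for cohort sizes in the hundreds at 32-128
  regions; thousand-subject, high-resolution parcellations would want a
  compiled backend.
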