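---
title: "Panel reduction for multiplex immunofluorescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel reduction for multiplex immunofluorescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panelreduce)
```

## The problem

Cyclic immunofluorescence and related multiplex imaging methods acquire
dozens of marker channels on one tissue section through repeated
stain/image/bleach rounds. Each round costs acquisition time and degrades the
tissue, so panel slots are scarce. Because many proteins are co-expressed,
part of a panel is informationally redundant: a withheld marker's single-cell
signal can often be predicted from markers that remain. `panelreduce`
implements the computational side of that trade: score candidate reduced
panels, impute the withheld channels with a generative model, and measure
what information survived.

The package operates on two data atoms: the `single_cell_image` (a
channels × height × width crop in [0,1] with its binary mask) and the
cells × markers mean-intensity matrix. Segmentation is deliberately out of
scope — label masks are consumed as inputs, produced upstream by whatever
pipeline the lab uses.

## Preprocessing

Raw channels are normalized by percentile histogram stretching
(`histogram_stretch`, defaults 1st/99th percentile computed over foreground
only; the background mask is an explicit input because background level is an
acquisition property we cannot guess). Single cells are cut from label masks
(`extract_single_cells`), with the cell mask formed by dilating the label by
3 px (a rasterized Euclidean disk) without absorbing neighbouring labels —
the conventional "ring mask" that captures peri-nuclear and membrane signal.

Two nuisance transformations are removed before encoding, because a VAE
otherwise spends latent capacity on them: each crop is rotated so the mask's
second-central-moment major axis is horizontal (`align_major_axis`; bilinear
for pixels, nearest-neighbour for the mask; a perfect circle is defined to
have orientation 0 and is left alone), and flipped so the reference channel's
intensity centroid lies in the upper-left quadrant (`orient_by_mass`; the
flip is exactly idempotent, centroids exactly on an axis trigger no flip).
The choice of quadrant and of reference channel (default: the nuclear marker)
is a convention; any consistent one removes the nuisance, so we fix one and
expose the channel as an argument.

Training/evaluation use a seeded 90/10 cell split (`split_cells`), and the
same split must be reused across selection and evaluation — reuse the seed.

## Panel scoring and selection

**Correlation scoring.** For a candidate panel *R* with withheld set *W*,

score(R) = mean over w in W of max over r in R of corr(w, r),

computed on a marker–marker Spearman correlation matrix of mean intensities
(`correlation_matrix`; Pearson by flag). Spearman is the default because
mean-intensity accuracy is reported as rank correlation downstream, and
because CyCIF intensity distributions are heavy-tailed. The max is over
*signed* correlations by default; `use_abs = TRUE` treats anticorrelated
markers as predictive too. Both are defensible — an anticorrelated partner
carries the information but a simple substitution baseline cannot use it —
so the knob is exposed and defaults to the signed reading.

`select_panel_corr` enumerates every size-*n* superset of the required
markers and keeps the best score; ties go to the lexicographically smallest
sorted panel so results are reproducible. Enumeration is exact up to a
budget (default 2.5e5 candidate panels, configurable); beyond it, `"auto"`
mode falls back to greedy forward selection, which is the documented
approximation for large panels. The nuclear stain is required in every panel
because segmentation depends on it. Panels are re-selected independently at
each size — a marker present at size *n* may be absent at size *n* + 1.

**Self-expressive interaction map.** `fit_interaction_map` learns a
zero-diagonal coefficient matrix `C` reconstructing each cell's intensity
vector from the other markers:

minimize mean over cells of ||I − C·I||² + (λ/n)·||C||²,  with C_ii = 0,

where n is the marker count. The diagonal constraint stops `C` from
collapsing to the identity. Written this way the problem separates into one
ridge regression per row, which the closed-form solver solves exactly; a
projected-gradient solver is provided and agrees with the closed form to
better than 1e-3 relative Frobenius error (it exists to mirror the original
trained-matrix formulation and as a check of the algebra). Two points were
genuinely open and are fixed here by documented choice: the data term is the
*mean* over cells, so λ (`lambda_scale`, default 0.1) does not change meaning
with sample size; and although the penalty is described as sparsity-inducing,
a squared penalty is what the objective states, so ridge is the default and
an L1 mode (via glmnet) is available but off. Entries with |C| < 0.05 are
then zeroed (`threshold`), matching the stated cutoff.

**Interaction scoring.** For a candidate panel,

score(R) = mean over w in W of Int(w, R) − mean over r in R of Int(r, R\{r}),

where Int(m, S) sums |C[m,s]| + |C[s,m]| over s in S. `C` is not symmetric
and the score's directionality is otherwise ambiguous, so both directions are
summed and absolute values prevent cancellation. One subtlety of this score
is worth knowing: moving a marker with *no* interactions from the withheld
set into the panel removes a zero term from the withheld average and can
therefore raise the score even though the marker predicts nothing — the
score rewards panels whose withheld set is well-covered, not panels that are
individually informative. The same exhaustive/greedy machinery and
tie-breaks apply (`select_panel_ssc`).

**Gradient ranking.** `encoding_gradients` takes a `mevae` trained with the
full panel as both input and output, backpropagates the reconstruction (BCE)
loss to each channel's latent encoding, and averages absolute gradients over
latent dimensions and cells (absolute values first, otherwise opposite-signed
gradients cancel). Channels whose encodings the decoder relies on get large
gradients. `select_panel_gradient` then takes the top-*n* by importance;
because the ranking is static, panels are nested across sizes. Whether
importances are computed on training or held-out cells is not pinned down by
the method; the default is the training split, and the argument accepts any
cell set.

**Baselines.** `select_panel_random` gives a seeded nested random ordering.
`baseline_substitute` is the no-model baseline: each withheld marker's
prediction is a verbatim copy of its most-correlated in-panel partner's
column. By construction its withheld-marker Spearman equals the precomputed
partner correlation — a definitional identity the test suite asserts — which
is exactly why it is a useful floor: it is what a reduced panel buys you with
no computation at all.

## The imputation model

`mevae()` is a multi-encoder variational autoencoder: one encoder per input
channel maps that channel's pixels to the mean and log-variance of its own
latent block; blocks are concatenated and a single decoder emits all output
channels through a sigmoid. Keeping per-channel encodings separate is what
makes the gradient ranking above well-defined. Encoders and decoder are each
3 layers deep with ReLU activations (sigmoid at the output). The layers are
dense: at the 32–64 px crops this package targets, a 1024-dimensional pixel
vector per channel is comfortably handled by dense layers, the parameter
count stays modest, and training is exactly reproducible with plain matrix
arithmetic — convolutional encoders would buy translation equivariance the
aligned, oriented crops no longer need.

The loss is

L = BCE(x, decoder(z_all)) + (1/n) Σᵢ KL[qᵢ(zᵢ|xᵢ) ‖ N(0, I)],

pixelwise binary cross-entropy (targets must be in [0,1]; the preprocessing
guarantees it, and the fitter clips with a warning otherwise) plus the mean
over the n encoders of each posterior's KL divergence from a unit-Gaussian
prior. This is the standard VAE objective applied per-encoder; a literal
reading of the originating formulation (subtracting a KL between the
posterior and the decoder output) is not a well-defined objective, so the
standard reading is implemented deliberately rather than silently.

Tunables, with defaults and reasoning:

* `latent_total` (128): per-channel dimension k = argmin |n·k − 128|, ties to
  the larger k (`latent_allocation`); equal allocation keeps channels
  comparable for gradient ranking, and 128 cannot always be hit exactly.
* `hidden` (128, 64): encoder widths, mirrored in the decoder. Wide enough to
  carry intensity and shape at these crop sizes; doubling them measurably
  slows training without changing the evaluation metrics at study scale.
* `epochs` (10), `batch_size` (64), `learning_rate` (1e-3, Adam): the epoch
  count follows the training protocol the evaluation assumes; optimizer
  settings are unexceptional defaults for this loss scale.
* `seed`: initialization (Glorot uniform), shuffling and reparameterization
  noise all derive from one R stream, so two fits with the same data and
  seed are bit-identical — the determinism the tests assert.

Inference (`impute_full` / `predict`) uses encoder means with no sampling, so
it is deterministic and repeated calls agree exactly. Outputs are sigmoid
activations, strictly inside (0,1).

## Evaluation metrics

* `spearman_per_marker`: rank correlation per marker between true and
  imputed mean intensities, means and across-marker variances reported
  separately for withheld and all markers (the variance distinguishes
  "everything predicted reasonably" from "a few markers predicted well").
  Constant columns get 0 with a warning.
* `ssim`/`ssim_per_channel`: structural similarity with the classical
  Gaussian window (11×11, σ = 1.5) and constants (0.01·L)², (0.03·L)²; the
  local map is averaged over the fully-windowed region, and the window
  shrinks with a warning on small crops. Identity, symmetry and the
  constant-image closed form are asserted in tests.
* `nmi`: MI(U,V)/mean(H(U),H(V)) in natural logs (the ratio is
  base-invariant). Cells labeled −1 (outliers) in either labeling are
  excluded pairwise; a constant labeling has zero entropy and returns 0 with
  a warning — a documented convention for a case the method does not
  normally reach.
* Clustering: seeded `kmeans_cluster` on per-marker z-scored intensities
  (the same standardization applied to truth and prediction, so the
  comparison is fair), with `choose_k_silhouette` automating the elbow as
  the maximum second difference of the silhouette-vs-k curve (ties to
  smaller k). `graph_cluster` is a kNN-graph/Louvain community detection
  with the two classical cytometry-scale parameters exposed (neighbours,
  minimum community size; communities below the minimum become outliers);
  optional Jaccard edge weighting reproduces the shared-neighbour weighting
  of PhenoGraph-style tools. Both parameter defaults (500/2000) assume
  ~10⁵–10⁶ cells and must be scaled down proportionally on small data.
* `match_clusters`: optimal one-to-one label pairing maximizing shared cells
  on the contingency table (a native Hungarian implementation, tested
  against brute-force permutation enumeration); surplus labels when cluster
  counts differ are left unmatched rather than forced.
* `shuffled_baseline`: mean NMI of seeded permutations — the chance level an
  observed NMI must clear. Its magnitude depends on cell count: with ~2000
  cells and 4 clusters chance sits near 0.002, but at 200 cells it rises
  above 0.01, which is why cluster-level comparisons here are computed on
  the full imputed population while mean-intensity accuracy is judged on the
  held-out split (a population analysis needs population scale).
* `embed_cells`: a deterministic two-axis principal-component projection
  with a fixed sign convention, used only to visualize cluster structure
  (`plot_embedding`; outliers grey). Any nonlinear embedding could be
  substituted; nothing downstream consumes the coordinates.

## The synthetic data generator

`generate_dataset` exists so that every stage is testable without external
data. It plants exactly the two properties the selection and imputation
methods exploit:

1. **Block-correlated expression.** Markers are partitioned into redundancy
   blocks; each cell draws a latent factor per block (Gaussian around its
   cell type's mean, sd `factor_sd` = 0.06, clipped to [0,1]) and each
   marker's scalar expression is its block factor times a fixed gain
   (1, 0.88, … within a block) plus Gaussian noise
   (`within_block_noise_sd`, default 0.05). With zero noise, within-block
   correlations are exactly 1 — the property the selector-recovery tests
   lean on — and with noise the attenuation is analytically checkable.
2. **Channel-distinct spatial patterns.** Each cell is an ellipse with major
   axis 10–20 px (at the default 32 px crop), random eccentricity and
   orientation; nuclear markers paint an inner ellipse (55% linear scale),
   membrane markers a ~2 px boundary band, cytoplasmic markers the rest.
   Painted pixels carry multiplicative Gaussian texture (sd 0.05).

The default panel is 8 markers in 4 blocks over 4 cell types, with type
means chosen so types are separable but overlapping, and the nuclear block
bright in every type (nuclei are always stained). All randomness flows from
one seed, scalar draws precede rendering draws (so intensity-only runs are
consistent with rendered ones), and identical (spec, seed) gives
byte-identical output.

What the generator does **not** emulate: autofluorescence, staining-cycle
misregistration, illumination gradients, cell–cell contact topology, or the
heavy-tailed intensity distributions of real CyCIF — it is a stand-in with
planted structure, not a physical model. Passing tests on it demonstrates
that the machinery recovers structure that is present; it says nothing about
how much redundancy a real panel contains.

## Numerical choices and conventions

* Tensors are channel-first; pixel indices are (row, column); one stated
  convention prevents silent transposes.
* Degenerate branches: all-background images error; constant foreground
  stretches to zeros with a warning; empty labels and empty perturbed masks
  are skipped with a message; zero-entropy labelings give NMI 0 with a
  warning; singular ridge systems at λ = 0 instruct the user to set λ > 0.
* Score ties in selection break to the lexicographically smallest sorted
  panel; importance ties in gradient ranking break by marker name; the
  silhouette elbow breaks to smaller k.
* The segmentation-noise simulator erodes the left half and dilates the
  right half (vertical split) by a 1 px disk — which half does what is
  arbitrary, so it is fixed and kept consistent across cells.
* Problem sizes in the shipped tests and acceptance script: 2000 cells,
  8 markers, 32 px crops for the end-to-end pipeline; 1500 cells for the
  duplicate-recovery contract; graph clustering exercised at 15 neighbours /
  minimum size 50, proportional to those cell counts.

## Known limitations

* The ME-VAE reconstructs mean intensity more faithfully for markers painted
  over many pixels; nuclear channels (small painted area) show noisier
  mask-mean ranks than cytoplasmic ones at equal training budget.
* The gradient ranking inherits the decoder's biases: a channel the decoder
  ignores scores low even if it carries unique information in principle.
* Selection quality is only ever relative to the pilot dataset's correlation
  structure; a reduced panel does not transfer to a different tissue or
  panel context, and the package makes no claim that it does.
* Exhaustive enumeration is exact but combinatorial; above the budget the
  greedy fallback carries no optimality guarantee.
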