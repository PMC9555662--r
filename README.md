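# panelreduce

Multiplex imaging modalities such as cyclic immunofluorescence (CyCIF) can
stain dozens of protein markers on one tissue section, but every staining
round costs time, reagents and tissue integrity. Many markers are
co-expressed and therefore redundant: their single-cell signal can be
predicted from other markers on the panel. `panelreduce` is an R toolkit for
choosing which markers to keep — an optimally **reduced panel** — and for
quantifying how much of the full panel's information survives when the
withheld markers are imputed computationally. It is aimed at imaging
scientists designing CyCIF/CODEX-style panels and at computational biologists
evaluating marker redundancy in cells × markers intensity data.

## What it does

Given single-cell images (or a cells × markers mean-intensity table) from a
pilot experiment with the full panel:

1. **Panel selection.** Four strategies produce a reduced panel *R* of size
   *n* (the nuclear stain is always forced in, since segmentation needs it):
   - *Correlation-based*: enumerate all candidate panels and maximize
     `score(R) = mean over withheld markers w of max over r in R corr(w, r)`;
   - *Sparse-subspace-based*: fit a zero-diagonal self-expressive coefficient
     matrix `C` minimizing `mean over cells of ||I − C I||² + λ ||C||²/n`
     (each marker's intensity reconstructed from the others), threshold it,
     and pick the panel maximizing interactions to withheld markers minus
     interactions within the panel;
   - *Gradient-based*: rank channels by the mean absolute gradient of a
     full-panel autoencoder's reconstruction loss at each channel's encoding;
   - *Random*: a seeded nested ordering, as a selection baseline.
2. **Imputation.** A multi-encoder variational autoencoder (`mevae()`) — one
   3-layer encoder per reduced-panel channel, concatenated latent space
   (~128 total), one decoder emitting every full-panel channel through a
   sigmoid — is trained with pixelwise binary cross-entropy plus the mean
   per-encoder KL divergence from a unit-Gaussian prior, and imputes the
   full panel's single-cell images from the reduced panel.
3. **Evaluation.** Per-marker Spearman correlation between true and imputed
   mean intensities (withheld and all markers, with across-marker variance),
   per-channel SSIM, and normalized mutual information
   `NMI(U,V) = MI(U,V) / mean(H(U), H(V))` between cluster labels of the
   imputed and true tables (k-means and kNN-graph/Louvain clustering, with
   Hungarian cluster matching and a shuffled-label chance baseline).
4. **Noise context.** Gaussian blur, salt-and-pepper, and
   erode/dilate segmentation perturbation provide technical-noise baselines
   against which imputation error can be judged.

A synthetic-data module (`generate_dataset()`) renders CyCIF-like single-cell
crops — elliptical cells 10–20 px across with nuclear / membrane /
cytoplasmic marker localizations and block-correlated expression planted
across latent cell types — so the whole pipeline is testable without any
external download.

## Worked example

```r
library(panelreduce)

spec  <- synthetic_spec(n_cells = 2000, seed = 1)   # 8 markers, 4 redundancy blocks
ds    <- generate_dataset(spec)
cells <- lapply(ds$cells, function(x) orient_by_mass(align_major_axis(x)))
split <- split_cells(cells, train_fraction = 0.9, seed = 1)

cm    <- correlation_matrix(ds$truth[split$train, ])
panel <- select_panel_corr(cm, n = 5, required = "Hoechst")
panel
#> reduced_panel (correlation, n = 5, score = 0.9162)
#>   panel:    Hoechst, CD3, CD31, CK19, ECad
#>   withheld: LaminB1, PanCK, CD45

model <- mevae(cells[split$train], panel$panel, epochs = 10, seed = 1)
imputed <- impute_full(model, cells[split$test])
report  <- evaluate_panel(ds$truth[split$test, ],
                          mean_intensity_table(imputed), panel,
                          cells_true = cells[split$test],
                          cells_pred = imputed, kmeans_k = 4, seed = 1)
report
#> evaluation_report
#>   panel (5 markers): Hoechst, CD3, CD31, CK19, ECad
#>   Spearman: withheld 0.834 (var 0.0115), all 0.842 (var 0.0079)
#>   SSIM: 0.790
#>   NMI (k-means, k=4): 1.000 (shuffled baseline 0.0156)
```

The selector kept exactly one marker from each planted redundancy block (the
other block member is recoverable from its partner). The report says: ranks
of the imputed mean intensities agree with the truth at Spearman 0.83 for
markers that were never "stained", imputed images resemble the true ones at
SSIM 0.79, and k-means cell populations derived from the imputed table match
the full-panel populations essentially perfectly (NMI 1.0 on the held-out
cells, against a ~0.02 chance level).

A command-line interface wraps the same functions
(`Rscript <pkg>/cli/panelreduce.R simulate|select|evaluate|noise ...`); every
stage is deterministic given its `--seed`.

## Vignette

`vignettes/panel-reduction.Rmd` documents the models, their assumptions, the
synthetic-data design, parameter defaults and known limitations.
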