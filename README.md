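# modfuse

Medical image **modality classification** from images and their captions.

Retrieval systems for medical imaging want to filter results by modality —
CT, MR, PET, nuclear medicine (NM), ultrasound (US), x-ray (XR), graphics
(GX), photographs (PX) — but caption metadata is unreliable. `modfuse`
classifies modality by fusing five visual features with a caption-derived
textual feature:

* gray intensity histogram (256 bins) and quantized joint color histogram
  (k·m·l bins, default 4×4×4);
* block-based gradient-orientation edge histogram (4×4 blocks × 20 bins =
  320 dimensions, magnitude-weighted, per-block normalized);
* block-based local-variance histogram (32 bins over [0, 255²/4]);
* bag of visual words: dense-grid SIFT descriptors (128-dim, unit norm)
  quantized against a k-means codebook, h_c = (1/L) Σ_l δ(c, c(x_l));
* binary keyword histogram over a 90-term vocabulary from the caption.

**Fusion** works at the kernel level. For feature *m* with pairwise
distances S_m (χ² by default; L1/L2 selectable),

    K_m = exp(−S_m / γ_m),   γ_m = mean of S_m over all N² ordered training pairs,
    K   = (1/M) Σ_m K_m

so every feature's normalized distances average to exactly 1 and each
feature contributes equally to the fused kernel ("joint kernel equal
contribution"). A one-vs-one SVM runs on the precomputed fused kernel.
Finally, a **refinement** stage re-classifies samples predicted into an
easily confused modality group ({CT, MR, XR}, {NM, PET}, {GX, PX} by
default) with a group-local classifier whose γ values are recomputed on the
group subset — rescaling that re-expands the weak within-group differences
the global kernel compresses.

## Worked example

Everything below runs on synthetic data generated by the package itself —
no download needed.

```r
library(modfuse)

spec <- demo_synthetic_spec(n_per_class = 20, seed = 3)
generate_dataset(spec, "demo_ds")
man <- load_manifest("demo_ds/manifest.tsv")

cfg <- default_config()
cfg$image_size <- 64L      # images are generated at 64 px
cfg$codebook_size <- 40L

res <- run_fixed_split(man, cfg, n_train_per_class = 12, seed = 5)
res$accuracy_global
#> [1] 100
round(res$confusion, 1)
#>      ct  mr  nm pet  us
#> ct  100   0   0   0   0
#> mr    0 100   0   0   0
#> nm    0   0 100   0   0
#> pet   0   0   0 100   0
#> us    0   0   0   0 100
```

The confusion matrix rows are true classes in percent (each row sums to
100); the diagonal is per-class recall. With five well-separated synthetic
classes the fused pipeline recovers every test label. The interesting
regimes are the engineered confusable pairs:
`demo_synthetic_spec(confusable = "visual")` makes two classes visually
identical (only captions separate them — fusing the textual feature
recovers the pair), and `confusable = "weak"` gives the pair a weak visual
difference with uninformative captions (the refinement stage recovers it).
See the vignette (`vignettes/modality-classification.Rmd`) for the model
details and design choices.

A thin command-line interface over the same functions ships at
`inst/cli/modfuse.R`:

```sh
Rscript inst/cli/modfuse.R simulate --out ds --n-per-class 20 --seed 1
Rscript inst/cli/modfuse.R crossval --manifest ds/manifest.tsv --out results
```

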