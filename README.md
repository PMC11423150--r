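# nldnn

Nucleotide-level deep regression of transcription-factor (TF) binding, with
adversarial cross-species adaptation — implemented end to end in R.

## The problem

Given a genome and a TF's ChIP-seq experiment, predict where and how strongly
the TF binds, from sequence alone. `nldnn` treats this as **nucleotide-level
regression**: a U-shaped encoder–decoder network maps a one-hot encoded
600-bp DNA window `x` to its per-base coverage signal `z ∈ R^600`, trained
with a nucleotide-resolution mean-squared-error loss

    L = (1 / (N·L)) · Σ_i Σ_j (z_ij − ẑ_ij)² + α‖w‖₂²

where `ẑ` is the observed log10(1 + coverage) track, `N` the batch size,
`L` the window length and `w` the network weights. The encoder (three
conv–ELU–maxpool–dropout blocks, a bidirectional GRU, and a pyramid pooling
module) is the **generator**; the decoder (three refinement-residual skip
fusions, three upsample blocks, a linear width-1 head) is the **predictor**.

The **max-coverage bridge** makes the per-base output comparable with
sequence-level classifiers: a window's score is the maximum of its predicted
coverage, evaluated by PR-AUC/ROC-AUC against window labels and by Pearson
correlation against true maxima.

For **cross-species prediction**, a species discriminator `D` is trained on
generator feature maps of source-species binding windows (label 1) versus
target-species windows (label 0),

    min_D  −E[log D(G_s(x_s))] − E[log(1 − D(G_t(x_t)))]

while a target generator `G_t` (initialised from the frozen source generator
`G_s`) is adversarially nudged with the inverted-label loss

    min_{G_t}  −E[log D(G_t(x_t))]

so that target-species features become indistinguishable from source
features; target windows are then predicted by `G_t` composed with the
frozen predictor.

The package also provides: variant-effect scoring `Σ_{i∈D}|v_alt − v_ref|`
and in-silico saturation mutagenesis (4×L effect matrices), causal-SNP
prioritisation within LD groups, binding-region localization (top-1% of
non-overlapping windows by predicted maximum, scored by peak intersection
and by exact-p-value PWM motif scanning), kernel-based motif discovery,
gradient×input attribution, TP/FP/FN site categorisation, and a synthetic
two-species planted-motif data generator so that everything is testable on
one CPU without downloads. All network forward/backward passes are written
in R (conv via compiled im2col + BLAS) and verified against finite
differences.

## Worked example

Train on synthetic species A, evaluate within species and on the
domain-shifted species B, then adapt:

```r
library(nldnn)

rep <- run_experiment(list(mode = "cross_adapted", seed = 1))
round(c(within  = rep$within$prauc,
        cross   = rep$cross$prauc,
        adapted = rep$adapted$prauc), 3)
#>  within   cross adapted
#>   0.973   0.904   0.906
round(rep$within$pearson_max, 4)
#> [1] 0.7794
```

Read: the model recovers within-species binding nearly perfectly (PR-AUC
0.973; predicted window maxima correlate 0.78 with the true maxima), loses
about 0.07 PR-AUC when evaluated on the second species — the
species-private repeat there carries a degenerate motif decoy that draws
false positives — and adversarial adaptation operates on that gap (the
per-run effect at desk scale is small and seed-noisy; see the methods
vignette).

Locate binding regions on a held-out chromosome and check them against the
truth:

```r
seeds <- nldnn:::fan_out_seeds(1)
spec <- synthetic_spec(seed = seeds$data)
ga <- make_genome(spec, "A")
ds <- make_datasets(ga$genome, ga$truth, seed = seeds$train)
tr <- train_nldnn(build_nldnn(desk_config(seed = seeds$model)),
                  ds$train, ds$val, desk_train_config(seed = seeds$train))

scan <- scan_chromosome(tr$model, ga$genome, "chr2")
top <- select_top_regions(scan, 0.01)
intersect_ratio(top, ga$truth$peaks)
#> [1] 1
motif_instance_ratio(top, ga$genome, spec$motif_pwm, 1e-4)
#> [1] 1
```

The held-out chromosome tiles into 166 windows, so the top 1% is a single
window; it overlaps a true peak and contains a significant (exact
p < 1e-4) motif instance.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/nldnn.R synth --seed 1 --species A --out data/
Rscript inst/cli/nldnn.R run --mode cross_adapted --seed 1 --out run1/
```

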