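# stimedit

Gene-expression-guided generation, reconstruction and in-silico editing of
single-cell immunofluorescence images, for researchers working with
imaging-based spatial transcriptomics (CosMx/Xenium-style data: per-cell
transcript counts paired with nuclear-stain and membrane-marker image
crops).

The scientific question the package operationalizes: if a tumor cell
population's expression distribution is shifted to the normal state, do
images generated (or reconstructed) from the edited expression shift
toward normal morphology — smaller nuclei, dimmer membrane marker, lower
distributional distance to real normal cells?

## The core algorithm

Each population *i* is summarized by the scaled uncentered second-moment
matrix of its expression collection G<sub>i</sub> (n<sub>i</sub> × p):

S<sub>i</sub> = (1/n<sub>i</sub>) G<sub>i</sub>ᵀG<sub>i</sub> = O<sub>i</sub> diag(λ<sub>i</sub>) O<sub>i</sub>ᵀ.

Editing population *i* toward population *j* applies the fixed linear map
rowwise:

G<sub>i</sub>′ = G<sub>i</sub> O<sub>i</sub> diag(√(λ<sub>j</sub>/λ<sub>i</sub>)) O<sub>j</sub>ᵀ,

a whitening–recoloring transform that makes the edited second moment equal
the target's exactly (full-rank case).  A leading-eigenvalue mode rescales
only the dominant eigenvalue, and a gene-restriction step confines the edit
to chosen genes (e.g. the HLA-A/B2M-like drivers) while freezing the rest.

Around the edit sit: an expression-conditioned adversarial generator whose
mapping network turns the (standardized) expression plus a binary
normal/tumor label into per-layer style latents; dual-encoder inversion of
the frozen generator for reconstructing and manipulating real crops; and an
evaluation suite — Fréchet distance between image-feature Gaussians (dFID),
PSNR/SSIM, segmented nuclear area and marker level, and per-gene
Mann–Whitney shift tests with Benjamini–Hochberg adjustment.  A synthetic
data module generates CosMx-like fixtures (transcript tables, metadata,
16-bit TIFF tiles) in which driver-gene expression causally controls
nuclear area and marker intensity, so every claim is testable end to end
with known ground truth.

## Worked example

```r
library(stimedit)

## paired synthetic dataset: 2000 normal + 2000 tumor cells, 30-gene panel,
## genes 1-2 drive nuclear area and membrane-marker intensity
ds <- simulate_dataset(sim_default_config(seed = 1))

## edit tumor expression toward the normal distribution
ed <- edit_population(ds, edit_spec("full", source = 1, target = 0))
ed$provenance$scm_residual
#> [1] 2.503659e-15

## the edited driver genes shift significantly toward normal
expression_shift_test(ds$expr[ed$index, 1:2], ed$expr_edited[, 1:2])$stars
#> [1] "****" "****"

## smoke-train the conditional generator (a few minutes on one CPU)
gm <- train_gan(ds, gan_config(p = 30, iters = 2000, ckpt_every = 500, seed = 1))

## generate images from unedited vs edited tumor expression and compare
## both against the real normal population
normal <- ds$images[ds$labels == 0, , , ]
gen_un <- generate_edited(ds$expr[ed$index[1:400], ], 1L, gm, noise_seed = 101)
gen_ed <- generate_edited(ed$expr_edited[1:400, ], 0L, gm, noise_seed = 101)
dfid(gen_ed, normal, seed = 1)$mean   # edited-to-normal: close to normal
#> [1] 0.2856288
dfid(gen_un, normal, seed = 1)$mean   # unedited tumor: far from normal
#> [1] 1.376515

## interpretable cellular features move the same way
colMeans(cellular_features_set(gen_ed[1:150, , , ])[, 2:3])
#> nuclear_area  marker_mean
#>   33.02000000   0.09539609
colMeans(cellular_features_set(gen_un[1:150, , , ])[, 2:3])
#> nuclear_area  marker_mean
#>   86.8200000    0.2941817
```

Editing tumor→normal reduces the dFID to the real normal population by
roughly 5× and moves mean nuclear area and marker intensity from
tumor-like values toward the normal range — the desk-scale analogue of the
editing effect the method is designed to measure.  A pipeline-style
interface (`run_stage("simulate" | "preprocess" | "edit" | "train-gan" |
"train-inversion" | "generate" | "reconstruct" | "evaluate", config)`) and
a thin CLI wrapper (`inst/scripts/stimedit-cli.R`) orchestrate the same
steps with YAML configs and provenance records.

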