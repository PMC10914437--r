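---
title: "Expression-guided editing of single-cell immunofluorescence images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-guided editing of single-cell immunofluorescence images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimedit)
```

## The problem

Imaging-based spatial transcriptomics platforms (CosMx, Xenium) measure, for
each detected cell, both a high-plex gene expression vector (transcript
counts with spatial positions) and a multi-channel immunofluorescence image
— typically a nuclear stain (DAPI) and a membrane marker (CD298/B2M).  In
liver cancer material, tumor cells differ from normal hepatocytes both in
expression (e.g. upregulated HLA-A/B2M) and in morphology (larger nuclei,
brighter membrane marker).  `stimedit` treats the expression vector as the
"text" modality of a conditional generative model of cell images, and asks:
if we algorithmically shift a population's expression distribution from the
tumor to the normal state (or vice versa), do images generated or
reconstructed from the edited expression shift accordingly?

The package has three computational layers:

1. **Expression editing** — a closed-form covariance-matching transform
   between two cell populations.
2. **Generation and inversion** — an expression-conditioned adversarial
   generator plus dual-encoder inversion for real-image reconstruction and
   manipulation.
3. **Evaluation** — Fréchet distance between image-feature Gaussians
   (dFID), PSNR/SSIM, interpretable cellular features, and per-gene
   expression-shift tests.

A synthetic-data module provides paired fixtures with known ground truth so
the whole pipeline is testable without any external download.

## The covariance-matching edit

For population $i \in \{0, 1\}$ with expression matrix
$G_i \in \mathbb{R}^{n_i \times p}$, the population's distribution is
summarized by its scaled, *uncentered* second-moment matrix (referred to in
the field as the sample covariance matrix of the expression collection):

$$ S_i = \tfrac{1}{n_i} G_i^\top G_i = O_i \,\mathrm{diag}(\lambda_i)\, O_i^\top,$$

with eigenvalues sorted nonincreasing.  Editing population $i$ toward
population $j$ applies the fixed linear map rowwise:

$$ G_i' = G_i \, O_i \,\mathrm{diag}\!\big(\sqrt{\lambda_j / \lambda_i}\big)\, O_j^\top. $$

This is a whitening–recoloring transform: rotate into the source eigenbasis,
rescale each direction from the source to the target spectrum, rotate into
the target eigenbasis.  In the full-rank case it satisfies
$\tfrac{1}{n_i} G_i'^\top G_i' = S_j$ *exactly*, which is the module's
acceptance surface (tests require relative Frobenius error below $10^{-8}$).
The square root in the scaling and the transposed final rotation are forced
by this postcondition.  Directions with numerically zero source eigenvalue
receive scale 0 (the pseudo-inverse rule); an all-zero source population is
an error.

Two practical variants:

* **Leading mode** keeps the full rotation sandwich but rescales only the
  leading eigenvalue, $\mathrm{diag}(\sqrt{\lambda_j[1]/\lambda_i[1]}, 1,
  \dots, 1)$ — smaller eigenvalues fluctuate under sampling, and the leading
  direction dominates the contrast between the populations.  When the two
  eigenbases coincide this perturbs the second moment by exactly
  $|\lambda_j[1] - \lambda_i[1]|$ in Frobenius norm, which the tests verify
  on constructed inputs.
* **Gene restriction** (`edit_genes`) copies the edited values only for a
  chosen gene set and freezes the complement at its original values,
  narrowing the edit to genes of interest (e.g. the drivers).  The
  restricted edit no longer matches the target moment exactly; the achieved
  residual is recorded in the provenance.

Edited matrices are real-valued and may contain negative entries; clipping
would break the exact-matching property, and the generator's conditioning
pathway accepts real vectors (see standardization below).  Self-editing
(identical source and target decompositions) short-circuits to the bit-exact
identity rather than multiplying through $O O^\top \approx I$.

Ties in degenerate spectra are handled deterministically: the symmetric
eigensolver's output is post-processed with a sign convention (each
eigenvector's largest-magnitude entry is positive), making decompositions
reproducible across calls.

## The synthetic data model

`sim_config()` defines two populations whose latent expression is mean-zero
Gaussian with prescribed second-moment matrices, passed through an
elementwise rectification $g = \max(z, 0)$.  The rectified link has exact
closed-form moments (for standardized coordinates with correlation $\rho$,
$E[z_a^+ z_b^+] = s_a s_b (\sqrt{1-\rho^2} + \rho(\pi/2 + \arcsin\rho)) /
(2\pi)$, an arcsine-law identity), so moment-convergence tests compare the
empirical second moment against an analytic oracle rather than a simulation.
The pipeline default additionally rounds to integer counts
(`"rectified-counts"`): transcript tables need integer multiplicities for
the exact crop-and-sum round trip; the rounding perturbs the moments by a
small, bounded amount and is not used in the moment tests.  The empirical
count distribution of real panels is not modeled — any heavy-tailed choice
would be defensible, and nothing downstream depends on it beyond the
second-moment structure.

The default study conditions (chosen once, used everywhere): a 30-gene
panel; genes 1–2 are drivers with latent standard deviation 2 (normal) vs 6
(tumor) and positive driver–driver correlation; 2000 cells per population;
32×32 two-channel crops.  Rendering couples phenotype causally to the
driver-gene sum $s$:

* nucleus: a centered axis-aligned ellipse with area
  $18\,s + 25$ pixels² (±8% jitter, eccentricity jitter 0.85–1.18),
  clamped to $[9, 0.2\,H^2]$;
* marker: an elliptical membrane ring at 1.1–1.6× the nucleus ellipse with
  mean intensity $\min(0.14\,s, 1)$;
* i.i.d. Gaussian pixel noise (sd 0.02), values clipped to $[0,1]$ and
  snapped to the 16-bit grid so TIFF round trips are bit-exact.

Under these conditions the normal/tumor populations differ in driver
expression (roughly 0.8 vs 2.4 mean counts per driver), nuclear area
(≈55 vs ≈110 px²) and marker level (≈0.23 vs ≈0.67) — a deliberately strong,
desk-scale cartoon of the real normal/HCC contrast.  What passing tests show
is that the *machinery* (editing, conditioning, metrics) behaves correctly
on data whose generative process is known; they do not show that a model
trained at this scale captures real CosMx image statistics, optics,
segmentation errors, or 1000-plex count distributions, all of which are out
of scope.

Fixtures are written in a CosMx-like dialect: a transcript table
(`fov,cell_ID,target,x_global_px,y_global_px`), per-cell metadata, one
multi-page 16-bit TIFF per slide, and a YAML manifest with checksums and the
intensity rescale.  Transcripts are placed on the integer grid inside a
disc (radius 10) around each centroid, strictly inside the cell's crop
window, so crop-and-sum recovers the simulated counts exactly.  Coordinates
are 0-based pixel centers; crop windows are half-open
$[c - \lfloor H/2\rfloor, c + \lceil H/2\rceil)$, which makes boundary
behavior exactly testable.  Unassigned transcripts (empty `cell_ID`) are
dropped at load time.  A centroid too close to the border is clamped so the
window fits, and the cell is flagged.

## The conditional generator

No deep-learning framework is assumed: the networks are dense,
style-modulated multilayer perceptrons with hand-written forward and reverse
passes, verified against finite differences in the test suite.  This is a
deliberate desk-scale realization of a style-based conditional generator:

* **Mapping network.**  Expression is transformed by a signed
  $\log(1+|x|)$ and per-gene z-scored with statistics stored at training
  time (robust to the negative values edited vectors can contain), a learned
  class embedding is added, and a 2-layer MLP produces the style latent $w$.
  Expression and class are the sole inputs — there is no separate random
  latent; per-layer noise injection is the only stochasticity, and it is a
  pure function of a caller-supplied seed.
* **Synthesis network.**  A stack of leaky-ReLU layers, each receiving the
  style through its own learned affine injection (`a_l = h_{l-1} W_l + w A_l
  + b_l + s_l ε`), with a final tanh to (−1, 1).  The number of style slots
  scales with image size; inversion encoders later perturb these slots
  individually.  The output bias is initialized at the dataset mean image
  (in pre-tanh units), so early training learns modulation around the mean
  cell rather than the mean itself.
* **Discriminator.**  A leaky-ReLU MLP with a projection head:
  `logit = h·v + b + h·e_c`.  Besides the standard real/fake terms of the
  non-saturating logistic loss, the discriminator also sees real images
  paired with the *wrong* label as fakes (a matching-aware term, weight
  `lambda_mismatch`).  With only two classes and short training schedules,
  the plain projection loss can leave the class embedding unused for a long
  time; the mismatch term forces label usage from the start and was the
  difference between conditioning emerging in minutes versus not at all at
  desk scale.

Regularization follows the style-GAN recipe: lazy R1 (gradient penalty on
real samples, every 16 discriminator steps) and lazy path-length
regularization (every 8 generator steps).  Both penalties need second-order
gradients; for piecewise-linear activations the double-backprop is exact
almost everywhere and is implemented in closed form (and finite-difference
tested).  For the path penalty the curvature of the output tanh is dropped
(the activation linearization is frozen), a standard Gauss–Newton-style
simplification; the penalty *value* is always exact.  Two numerical choices
matter at this scale and are worth recording:

* the path-length running mean is warm-started at the first observed path
  length instead of 0 — started at 0, the penalty actively shrinks the
  style Jacobian toward zero and the generator learns to ignore its
  conditioning;
* the contraction noise is scaled by $1/\sqrt{HWC}$ so the path length is a
  pixel average, keeping the regularizer's strength comparable across image
  sizes (and to its usual implementation); with unit-variance pixel-sum
  noise the same weight is orders of magnitude too strong.

Defaults: $\lambda_{R1} = 1$, $\lambda_{path} = 2$, mismatch weight 1,
Adam(lr $2\times10^{-3}$, $\beta_1 = 0$, $\beta_2 = 0.99$), batch 16.  The
desk-scale schedule (a few thousand iterations, minutes on one CPU) is the
tested profile; a `profile = "full"` preset records the full-scale schedule
(800k iterations, batch 16) used for real data but is not exercised here.
Model selection over checkpoints minimizes dFID against the training images,
computed with the toy feature extractor (below).

When generating from edited expression, the class label fed to the model is
the *target* population's label: the edit makes the population statistically
a member of the target class, and the label is part of that description.
(The alternative — keeping the source label — is one argument away.)

## Inversion

Two encoders invert the frozen generator: a global encoder $E_c$ (one
bounded latent term, the editability pathway, also the contrastive
embedding network) and a per-layer offset encoder $E_p$ (reconstruction
pathway).  The final latent is additive:
`style_l = mapping(expr, c) + tanh-bounded global + tanh-bounded offset_l`.
Additive fusion is the minimal scheme that keeps expression substitution
well-defined at inference: replacing the mapping base with an edited
expression's base while keeping the image-derived terms manipulates the
reconstruction.  With zero encoder outputs the latent equals the mapping
base exactly, and reconstruction with the original expression is bit-exactly
deterministic (noise is disabled during inversion).

The objective is a weighted sum of an InfoNCE contrastive term between
input and reconstruction embeddings (queries from the current encoder on
reconstructions, keys from a momentum copy on inputs; temperature 0.07),
mean-squared pixel error, and a perceptual distance computed on the
activations of a small *fixed random-weight* convolutional stack.  Random
convolutional features are a valid (deterministic, architecture-sensitive)
perceptual metric for testing; externally trained feature networks can be
plugged in.  Weights default to 0.5 / 1.0 / 0.8.  PSNR and SSIM on a
held-out split (10%) are logged at checkpoint cadence and the best-SSIM
checkpoint is returned.

## Evaluation metrics

* **dFID**: features are extracted per image, summarized as a Gaussian
  (mean, covariance), and two collections are compared by the squared
  Fréchet distance $\|\mu_1-\mu_2\|^2 + \mathrm{Tr}(\Sigma_1 + \Sigma_2 -
  2(\Sigma_1\Sigma_2)^{1/2})$.  The matrix square root uses the symmetrized
  $\sqrt{\Sigma_1}\,\Sigma_2\sqrt{\Sigma_1}$ form with clipping of small
  negative eigenvalues.  The computation is repeated (default 4×) on random
  subsamples, reporting mean ± sd.  The default extractor is a fixed-seed
  random strided convolutional stack with global average pooling (64-D) —
  hardware-independent and sensitive to the fixture's morphology; an
  Inception-style network is a pluggable alternative, and absolute dFID
  values are not comparable across extractors.
* **PSNR / SSIM**: standard definitions; SSIM uses an 11×11 Gaussian window
  (σ = 1.5), $k_1 = 0.01$, $k_2 = 0.03$, channels averaged, and is verified
  against an independently coded textbook implementation.
* **Cellular features**: nuclear area from a pluggable segmenter (built-in
  fallback: Otsu threshold on the nuclear channel, connected components,
  centermost component) and marker level as the mean marker intensity over
  a 3-pixel dilation ring around the nucleus mask — the membrane-marker
  convention.  An empty mask yields area 0, the marker averaged over the
  whole crop, and a flag.
* **Expression shift**: two-sided Mann–Whitney U per gene with
  Benjamini–Hochberg adjustment across genes and conventional stars
  (`****` ≤ 1e−4).

## Problem sizes

Tests and the acceptance script run at desk scale by the package's own
choice of study conditions: 2000 cells per population for editing and
training experiments, 500 per population for distributional properties,
60 per population for exact round trips; generator smoke training uses 2500
iterations at 32×32 and inversion 500 iterations.  These sizes make the
directional editing-effect experiments decisive (the effects are large by
construction) while the whole suite remains a matter of minutes.

## Known limitations

* The generator and encoders are dense networks at 32×32; they demonstrate
  the mechanism, not photorealism, and absolute metric values do not
  transfer to full-scale convolutional models on real data.
* The covariance-matching edit aligns second moments, not full
  distributions, and provides no per-cell correspondence — by design.
* The classical segmenter underestimates areas on blurry generated images;
  comparisons are therefore always made between conditions quantified the
  same way.
* Editing with gene restriction breaks exact moment matching; the residual
  is reported, not hidden.
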