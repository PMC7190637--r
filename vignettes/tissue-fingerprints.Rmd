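---
title: "Tissue fingerprints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue fingerprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tissuefp` implements patient-identity pretraining for histology features.
A convolutional network is trained to answer a deliberately clinical-label-free
question: *which tissue core did this patch come from?* Tissue microarray
(TMA) cores are prepared to a fixed geometry (1600 x 1600 px at 0.5 um/px),
split into left and right halves, and the network learns to map 224 x 224
patches from the **left** halves to their core index. The 512-dimensional (for
the reference residual backbone; configurable for the desk-scale backbone)
feature vector from the final global-average-pooled layer — taken immediately
*before* the identity head — is the **tissue fingerprint**. Generalisation is
monitored as core-index accuracy on patches from the unseen **right** halves,
and training stops when that accuracy plateaus.

Because serial sections of one TMA stained at two sites differ markedly in
color ("style") while sharing morphology, identity training alone tends to
learn stain shortcuts. The composite loss counters this. For a pair of
renderings of the same core in two styles, with shared identity label $y$,

$$\mathrm{loss} = \mathrm{CE}(c_1, y) + \mathrm{CE}(c_2, y)
  + \gamma\, d^2_{FP}(f_1, f_2),$$

where $\mathrm{CE}$ is softmax cross entropy over core indices and

$$d^2_{FP} = \left\lVert \frac{f_1}{\lVert f_1\rVert + \epsilon}
  - \frac{f_2}{\lVert f_2\rVert + \epsilon} \right\rVert^2 \in [0, 4].$$

The distance term pulls the two styles' fingerprints of one core together;
$\gamma = 0$ recovers plain identity training and is the matched-budget
baseline everywhere we compare ("plain" vs "style_paired" modes).

**Matching game.** Quality is evaluated by matching: compute fingerprints for
left halves rendered in one style and right halves in the other, assign each
left half its nearest right half (Euclidean; each left item independently, no
bijection constraint; ties break to the lowest core index), and score the
fraction of cores matched to themselves. Chance is $1/n$ cores. A
patient-pooled accuracy averages each patient's half fingerprints
(normalize, mean, re-normalize) before matching, which rescues
within-patient core swaps.

**Marker prediction.** Fingerprints are reused downstream: whole-slide-like
images are tiled into non-overlapping 112 um foreground squares (resampled to
224 px), 120 patches per patient form a bag, and a small head
(D x 8 linear, ReLU, 8 x 1 linear, tanh) maps each patch fingerprint to a
score in $(-1, 1)$. The bag score is the mean patch score and is regressed
onto the patient's clinical marker label ($\pm 1$) with squared error —
a mean-pooling multiple-instance rule. We state this rule as the package's
interpretation: several MIL variants exist, and mean pooling plus MSE on the
tanh output is the simplest one consistent with averaging patch predictions
into a patient score at inference time. Evaluation is 5-fold label-stratified
cross-validation; in each fold three groups train, one (the "overfitting
group") is used only to monitor patient-level AUC and early-stop (best
weights kept), and one is tested. AUC is the Mann-Whitney rank statistic with
tie correction.

## The synthetic cohort generator

Real TMA scans and clinical cohorts cannot ship with a package, so `synthgen`
produces cohorts whose *statistical structure* matches what the method
assumes, at sizes a CPU can process:

- **Patient phenotype.** Each patient draws a gland fraction
  $g \sim U(0.05, 0.95)$, nuclear density $d \sim U(0.3, 0.9)$ (nuclei per
  100 px$^2$), nucleus radius $r \sim U(3, 7)$ px, stromal texture wavelength
  $w \sim U(8, 32)$ px and anisotropy $a \sim U(0, 1)$. Every core of a
  patient is an independent render from these parameters, so cores share
  texture statistics but no pixels — exactly the property identity training
  exploits.
- **Morphology and style are separated.** A core is a two-channel raster
  (nuclear, cytoplasm); color comes from a parametric site style
  (hematoxylin/eosin/background RGB, gamma, brightness, optional hue jitter)
  via a convex stain composition. The two built-in styles ("siteA", "siteB")
  differ by ~40 gray levels on average — the same morphology in two
  colorations, standing in for restained serial sections or GAN-restyled
  pairs. Restyling inverts the (known) composition and re-renders, so
  morphology is preserved by construction; externally restyled images can be
  supplied from a directory instead.
- **Marker labels couple to texture.** $P(m = +1 \mid g) =
  \operatorname{logit}^{-1}(k (g - 0.5))$ with $k = 16$ by default. At this
  coupling the intrinsic Bernoulli noise (disagreement with the threshold
  rule $\operatorname{sign}(g - 0.5)$) is about 10%, and logistic regression
  of $m$ on the true $g$ reaches AUC $\approx 0.96$ at $n = 200$ — a strong
  but noisy signal, recoverable but not trivial. The sigmoid sampling itself
  is the label noise; no extra flips are applied.
- **Whole slides.** A slide is a mosaic of background, epithelium, stroma and
  fat with a ground-truth label map. Only epithelium is rendered from the
  patient's phenotype, and with the *same recipe as the cores* — gland blobs
  occupying fraction $g$ of the epithelial area, nuclei following $d$ and
  $r$ — so core-trained fingerprints transfer to slides; stroma and fat use
  fixed, patient-independent parameters (fat is a few large pale lobules
  with a stained interstitial web, big enough that whole tiles are
  fat-majority). Marker signal therefore lives in epithelial patches only,
  which is what the tissue-type-restricted AUC analysis probes.

What the generator does **not** emulate: realistic H&E appearance (no optical
blur, chromatic noise, pen marks, folds), nucleus instance ground truth,
scanner compression, or GAN-style transfer artifacts. Tests passing on this
cohort show the machinery is correct and the statistical mechanisms work;
they do not certify accuracy on real slides.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| $\gamma$ | 0.5 | — | weight of the style-invariance term |
| $\epsilon$ | 1e-6 | — | norm stabiliser, applied to each norm separately |
| marker coupling $k$ | 16 | — | ~10% intrinsic label noise (see above) |
| core geometry | 1600 px @ 0.5 um/px | — | ~800 um core square |
| patch | 224 px | px | network input |
| half-aggregation stride | 112 | px | 50% overlap balances coverage and cost |
| identity-heatmap stride | 45 | px | 80% linear overlap, round(0.2 x 224) |
| monitor patches per half | 8 | — | right-half early-stopping estimate |
| bag size K | 120 | patches | patient bag for marker prediction |
| foreground rule | saturation Otsu at 8x, >= 50% | — | "gross" segmentation made concrete |
| MIL batch | 8 bags, Adam 3e-3 | — | head training (3 restarts, scores averaged) |

Augmentation applies, in order, a right-angle rotation (interpolation-free),
optional mirror, multiplicative (contrast) and additive (brightness) jitter,
then optional grayscale conversion. Whether identity training should see
color or grayscale input is genuinely ambiguous in practice — color carries
the style signal, grayscale partially normalises it away — so it is a
configuration flag (`augment_config(grayscale = )`), defaulting to grayscale.
The **dual-style experiments in this package run in color**: the point of the
style-paired loss is to remove style sensitivity that is present at the
input, and grayscale conversion would remove much of it beforehand, muddying
the comparison. (At desk scale we also observed that the small backbone can
collapse its fingerprints under the paired loss on grayscale input, where
the two styles are nearly indistinguishable to begin with.)

## Numerical choices

- **Backbones.** The reference profile is the standard 34-layer residual
  network (512-d pooled features), provided forward-complete behind the same
  contract. Training at desk scale uses the "tiny" profile: a 4x4
  average-pool stem followed by three conv blocks (3x3 convolution, batch
  normalization, ReLU, 2x2 max pool; 16/32/D channels), global average
  pooling (the fingerprint, default D = 32; the style experiments use
  D = 64) and a linear identity head. Inputs are mapped from `[0, 1]` to
  `[-1, 1]` ("center" mode), which preserves the between-style color and
  brightness differences at the input — batch normalization provides the
  conditioning, and style invariance is left to the loss, where it belongs.
  (A per-patch "standardize" mode exists; it largely removes global stain
  differences before the network sees them, which both weakens what the
  invariance experiments measure and, at desk scale, destabilised training
  without batch norm's per-channel control.) Convolution is im2col + GEMM
  on BLAS; all gradients, including through batch normalization, are exact
  (verified against numerical differentiation in the tests).
- **Optimiser.** Adam under a one-cycle schedule: linear warmup over the
  first 10% of steps to the peak rate (3e-3 for the tiny profile), cosine
  decay to a tenth of it. Batches are 8 core pairs sampled without
  replacement; the identity head starts at zero so early gradients reflect
  the features, not random head noise. The weights of the last 40% of
  steps are averaged (stochastic weight averaging), which damps the
  run-to-run noise of small-batch training. The plateau rule is patience
  10 monitor rounds at min_delta 0.002 unless configured otherwise.
- **Style pairing.** Each optimisation step samples one patch location per
  core and renders it in two styles (cycled among the registered styles);
  the pair shares its rotation/flip, jitter is independent. Left halves are
  pre-rendered once per style into an 8-bit cache, since training touches
  them thousands of times.
- **Desk-scale problem sizes** (chosen once as the package's study
  conditions): style experiments use 32 patients x 2 cores at 512 px
  (the smallest geometry with meaningful patch variety: halves are
  512 x 256), 350 optimisation steps at batch 8; half fingerprints there
  aggregate patches at stride 56, which restores the patch count per half
  (6) that the default stride 112 was designed to give on full-size
  1600-px halves. Marker recovery uses 100 patients with 1280-px slides,
  bags of 120 sampled (with replacement, since such a slide yields only
  ~20-25 foreground tiles) from the tiling, and the fingerprinter trained
  on the TMA cohort — mirroring the intended workflow of pretraining on
  cores and transferring to slides. Each cross-validation fold trains
  three independently initialised heads and averages their patient
  scores; the small-bag regime makes single head fits noisy, and score
  averaging is the usual remedy.
- **Style-invariance metric.** The inter-style distance is measured on
  *patch* fingerprints at matched tiling positions of the held-out halves —
  the same quantity the paired loss penalises. Measuring it on per-half
  aggregated fingerprints instead would reward undertrained features: a
  model with hardly any signal produces aggregates that are close across
  styles for the wrong reason.
- **tSNE.** The embedding uses an exact (dense) tSNE implementation:
  bisection-tuned per-point precisions at the target perplexity, symmetrized
  affinities, early exaggeration 4 for 100 iterations, momentum 0.5/0.8,
  500 iterations. Adequate for a few thousand fingerprints; not Barnes-Hut.
- **Ties and conventions.** 0-based, half-open pixel coordinates in
  (row, col) order everywhere; the left half is columns [0, W/2). Nearest
  neighbour ties break to the lowest right core index. "Normalized Euclidean
  distance" in similarity maps means distance between unit-norm fingerprints
  divided by 2, so similarity $= 1 - d/2 \in [0, 1]$.
- **Degenerate inputs.** Constant halves collapse every patch fingerprint to
  one point (aggregate = that point, unit-normalized); empty patch lists
  produce 0 x D matrices; all-background slides tile to an empty list with a
  warning; single-class groups make AUC undefined and raise a fold error
  (or skip the fold with a warning inside cross-validation).

## Known limitations

- The tiny backbone at desk scale reaches a few times chance on cross-style
  matching within minutes of CPU time; absolute accuracies are not
  comparable to a residual network trained for hours on a GPU over
  thousands of real cores. All comparative claims in the tests are
  *orderings* (paired vs plain, epithelium vs fat) or multiples of chance,
  not absolute targets from real cohorts.
- GAN-based neural restyling is out of scope; the parametric renderer
  plus the file-backed twin directory covers the interface.
- The tissue-type segmenter for real slides is out of scope; masks are
  accepted as input, and the generator provides ground-truth masks.
- Her2-like labels couple to nuclear density in the generator; no claim of
  biological fidelity is made for that choice — it simply provides a second,
  independent texture-label channel.
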