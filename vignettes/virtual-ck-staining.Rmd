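---
title: "Virtual cytokeratin staining and dTSR scoring: methods and design"
author: "virtualCK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual cytokeratin staining and dTSR scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualCK)
```

## The problem

The tumor–stroma ratio (TSR) — the share of stroma within a tumor region —
is a prognostic marker in gastric carcinoma, but its visual estimation on
H&E slides suffers from intra- and inter-observer variability. Cytokeratin
(CK) immunohistochemistry marks epithelial tumor cells objectively, yet
routine diagnostics rarely includes a CK stain. `virtualCK` implements a
computational alternative: a conditional adversarial network, trained on
re-stained H&E/CK pairs of the same sections, renders a *virtual* CK image
from H&E input, and a digital TSR (dTSR) is then computed from binarized
tissue and tumor masks over pathologist-selected hotspots.

The pipeline has five stages, each an exported module:

1. **Color deconvolution** (`rgbToStain()`, `stainToRgb()`) between RGB
   and the hematoxylin–eosin–DAB (HED) stain space under Beer–Lambert
   absorption.
2. **Registration** (`estimateGlobalShift()`, `estimateLocalShifts()`)
   of the re-stained pair by FFT cross-correlation of binarized stain
   channels, global then per local region.
3. **Patch curation** (`tilePairs()`, `assembleTrainingSet()`) into
   256×256 training pairs with white-background removal and
   rebalancing of little-dyed patches.
4. **Virtual staining** (`trainVirtualStain()`, `generatorForward()`,
   `generateAndStitch()`): a U-Net generator against a PatchGAN
   discriminator, with an added HED-space L1 loss.
5. **dTSR scoring and evaluation** (`scoreWSI()`, `cohenKappa()`,
   `rocAuc()`): stroma percentage per hotspot, slide-level
   dichotomization, and agreement statistics against visual labels.

## Stain model

A brightfield pixel value $v_c \in [0,255]$ in channel $c$ relates to
stain concentrations $s = (s_H, s_E, s_{DAB})$ through Beer–Lambert
absorption: $v_c = 255 \cdot 10^{-(s \cdot M)_c}$, where the rows of the
3×3 matrix $M$ are the unit optical-density vectors of the stains
(Ruifrok–Johnston values by default, overridable through
`stainBasis()`). Deconvolution inverts this:
$OD_c = -\log_{10}((v_c + \varepsilon)/255)$, $s = OD \cdot M^{-1}$.

Numerical choices:

* $\varepsilon = 1$ keeps the logarithm finite at $v = 0$; the price is a
  small downward bias in very dark pixels. With 8-bit quantization the
  round trip concentration error stays below 0.02 OD while all rendered
  channels remain ≥ 50; darker, heavily mixed pixels can deviate more,
  which is inherent to any fixed-offset log transform.
* Optical densities below zero (pixels brighter than the blank) are
  unphysical and treated as zero; negative unmixed concentrations are
  clamped to zero.
* 8-bit stain channels (`stainChannel8bit()`) map concentration linearly
  with saturation at `cMax = 1`, so the conventional DAB threshold of 80
  corresponds to ≈ 0.314 OD. The source method states its thresholds on
  the 8-bit scale without fixing the mapping; `cMax` is therefore an
  explicit configuration constant.
* The HED-space loss inside training uses a *smooth* variant of the same
  transform — no rounding, no clamping — so gradients flow; the scoring
  path always uses the quantized version. This divergence is deliberate
  and documented here.

## Registration

Re-stained sections are physically the same tissue, so misalignment is an
integer translation (no elastic deformation is modelled — see
Limitations). Both slides are reduced to one informative stain channel:
eosin for H&E, DAB for CK. Channels are binarized by locally adaptive
thresholding and cleaned by removing 8-connected components with area
strictly below `minArea` (default 200). The shift maximizing the
zero-padded linear cross-correlation of the two masks — computed via FFT,
ties broken by the lexicographically smallest `(drow, dcol)` — is the
estimate. Global estimation runs at 32× downsampling (block average) and
multiplies the result back to level 0; local refinement tiles each
10,240-pixel region into 1,024-pixel patches, estimates per-patch
residual shifts, discards outliers, and adds the rounded inlier mean to
the global shift.

Design decisions worth knowing:

* **Threshold direction.** The adaptive rule marks a pixel foreground iff
  its value exceeds the Gaussian-weighted local mean (window
  `blockSize = 151`, $\sigma = (\text{block}-1)/6$) *plus* the offset
  (default 10). Reading the offset with the opposite sign would make
  every uniform area — including empty background — foreground, which
  cannot drive a meaningful correlation; the package therefore interprets
  the offset as a required local contrast.
* **Shift convention.** A `ShiftVector` records the displacement of CK
  content relative to H&E; applying its negative aligns CK onto H&E.
* **Outlier rule.** A patch shift is an outlier if either component
  deviates from the per-region component median by more than 3× the raw
  median absolute deviation (no normality constant), with the MAD floored
  at 2 px so a perfectly consistent region does not reject the benign
  ±1 px jitter. The underlying method reports outlier removal without
  specifying a rule; this one is the package's choice.
* Patches that are near-white in H&E (white-background rule) or carry no
  DAB signal in CK (little-dyed rule) are skipped: they cannot constrain
  the stain-channel correlation. Regions with no usable patch inherit the
  global shift.
* Coordinates are 0-based with half-open tiles; partial edge regions are
  processed at their natural size.

## Patch curation

Aligned region pairs are tiled into non-overlapping 256×256 patches
(partial tiles dropped). Two filters follow, with strict inequalities at
every stated constant:

* **White background**: more than 95% of grayscale pixels above 220
  (grayscale = ITU-R 601 luma, `0.299R + 0.587G + 0.114B`, rounded).
  These pairs are removed outright.
* **Little-dyed**: fewer than 5% of CK pixels above 80 on the 8-bit DAB
  channel. Such pairs teach the translator little about structure and are
  uniformly subsampled (seeded, without replacement) to a configurable
  10% share of the final set — interpreted as 10% of the *final* set,
  i.e. `k = round(0.1 · n_informative / 0.9)` kept.

## The conditional adversarial translator

The generator $G$ is a U-Net: `depth` stride-2 4×4 convolutions
(LeakyReLU 0.2, instance normalization except on the first layer and on
1×1 bottlenecks) mirrored by transposed convolutions with symmetric skip
concatenations and a tanh output; dropout is deliberately absent, so
inference is deterministic — a property the scoring stage relies on and
the test suite asserts bit-exactly. The discriminator $D$ is a PatchGAN
over the channel-concatenated (H&E, CK) pair: a grid of patch logits
rather than one global score; with the default three stride-2 layers its
receptive field is about 70×70.

The generator objective combines three terms:

$$G^* = \arg\min_G \max_D \; \mathcal{L}_{cGAN}(G, D)
  + \lambda_1 \, \mathcal{L}_{L1}^{RGB}(G)
  + \lambda_2 \, \mathcal{L}_{L1}^{HED}(G),$$

with $\mathcal{L}_{cGAN} = \mathbb{E}[\log D(x,y)] +
\mathbb{E}[\log(1 - D(x, G(x)))]$, and the two L1 terms the mean absolute
error between real and generated CK in RGB (on the [0,1] scale) and after
the smooth HED transform (raw OD units). Defaults: $\lambda_1 = 10$,
$\lambda_2 = 0.9$, batch size 1, Adam (lr $2\cdot10^{-4}$,
$\beta_1 = 0.5$, $\beta_2 = 0.999$), 200 epochs, weights initialized
N(0, 0.02).

Further choices:

* L1 terms use *mean* (not sum) reduction, so the $\lambda$ values are
  resolution-independent.
* The generator maximizes $\log D(x, G(x))$ (the standard non-saturating
  form) rather than minimizing $\log(1-D)$; the adversarial weight is
  fixed at 1.
* At batch size 1 the normalization layers are instance normalization by
  construction.
* The engine is a self-contained, pure-R implementation: im2col
  convolutions, transposed convolutions as the conv adjoint, manual
  backpropagation and Adam. Every layer is verified against
  finite-difference gradients in development; the shipped tests verify
  loss arithmetic against independent oracles and training behaviour on
  phantoms. A reduced architecture (`tile = 64`, `depth = 3`, 8 base
  filters, 2 discriminator layers) makes CPU-scale experiments practical;
  the full 256/depth-8/64-filter configuration is the default for real
  training.

At inference, regions are tiled, each tile is translated independently,
and outputs are placed back at their origins without blending; uncovered
right/bottom margins are filled white and flagged.

## dTSR scoring

For each hotspot polygon (even–odd fill over pixel centers, boundary
pixels included), the H&E crop is masked to the polygon, a virtual CK
crop is generated, and three masks follow: tissue = grayscale < 200,
tumor = DAB > 80 *restricted to tissue* (so tumor + stroma = tissue
exactly), stroma = tissue minus tumor. Then

$$\mathrm{dTSR} = \frac{\text{stroma area}}
  {\text{tumor area} + \text{stroma area}} \times 100\%.$$

The slide score is the unweighted mean over hotspots and the class is
`dTSR-high` iff the mean is *strictly* above the cut-off (default 65%,
the value at which dichotomized agreement with visual scoring peaks).
Hotspots without tissue are skipped; a slide whose hotspots are all
tissue-free is an error, not a zero.

## Agreement evaluation

`buildContingency()` cross-tabulates visual (vTSR) against digital
(dTSR) classes; `cohenKappa()` implements the standard
$\kappa = (p_o - p_e)/(1 - p_e)$; `rocAuc()` computes the rank-sum AUC
with half credit for ties (identical to the trapezoidal area under the
empirical curve), with vTSR-high as the positive class and continuous
dTSR percentages as scores. Report percentages are rounded half-up to
two decimals, the convention of published cross-tables.

## The phantom generator

Because slide images of this kind are large, proprietary and rarely
deposited, the package ships a first-class synthetic module. A phantom
pair is rendered through the package's own Beer–Lambert forward model
from piecewise-constant stain levels over known geometry: a rectangular
tissue region, tumor as a row band (pixel-exact stroma fraction) or as
discs, hard edges (no anti-aliasing) so area accounting is exact, and a
seeded multi-scale pattern of "cell" dots inside tumor rendered into
*both* rasters at identical positions — the analogue of the shared
cellular texture that registration keys on in a genuinely re-stained
section. Gaussian noise (σ = 3 on the 8-bit scale, clamped) is added
after rendering; truth masks record the pre-noise geometry. Default
levels: hematoxylin 0.6 (tumor) / 0.25 (stroma), eosin 0.5 in both
(eosin contrast comes from the cellular texture, as in real tissue,
rather than from a region-level offset — a uniform offset would also
create spurious region-boundary correlations that no real section
exhibits), DAB 0.45–0.9 over tumor, counterstain 0.15.

What the phantoms do **not** emulate: realistic histological texture,
scanner artifacts, stain variability between laboratories, non-rigid
deformation, and ambiguous cell morphology. Passing phantom tests
therefore demonstrates that the machinery is correct — registration
recovers planted shifts exactly, scoring recovers known stroma fractions
within 2 points, training reduces its reconstruction loss — not that the
trained translator reaches any particular accuracy on real slides.

## Problem sizes used in the tests

The shipped test-suite and the acceptance script run everything at
deliberately small scale, chosen as the smallest sizes at which each
property is non-trivial: 1024² phantoms with 512/256 region/patch sizes
for registration; 160–192² phantoms for scoring; a 10-slide benchmark;
and adversarial training with 8 pairs of 64² patches for 150 generator
steps under the reduced architecture, repeated over three seeds. The
published-scale defaults (10,240/1,024 regions, 256² patches, depth-8
generator, 200 epochs) remain the package defaults for real data.

## Known limitations

* Only rigid integer translations are modelled; rotational or elastic
  misalignment must be handled upstream.
* The pure-R network engine favours correctness and portability over
  speed; full-scale training of the default architecture is not practical
  without substituting a GPU-backed engine behind the same interfaces.
* The recomputed kappa of a published 2×2 cross-table need not match a
  kappa value printed alongside it if the latter was derived from a
  different subset or weighting; this package always reports the standard
  unweighted statistic computed from the table itself.
* Hotspot selection is manual by design; automatic hotspot detection is
  out of scope.
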