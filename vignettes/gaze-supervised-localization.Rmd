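---
title: "Gaze-supervised lesion localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-supervised lesion localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemil)
```

## The problem

Bounding-box or ellipse annotations make chest-radiograph classifiers far
better at *pointing at* the abnormality they claim to see, but they are
expensive to collect. Eye-tracking (ET) data recorded while a radiologist
dictates a report is nearly free by comparison — and it contains implicit
localization: when a finding is being dictated, the reader has just been
looking at it. The catch is that a full reading session covers the whole
image; to supervise *label-specific* localization the gaze stream must be
cut into pieces attributable to individual findings.

`gazemil` implements that pipeline end to end: mention detection in the
timestamped transcript, temporal association of fixations with each
mention, Gaussian heatmap rendering, conversion to grid annotations, and
weakly-supervised training of a convolutional grid classifier with an
auxiliary decoder.

## From dictation to label-specific heatmaps

**Mention detection.** A transparent phrase matcher with a shipped,
versioned vocabulary maps report wording to ten study labels
(`study_labels()`), following the public datasets' label grouping:
"cardiomegaly" counts as *Enlarged Cardiac Silhouette*, and parenchymal
terms ("pulmonary edema", "atelectasis", "consolidation", nodules/masses)
additionally map to the umbrella label *Opacity*. Negation is a
sentence-local scope rule: a cue ("no", "without", "negative for", ...)
negates spans after it until a clause boundary. Hedged mentions ("may
represent") count as positive by default, with a configurable cue list to
drop them; rule-based labelers of this kind are imperfect, and the
training formulation tolerates that noise gracefully. This matcher stands
in for the heavier rule-based labeler used with the original datasets; it
is deliberately simple, editable configuration rather than a claim of
equivalence.

**The fixation window.** Readers' gaze *leads* their speech. The default
window for a mention therefore starts `delay = 1.5` s before the
mentioning sentence — capped at the start of the previous sentence,
falling back to the recording start for the first sentence — and ends at
the end of the last mention in the sentence:

$$t_0 = \max(\text{sentence start} - 1.5\,\mathrm{s},\;
\text{previous sentence start}), \qquad
t_1 = \text{last mention end}.$$

All mentions in one sentence share one window and one heatmap. Fixations
partially overlapping the window are included with their overlap as
weight; an all-or-nothing rule would make the result discontinuous in the
window edges. The 1.5 s delay is not guessed: `sweep_policies()`
re-derives it by scoring every start/end rule combination and a
two-stage delay grid (coarse 2.5/5/7.5 s, then 13 delays from 0.5 to 5 s)
against ground-truth ellipses with a validated binarization threshold.

**Rendering.** Each selected fixation contributes an isotropic Gaussian
at its position with standard deviation one degree of visual angle and
amplitude equal to its (clipped) duration. Per-fixation pixels-per-degree
metadata is used when present; otherwise a configurable calibration
applies (85 px/degree at a 512-px working resolution — display geometry
is not recoverable from the data itself, so this is explicit
configuration). The summed map is normalized to peak 1; per-mention maps
of one label are combined by pixelwise maximum, which is associative,
commutative and idempotent, so mention order cannot matter. Gaussians are
truncated at 4 standard deviations (tail below 3.4e-4 of peak).

## Grid annotations

Images are letterboxed: the long side is scaled to 512 px (aspect
preserved, bilinear), the short side centred between black bands. The
identical transform applies to annotation maps, keeping geometry aligned;
padding is always negative. Heatmaps are binarized at 0.15 (a value
chosen from the intensity histograms of extracted maps) and max-pooled to
the 32 x 32 encoder grid, giving the annotated cell set $B_{kx}$; the
decoder target is the same construction at 256 x 256. Ellipse masks pass
through the identical path. Because max-pooling and thresholding are both
monotone they commute exactly; the package implements threshold-then-pool
and asserts the equivalence on random maps, so the unstated order is
immaterial.

## The losses

The encoder outputs one logit $\gamma_{jkx}$ per grid cell $j$ and class
$k$. The image-level probability is a soft OR over cells:

$$C_k(x) = 1 - \prod_{j \in \Gamma_x} g\bigl(1 - \sigma(\gamma_{jkx})\bigr),$$

where $g$ is the *balanced range normalization*: an affine remap of each
factor onto $[0.0056738^{1/n_t}, 1]$ with $n_t$ the number of factors.
The floor serves two purposes: products of hundreds of sub-unit factors
cannot underflow, and the product's range is independent of grid size
(with the shipped base, a 256-cell product reproduces the earlier fixed
$[0.98, 1]$ per-factor scheme). `mode = "fixed_098"` and `mode = "none"`
are retained for ablation.

Per (image, class) the MIL loss takes one of three forms: annotated
images push cells in $B_{kx}$ positive and the rest negative through a
single joint product (so $n_t = |\Gamma_x|$ — the loss is written as one
product inside one logarithm, and the normalization's $n_t$ is defined as
the number of factors being multiplied); unannotated positives pay
$-\log C_k(x)$; unannotated negatives push every cell negative. The batch
loss weights annotated images by $\lambda_A = 3$ and averages over images
and classes. The auxiliary multi-task loss is the mean per-pixel binary
cross-entropy between the decoder's per-class 256 x 256 logit maps and
the binarized label-specific map, applied only to annotated-positive
channels, weighted by $\lambda_T = 300$ in the total
$L = L_I + \lambda_T L_T$. Whether the per-pixel term is summed or
averaged is a free choice absorbed by $\lambda_T$; the package averages.

Because a soft OR over hundreds of cells initialized at $\sigma = 0.5$
starts out saying "present" for every class, the classification head's
bias is initialized to $-3$ (a negative-prior initialization, standard
for detection-style heads); all methods share it.

All products are computed in log space; $-\log C_k$ uses the
`log(1 - exp(x))` decomposition. Gradients are derived analytically and
verified against finite differences in the tests. One numerical guard:
the log-product is capped at $-10^{-12}$ before forming $\log C_k$, which
caps the unannotated-positive loss near $-\log 10^{-12}$ for a model that
is maximally confidently wrong; the cap is unreachable under balanced
normalization with any realistically mixed logits.

## Architecture

The encoder is a convolutional trunk whose stage outputs are bilinearly
resampled to the 32 x 32 grid and concatenated (the multi-resolution
branches; summation was the alternative, concatenation was chosen so that
no branch can cancel another before the head sees it), followed by a
classification block of two convolutions separated by batch
normalization and ReLU — replacing the usual global pooling + linear
head so that each cell keeps its own logit. The decoder is three blocks
of (bilinear x2 upsample, convolution, batch normalization), ending in
one channel per label at half the input resolution; its gradient flows
into the encoder. Two backbones are provided: `tiny` (strided conv
blocks, under 500k parameters, the default for CPU-scale work) and
`resnet50_shaped` (bottleneck residual stages at standard widths, with a
strided convolution standing in for the stem max-pool). The exact branch
tap points of the original full-scale design are not fully recoverable;
taps are taken after each stage, which reproduces the design's intent
(small findings survive at higher-resolution taps) without claiming
bit-identical architecture. Since no deep-learning framework is
assumed, convolution and resampling kernels (forward and backward) are
compiled code within the package and every gradient path is
finite-difference tested.

Training follows the standard protocol: AMSGrad (lr 0.001, weight decay
1e-5), batch 20, 60 epochs at full scale, augmentation by rotation up to
45 degrees, translation up to 15% and scale up to 15% applied identically
to image and annotation maps (re-binarized after interpolation). The best
epoch is chosen by mean validation AUC; the binarization threshold per
label and the heatmap source per method (decoder output vs spatial
activations; ties go to the simpler spatial source) are chosen by mean
validation IoU across seeds. Test IoU compares the chosen source,
binarized and nearest-neighbour upscaled, against ground-truth masks per
positive (image, label) pair.

## The synthetic cohort

Real ET corpora cannot ship with a package; the generator
(`simulate_case()`, `simulate_dataset()`) produces reading sessions with
the statistical structure the extraction method relies on, so the whole
pipeline is testable end to end:

- an initial silent interval (default 5 s) of dispersed scanning, then
  one dictated sentence per positive finding with silent pauses
  (default 2 s) between;
- gaze leading dictation uniformly by `gaze_lag` (default 1.5 s): at
  time $t$ the reader attends what is dictated at $t + \mathrm{lag}$, so
  on-lesion attention spans from lag-before-sentence-start to
  lag-before-mention-end. This is the package's reading of the observed
  behaviour ("looks at the content of the current or following
  sentence"); modeling gaze as lingering on the lesion until the spoken
  mention ends was considered and rejected because it would make every
  delay shorter than the true lag look equally good to the sweep,
  contradicting the observable identifiability of the lag;
- fixations at ~3/s with log-normal durations (~250 ms), scattered
  N(lesion centre, 0.06 x image size) during attention (with a 15%
  off-lesion scan fraction) and uniformly otherwise;
- elliptical lesions (semi-axes 8–20% of image size) as additive
  intensity bumps on smooth background noise, with exact binary masks.
  Each label draws its lesion centre around a characteristic,
  anatomy-inspired home region (jittered by 7% of the image size):
  abnormalities occur in typical locations, and without that structure
  the label identity of a finding would be unlearnable from the image —
  the classification task would be ill-posed and every method's AUC
  would plateau at chance-like levels. Parenchymal labels imply
  *Opacity*, whose mask is the union of its constituents — so
  transcripts, labels and masks are mutually consistent by construction;
- negated distractor sentences ("no pneumothorax") for absent labels
  (15% per negative label), which must never produce annotations;
- an unannotated pool carrying image-level labels only.

These defaults were fixed once, from reading-behaviour plausibility
(fixation rate, speech rate, durations) and lesion geometry, and are the
conditions under which the package's properties are demonstrated. What
the generator does *not* emulate — realistic radiograph texture, saccade
dynamics, reading-order habits, labeler vocabulary mismatch, multiple
readers — bounds what green tests mean: they validate the method's
mechanics and its qualitative behaviour, not clinical performance.

## Validation scale and expectations

The package validates itself at desk scale: 128-px images, an 8 x 8 grid
(the same 16-px cell geometry as 512/32), decoder at 64 x 64, the tiny
backbone, 150 annotated + 300 unannotated training cases, 50 validation
and 100 test cases, 15 epochs, 3 seeds. At that scale the test suite
checks *orderings*, not absolute scores: ellipse supervision >= ET
supervision > no annotation on test IoU — the qualitative fingerprint of
the method — plus an image-level AUC-stability check (difference under
0.05 between ET-supervised and unannotated) that is known to be in
tension with the desk-scale annotated fraction; see the limitations
section. Likewise the two-stage delay sweep must recover the generator's
programmed 1.5 s lag within one grid step in most seeds, and
label-specific heatmaps must beat whole-session heatmaps on at least 80%
of lesions. Multi-seed summaries at this scale use 3 seeds (5 at full
scale); where an interval is wanted, a t-interval over seeds is used and
labelled as such.

## Known limitations

- At full scale, annotated reading sessions are a fraction of a percent
  of the training stream, so the annotated loss terms barely perturb the
  image-level classifier and AUC is stable across supervision settings.
  The desk-scale cohort is one-third annotated, which multiplies the
  decoder term's share of the gradient by roughly two orders of
  magnitude: with $\lambda_T = 300$ and 15 epochs the annotated models'
  image-level AUC converges visibly more slowly than the unannotated
  baseline's (the gap shrinks with epochs and with a smaller
  $\lambda_T$, both verifiable with `run_method()`). The IoU orderings
  are unaffected. The package keeps the full-scale loss weights rather
  than re-tuning them for the small cohort, and the AUC-stability check
  in the validation suite documents this tension when it fails.
- The vocabulary is a transparent approximation of a full rule-based
  labeler; per-label recall/precision on real reports will vary, and
  labeler quality degrades localization quality correspondingly.
- The pixels-per-degree calibration must come from metadata or
  configuration; there is no self-calibration.
- The `resnet50_shaped` backbone is provided for full-scale use but is
  not exercised by the CPU-scale validation, and CPU training at 512 px
  is not practical.
- Sessions arrive pre-fixated; raw gaze-sample event detection and DICOM
  ingestion are out of scope.
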