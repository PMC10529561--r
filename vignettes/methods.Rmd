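---
title: "Constructive NLM with morphological residual processing: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructive NLM with morphological residual processing: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdenoise)
```

## The problem

Low-dose CT slices carry heavy, roughly Gaussian noise on top of
piecewise-smooth anatomy with sharp organ boundaries and small low-contrast
lesions. A good denoiser must smooth the flat regions aggressively without
blurring those boundaries — and a clinically usable one must be fast and
strictly deterministic. `ctdenoise` combines a non-local means (NLM) filter,
reformulated so its weight computation is a stream of vectorizable
prefix-sum passes, with a morphological post-processing stage that puts the
edges the lowpass smoothing removed back into the image.

## Stage 1: the constructive NLM filter

### Model

The recovered image is a convex combination of the pixels in each search
window,

$$u(s) = \frac{1}{Z(s)} \sum_{t \in N(s)} w(s,t)\, v(t), \qquad
w(s,t) = g_h\!\Big(\sum_{\delta \in \Delta}
  \big(v(s+\delta) - v(t+\delta)\big)^2\Big),$$

with the rational kernel $g_h(x) = 1/(1 + x^2/h^2)$. Note that $g_h$ squares
its argument, so the weight decays with the *square* of the patch distance;
this is the filter this package defines, and both implementations
(`nlm_fast`, `nlm_bruteforce`) use it identically. The self-weight
$w(s,s) = g_h(0) = 1$ is kept as-is, so $Z(s) \ge 1$ and no
division-by-zero guard is needed.

### Parameters

* `K` (default 3) — **search half-width**: the window is $(2K+1)^2$
  translations. We fix the half-width convention (7×7 window at the
  default); since the literature sometimes quotes window sides instead,
  `K` is exposed so either reading is runnable.
* `P` (default 5) — patch half-width, an 11×11 flat patch. The patch kernel
  is a constant rather than a Gaussian: the prefix-sum construction requires
  a translation-invariant flat weighting, and in practice the difference is
  negligible.
* `h` (default 0.15, on the [0, 1] intensity scale) — filtering strength;
  $g_h$ drops to 0.5 when the patch distance equals `h`.
* `boundary` — `"symmetric"` (edge-including reflection; default) or
  `"periodic"` wrap. Reflection is the physically sensible choice for CT
  content; the periodic mode exists because the prefix-sum identities hold
  for either and it is occasionally useful for synthetic tests.

### The prefix-sum construction

For each translation $d$ the squared-difference field
$D_d(p) = (v(p) - v(p+d))^2$ is accumulated into a 2-D prefix sum
(integral image) $S_d$. The flat-patch distance at any pixel is then an
axis-aligned box sum, recovered from $S_d$ with four corner reads — so the
per-translation cost is independent of `P`, and the whole filter is
$O(|\Omega| K^2)$ array operations instead of $O(|\Omega| K^2 P^2)$.

Two conventions matter and are fixed once:

* **Exclusive prefix.** The $(2P+1)$-sample box sum is
  $S(c+P) - S(c-P-1)$ per axis with the implicit $S(0) = 0$. A
  "$S(c+P)-S(c-P)$" variant would silently drop one sample of the patch and
  break agreement with the brute-force definition; the test suite pins this
  down.
* **Deterministic accumulation.** Translations are visited in a fixed
  row-major order and the numerator/denominator are accumulated per
  translation and divided once at the end, so results are bit-identical
  across runs and across tilings.

`nlm_bruteforce` — the naive quadruple loop in C++ — is not an optimization
fallback but the package's reference oracle: the suite requires
$\max |{\rm fast} - {\rm brute}| \le 10^{-8}$ across a battery of seeded
images (in practice agreement is at the $10^{-15}$ level), and a third,
pure-R naive implementation in the test helpers validates the C++ oracle
itself on small images.

### Tiling

Because no pixel outside $N(s)$ contributes to $u(s)$, the image can be cut
into disjoint tiles, each processed with a halo of `K + P` surrounding
pixels, with *exactly* the untiled result — this is the package's
correctness contract standing in for parallel/SIMD execution claims, which
are hardware-dependent and deliberately out of scope. `nlm_tiled` and
`denoise_tiled` verify their halo budget and raise an error rather than
silently produce seam artifacts. In the full pipeline only the NLM stage and
the lowpass convolution are tiled (halo `K + P` plus the kernel truncation
radius); geodesic reconstruction can propagate information arbitrarily far,
so it always runs globally.

## Stage 2: morphological residual processing

The NLM output `u` is decomposed as `Io = u * L` (Gaussian lowpass) and
`Res = u - Io`. The residual holds both the edges that smoothing removed and
residual noise; the stage's job is to separate the two. `Res` is split into
non-negative halves (`split_residual`; the split is exact:
`pos - neg == Res`, `pos * neg == 0`), and each half `I` passes through

`M(I) = R_I( min(I, S_{t,s}(I) | {min I, max I}) )`

* `threshold_mask`: keep amplitudes `>= t`;
* `area_open`: delete connected components smaller than `s_size` pixels —
  this is what kills salt-and-pepper-like single-pixel impulses however
  large their amplitude;
* `mask_to_levels` + pointwise minimum: convert the surviving mask into a
  grayscale marker lying below `I`;
* `grayscale_reconstruct`: geodesic reconstruction by dilation restores each
  marked structure to its full original profile (not a clipped version),
  which is why selected edges come back sharp.

The operator is anti-extensive (`0 <= M(I) <= I`) and monotone in both `t`
and `s_size`; the tests assert these order-theoretic contracts directly.
Finally `I_out = Io + c (M(I+) - M(I-))`. The recomposition is linear in
`c`, and two degenerate settings provide exact end-to-end checks: `t = 0,
s_size = 1, c = 1` returns `u` to machine precision, and `t` above the
residual maximum returns `Io`.

### Parameters

* `t` (default 0.15) — amplitude threshold, on the same [0, 1] scale as `h`.
  Edges whose residual amplitude falls below `t` stay smoothed.
* `s_size` (default 3 px) — minimum surviving component area. 1 disables the
  size screen; 2 already suffices to reject isolated impulses.
* `c` (default 1.2) — contrast coefficient; 1 restores original edge
  amplitude, the default mildly enhances it.
* `lowpass_sigma` (default 1.5 px) — width of the Gaussian base filter. The
  method only requires "a lowpass mask"; 1.5 px removes the residual noise
  grain left by NLM while keeping the base image close enough that residual
  amplitudes remain meaningful. The kernel is truncated at radius
  `ceiling(3*sigma)` and renormalized to sum exactly to 1.
* `connectivity` (default 8) — neighbor relation for both the area opening
  and the reconstruction; 8 is the standard 2-D morphology default, 4 is
  selectable.

### Reconstruction algorithm

Geodesic reconstruction is defined as iterating
`marker <- min(dilate(marker), mask)` to its fixed point. The package
implements the hybrid algorithm (one raster sweep, one anti-raster sweep
that seeds a FIFO queue, then queue propagation) in C++; the test suite
checks it against the plain iterated-dilation oracle to $10^{-12}$ and
asserts idempotence. Ties and plateaus need no special handling — the fixed
point is unique.

## Intensity scale and clipping

All computation happens on real-valued intensities nominally in [0, 1]
(8-bit files map to `value/255`, 16-bit to `value/65535`). Intermediate
images are *never* clipped: noisy inputs may dip below 0, and `c > 1` can
push `I_out` past the nominal range. Clipping to [0, 1] with round-half-even
quantization happens only when writing integer formats. This keeps every
algebraic identity in the pipeline exact, at the cost of output files not
being bitwise equal to in-memory arrays when values leave the range.

## The synthetic generator

`generate_phantom` emulates what matters for this method in an abdominal CT
slice: piecewise-constant regions (a body ellipse plus random overlapping
ellipses drawn from a fixed intensity palette), sharp step edges between
them, and a few small low-contrast lesion discs. `add_gaussian_noise` adds
i.i.d. Gaussian noise with standard deviation `sigma8/255`, `sigma8` from
roughly 5 (light) to 30 (heavy) — the conventional 8-bit-scale benchmark
degradation for simulated low-dose scans. Both are seeded and bit-exactly
reproducible, and restore the caller's RNG state.

What the generator does **not** emulate: streak artifacts and spatially
correlated sinogram-domain noise (a faithful simulation would require a
Radon/filtered-back-projection pipeline), organ texture, and the partial
volume effect. Passing the simulation tests therefore demonstrates that the
implementation is correct and that the method behaves as designed on
piecewise-constant content with additive Gaussian noise — not that the
default parameters are optimal for any particular clinical scanner or
reconstruction kernel.

## Problem sizes and study conditions

The package's own studies run at sizes where every property can be checked
exhaustively: the oracle-equivalence battery uses 20 seeded random images
between 32×32 and 96×96 (including non-square shapes) crossed with
`(K, P) ∈ {(1,1), (2,3), (3,5)}`, `h ∈ {0.05, 0.15, 0.5}` and both boundary
modes; the denoising-efficacy study uses 128×128 phantoms at
`sigma8 ∈ {10, 20, 30}` with 20 seeded repetitions per level and the default
parameters, requiring PSNR/RMSE/SSIM to improve in at least 95% of
repetitions. `scripts/acceptance.R` re-runs the same kind of study from a
single command-line seed and writes the measured quantities as JSON.

## Evaluation metrics

`rmse`, `psnr` (peak 1.0 on the internal scale; identical images report
`Inf`) and `ssim` (11×11 Gaussian window, sigma 1.5, K1 = 0.01, K2 = 0.03,
dynamic range 1 — the standard literature constants) follow their textbook
definitions; `line_profile` samples intensities along a Bresenham segment so
edge rendition can be compared against a reference image, summarized by the
mean absolute profile difference (`profile_overlap`). Feature-similarity
indices based on phase congruency are out of scope; `metric_report` is the
hook where one would be added.

## Known limitations

* 2-D single-channel images only; no 3-D volumes, no DICOM I/O.
* The rational kernel's `h` is not interchangeable with the `h` of
  exponential-kernel NLM implementations; tune accordingly when comparing.
* The amplitude threshold `t` lives on the [0, 1] scale — images with
  unusual dynamic range need `t` (and `h`) rescaled.
* Symmetric extension limits the padding margin to the image size, so very
  small images (below `2(K+P)+1` per side at the defaults) need smaller
  `K`/`P` or periodic boundaries.
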