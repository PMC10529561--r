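# ctdenoise

Edge-preserving denoising of low-dose computed tomography (LDCT) images in R.

Lowering the X-ray tube current reduces patient dose but floods the
reconstructed slices with noise and streak artifacts, which obscure exactly
the low-contrast structures (lesions, soft-tissue boundaries) a radiologist
needs to see. `ctdenoise` implements a two-stage post-processing method for
such images, aimed at researchers studying CT denoising and at anyone who
needs a fast, fully deterministic non-local means (NLM) implementation with
morphological edge restoration.

## The method

**Stage 1 — constructive non-local means.** Each pixel `s` of the noisy image
`v` is replaced by a similarity-weighted average over its search window
`N(s)` (half-width `K`):

    u(s) = 1/Z(s) * sum_{t in N(s)} w(s, t) v(t),      Z(s) = sum_t w(s, t)
    w(s, t) = g_h( sum_{|delta| <= P} (v(s + delta) - v(t + delta))^2 ),
    g_h(x) = 1 / (1 + x^2 / h^2)

with a flat (unweighted) square patch of half-width `P` and a rational
similarity kernel. The "constructive" part is how the weights are computed:
for each translation `d = t - s`, the per-pixel squared difference between
the image and its translate is accumulated into a prefix-sum (integral)
image, from which every pixel's patch distance is read back with 4 corner
lookups. The cost per translation is therefore independent of the patch
size, the arithmetic is plain vectorized array work, and pixels outside
`N(s)` never contribute — which is what makes tiled/parallel execution exact
(see `nlm_tiled`, `denoise_tiled`).

**Stage 2 — morphological residual processing.** NLM output `u` is split
into a Gaussian lowpass base `Io = u * L` and a residual `Res = u - Io`,
which carries the edges removed by smoothing along with leftover noise. The
residual is decomposed into non-negative halves `I+` and `I-`, and each half
is screened: regions must reach amplitude `t` and connected area `s` pixels
(area opening, so isolated high-amplitude impulses die), and the survivors
are restored to their full original profile by grayscale geodesic
reconstruction. The output is recomposed with a contrast coefficient `c`:

    I_out = Io + c * ( M(I+) - M(I-) )

With `c = 1` restored edges keep their original amplitude; `c > 1` enhances
them; everything that fails the screen stays smoothed.

Defaults are the reference operating point: `K = 3`, `P = 5`, `h = 0.15`,
`t = 0.15`, `s = 3`, `c = 1.2`.

## Worked example

No external data is needed — the package ships a synthetic phantom generator
that emulates the structure of an abdominal CT slice (piecewise-constant
ellipses, small low-contrast lesions) and its low-dose degradation (additive
Gaussian noise, sigma on the 8-bit scale):

```r
library(ctdenoise)
phantom <- generate_phantom(128, 128, seed = 7)
noisy   <- add_gaussian_noise(phantom, sigma8 = 20, seed = 8)
result  <- denoise(noisy)

print(result)
#> Denoise result: 128 x 128 image
#>   residual range [-0.3144, 0.4218]; restored pixels: 8107 (+), 8019 (-)
#>   output range [-0.1802, 0.7156]
metric_report(phantom, noisy)
#> PSNR 22.0321 dB | SSIM 0.2469 | RMSE 0.07914
metric_report(phantom, result$out)
#> PSNR 30.1483 dB | SSIM 0.7167 | RMSE 0.03109
```

At this noise level the pipeline buys about 8 dB of PSNR and nearly triples
SSIM; `result` also retains every intermediate (`u`, `Io`, `res`, the
residual halves and their processed versions) for inspection. Line profiles
(`line_profile`, `profile_overlap`) let you check edge rendition along any
segment.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/ctdenoise.R simulate --height 128 --width 128 --sigma8 20 --seed 7 --out sim/
Rscript inst/cli/ctdenoise.R run --input sim/noisy.tif --output out.tif \
    --metrics sim/phantom.tif --profile 64,1,64,128 --save-intermediates inter/
```

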