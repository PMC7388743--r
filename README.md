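# aggdenoise

Wavelet-domain de-noising of 2-D grayscale images — MRI brain slices are
the intended use case — built around a family of threshold (shrinkage)
functions that includes the adaptive generalized Gaussian distribution
(AGGD) family.

## The problem and the method

An observed image is modeled as `f = u + n`, where `n` is additive white
Gaussian noise (AWGN) with zero mean and unit-scale variance `v` (noise
standard deviation `255·√v` on the `[0, 255]` intensity scale). The
pipeline is the classical three-step wavelet shrinkage scheme:

1. a 2-D discrete wavelet transform (orthonormal periodized Daubechies
   filter bank; db4 with one decomposition level by default) splits the
   image into an approximation subband and detail subbands LH, HL, HH;
2. every detail coefficient `x` is passed through a threshold function
   `η(x)`; the approximation subband is untouched;
3. the inverse transform returns the de-noised image.

The noise level is estimated from the finest diagonal subband with the
robust median (MAD) rule `σ̂ = median(|HH₁|) / 0.6745`.

Threshold functions implemented (all elementwise, all odd):

| family | rule | threshold |
|---|---|---|
| `hard` | keep if `\|x\| > t`, else 0 | `t = σ̂√(2 ln n)` (VisuShrink) |
| `soft` | `sign(x)·max(\|x\|−t, 0)` | VisuShrink |
| `zhang_soft` | `x + ½(√((x−t)²+λ) − √((x+t)²+λ))` | VisuShrink |
| `zhang_hard` | sigmoid-gated hard, shape `μ` | VisuShrink |
| `adaptive_hard` | identity outside `[−σ, σ]`, AGGD-tuned inside | `t = σ̂` |
| `adaptive_soft` | continuous variant, shifts the tails | `t = σ̂` |
| `aggd` | identity outside `[−t, t]`, AGGD-tuned inside | `t = t*` |
| `improved_aggd` | sigmoid-weighted tails, AGGD-tuned inside | `t = t*` |

The AGGD core is `s(x) = σₙ(e^{x²/(2σₙ²)} − ½)`. Instead of zeroing
sub-threshold coefficients, the adaptive/AGGD families "tune" them through
the odd-extended shifted core `sign(x)(s(|x|) − s(0))`. The threshold `t*`
of the AGGD families is the intersection of that curve with the identity
line, i.e. the root of `σₙ(e^{t²/(2σₙ²)} − 1) = t`, which is
`t* = 1.28589·σₙ` — the unique choice that makes both AGGD functions
continuous. De-noising quality is reported as
`MSE = mean((d − d̂)²)` and `PSNR = 10·log₁₀(255²/MSE)` dB.

Because real MRI data need not be downloaded for any test, the package
ships a deterministic brain-like phantom generator (skull rim, nested
tissue ellipses, low-frequency shading, fine-scale tissue texture) and an
AWGN simulator.

## Worked example

```r
library(aggdenoise)

clean <- make_phantom()                               # 256x256, [0, 255]
noisy <- add_awgn(clean, noise_model(0.01, seed = 1)) # sd = 25.5
img_psnr(clean, pmin(pmax(noisy, 0), 255))            # 20.6 dB

rep <- denoise(noisy, "improved_aggd", ref = clean, quiet = FALSE)
#> denoise: family=improved_aggd sigma_hat=0.0997044 threshold=0.128209
print(rep)
#> De-noise report: improved_aggd, db4 x1 level(s)
#>   sigma_hat = 0.0997044, threshold = 0.128209 (unit scale)
#>   vs reference: MSE = 449.1, PSNR = 21.6079 dB
```

The estimated `sigma_hat` (0.0997 on the unit working scale, i.e. 25.4 of
255) recovers the injected noise level `√0.01 = 0.1`; the threshold is
`1.28589 × sigma_hat`; de-noising gains about 1 dB of PSNR over the noisy
input at this noise level. A multi-method sweep:

```r
run_benchmark(clean, 0.01, c("hard", "adaptive_soft", "improved_aggd"),
              seeds = 1:5)
#>          family variance mean_psnr mean_mse mean_psnr_noisy
#> 1          hard     0.01     21.30    482.0           20.59
#> 2 adaptive_soft     0.01     21.85    424.4           20.59
#> 3 improved_aggd     0.01     21.63    446.6           20.59
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "aggdenoise.R", package = "aggdenoise"))')
Rscript $CLI simulate  --out fixtures --variances 0.01,0.03,0.05 --seeds 1
Rscript $CLI denoise   --in noisy.png --out clean.png --method improved-aggd --report rep.json
Rscript $CLI evaluate  --ref ref.png --test clean.png --out metrics.json
Rscript $CLI benchmark --out bench.csv --seeds 5
```

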