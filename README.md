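# gafuse

Multi-modal image fusion with a geometric-algebra sparse representation
(GA-SR).

## What it does

Pseudo-colour functional images (e.g. SPECT rendered as RGB) acquired under
two different conditions carry complementary information. Fusion methods
that sparse-code each colour channel as an independent grayscale image break
the correlation between channels and distort colour in the fused result.
`gafuse` encodes each pixel as one element of the plane geometric algebra
G2 — basis {1, γ₁, γ₂, γ₁₂} with γ₁² = γ₂² = 1, γ₁γ₂ = γ₁₂ = −γ₂γ₁ — as

    q = 0 + R·γ₁ + G·γ₂ + B·γ₁₂ ,

so the three channels move through the whole pipeline as a single algebraic
object. Patches are coded under the sparse model

    min_a ‖a‖₀  s.t.  q = D a ,

where D is a dictionary of unit-norm multivector atoms, using a
geometric-algebra orthogonal matching pursuit (GAOMP: atom selection by the
magnitude of the multivector correlation Σᵢ d̃ᵢ rᵢ, least-squares refit on
the real embedding of the algebra). The dictionary is learned from the
pooled patches of both sources with K-GASVD (alternating GAOMP coding and
per-atom singular-vector updates on the embedded error matrix). Per patch,
the fused coefficient column is whichever source column has the larger GA
L1 norm Σₘ |aₘ| (ties to source 1); fused patches x_F = D a_F are
overlap-averaged and decoded back to RGB. The package also ships the four
fusion-quality metrics (CC, PSNR, RMSE, joint entropy, each averaged over
the two fused-vs-source terms), deterministic phantom/sparse-problem
generators with known ground truth, and a CLI.

## Worked example

Fuse a complementary phantom pair (each source reveals one half of a known
scene) and score the result:

```r
library(gafuse)

ph  <- make_phantom_pair(size = 64, seed = 1, complement_mode = "halves")
res <- fuse_images(ph$img1, ph$img2, fusion_config(seed = 1))
res
#> <fusion_result: 64x64 fused image, 3249 patches (50.5% from source 1)>

fusion_metrics(res$fused, ph$img1, ph$img2)
#> Fusion quality (mean over the two sources):
#>   CC            0.57217
#>   Joint entropy 8.4837 bits
#>   PSNR          10.3309 dB
#>   RMSE          0.3120

psnr <- function(a, b) 20 * log10(1 / sqrt(mean((a - b)^2)))
c(fused = psnr(res$fused, ph$truth),
  src1  = psnr(ph$img1, ph$truth),
  src2  = psnr(ph$img2, ph$truth))
#>     fused      src1      src2
#> 25.795088 11.834603  8.278052
```

The per-patch L1-max rule hands each half of the scene to the source that
actually saw it (the ~50/50 mask split), so the fused image ends up ~14 dB
closer to the ground truth than the better source alone. The
fused-vs-source CC/PSNR/RMSE are moderate by construction: each source
disagrees with the fused image on the half it never observed.

The same pipeline from a shell:

```sh
Rscript inst/bin/gafuse synth --kind phantom --seed 1 --size 64 --out demo/
Rscript inst/bin/gafuse fuse --in1 demo/img1.png --in2 demo/img2.png --out demo/fused.png
Rscript inst/bin/gafuse metrics --fused demo/fused.png --src1 demo/img1.png \
    --src2 demo/img2.png --report demo/report.json
```

Every command writes a JSON run manifest (resolved config, input digests,
seed, timings) next to its output; re-running with the manifest's settings
reproduces the output bit-exactly.

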