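# starcut

Seed-driven, real-time capable segmentation of focal liver lesions in 2D
B-mode ultrasound.

Manual outlining of liver metastases in ultrasound is slow and strongly
observer-dependent: the images are noisy and the contrast between a
metastasis and surrounding parenchyma is low. `starcut` implements an
interactive template-cut approach for this problem: the user supplies one
seed point inside the lesion, and the algorithm returns a closed,
star-shaped contour fast enough to be recomputed on every mouse move. It is
aimed at researchers in medical image analysis who want a reproducible,
scriptable implementation of this segmentation family together with the
standard evaluation metrics and a synthetic phantom generator, so the whole
pipeline can be developed and tested without clinical data.

## Method

A circular template of `R` rays is centred on the seed; `L` nodes are
sampled along each ray by bilinear interpolation. With `m` the average gray
value over a small disc around the seed, each node gets a cost

```
c[r, i] = | m − g[r, i] |
```

The nodes become an s-t flow network: the innermost node of each ray is
bound to the source with capacity `c[r, 1]`, the outermost to the sink with
`c[r, L]`, and every interior node carries the difference of adjacent costs
`w = c[r, i] − c[r, i−1]` — to the sink if `w ≥ 0`, else to the source with
`|w|`. Infinite-capacity intra-edges along each ray force the cut to cross
every ray exactly once (a star-shaped result), and infinite inter-edges
between cyclically adjacent rays bound the cut-level difference by a
smoothness parameter `Δr` (default 2). The minimum s-t cut then yields one
boundary position per ray, which is turned into a polygon and a binary
mask. On homogeneous tissue with no boundary inside the template, the
contour collapses to the seed — the intended "no lesion here" feedback.
Evaluation uses the Dice similarity coefficient
`DSC = 2|A∩R| / (|A|+|R|)` and the symmetric Hausdorff distance
`H(A,R) = max(h(A,R), h(R,A))` over boundary pixel centres, in pixels.

## Worked example

Generate a noise-free hypoechoic phantom (elliptical lesion of level 60 on
background 100), segment it from its centre and score the result:

```r
library(starcut)

sp  <- phantom_spec(lesion_level = 60, semi_axes = c(22, 18),
                    rotation = 0.4, speckle_scale = 0, blur_sigma = 0)
ph  <- generate_phantom(sp)
fit <- segment_lesion(ph$image, seed = sp$center, radius = 45)
fit
#> Star-shaped template-cut segmentation
#>   seed (79.5, 79.5), seed average 60.00
#>   template: radius 45.0 px, 60 rays x 40 nodes, delta_r 2
#>   foreground: 1152 px, cut cost 0
#>   solved in 0.222 s

dice(fit$mask, ph$mask)                 # 0.9624
hausdorff_distance(fit$mask, ph$mask)   # 1.41 px
```

The seed average (60.00) is the reference intensity; the cut cost 0 says the
contour runs entirely through nodes whose intensity matches it exactly; the
1 152 foreground pixels against a 1 242 px ground-truth ellipse give a Dice
overlap of 0.96, and no boundary point is further than 1.4 px from the true
boundary. `plot(fit, ph$image)` overlays the red contour and white seed on
the image. On *speckled* phantoms with featureless interiors, single-seed
localisation degrades markedly — the cost model has no regional term; see
the methods vignette (`vignettes/template-cut-methods.Rmd`) for the
analysis and for the role of interactive seed adjustment.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/starcut.R phantom  --suite 20 --seed 7 --out phantoms/
Rscript inst/cli/starcut.R segment  --image phantoms/phantom_001.png \
        --seed 80,80 --radius 45 --out out/
Rscript inst/cli/starcut.R evaluate --pred out/ --ref phantoms/ --out report.csv
```

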