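# burnscar

Unsupervised extraction of fire burn scars from bi-temporal multispectral
imagery (e.g. Landsat 5 TM or Landsat 8 OLI), for remote-sensing and fire
ecology workflows that need a burned-area mask without hand-picked thresholds
or training samples.

Given a co-registered pre-fire/post-fire raster pair, the package

1. builds a **fused difference image**
   `DI = Σ w_k D_k`, `w_k = σ_k / Σ σ_j`, from three normalized change
   features — the change vector analysis magnitude
   `ρ(x) = ‖X²(x) − X¹(x)‖₂` over the reflective bands, the NDVI difference
   and the normalized burn ratio (NBR) difference, both taken pre − post so
   burned vegetation is bright;
2. derives an **automatic initial contour**: the date-2 NIR band is regressed
   on the date-1 NIR band by least squares, each pixel gets the Mahalanobis
   fitting error `E = (x₂ − a·x₁ − b)² / S`, and a two-cluster K-means split
   of `E` yields the change mask used as the starting curve;
3. segments `DI` with the **Chan–Vese level-set model**, minimizing the
   piecewise-constant Mumford–Shah energy
   `μ∫δ_ε(φ)|∇φ| + ν∫H_ε(φ) + λ₁∫(u₀−c₁)²H_ε(φ) + λ₂∫(u₀−c₂)²(1−H_ε(φ))`
   by explicit gradient descent — topology changes (split scars, holes,
   concave blurred boundaries) are handled automatically.

Also included: the standard comparison methods (Otsu thresholding, fuzzy
C-means, and the traditional Chan–Vese configuration with a CVA-only
difference image and tiled-rectangle initialization), accuracy metrics
(missed/false/right alarm rates, Cohen's kappa, iteration counts),
class-separability diagnostics (`D = |μ_b − μ_u|/(σ_b + σ_u)`, histogram
overlap), and a synthetic bi-temporal scene generator with known ground
truth so the whole pipeline can be benchmarked without external data.

See `vignettes/burn-scar-extraction.Rmd` for the model, the stopping-rule
design, all tunable parameters, and what the synthetic benchmark does and
does not demonstrate.

## Worked example

```r
library(burnscar)

# a synthetic 128 x 128 TM-like scene pair with a known burn scar
pair <- make_burn_pair(scene_spec(seed = 42))

dp <- difference_image(pair$pre, pair$post)
dp
#> <difference_product> 128 x 128, weights cva=0.373 ndvi=0.309 nbr=0.318
separability(dp$di, pair$truth)
#> <separability> D = 5.6719 (burn 0.774+/-0.084, unburn 0.084+/-0.037), overlap = 0.000

res <- extract_burn_scar(pair$pre, pair$post, method = "proposed")
res$segmentation
#> <segmentation> 128 x 128, 2459 inside pixel(s), 357 iteration(s), converged

compare_methods(pair$pre, pair$post, pair$truth)
#>    method missed_pct false_pct right_pct  kappa iterations
#>  proposed   0.006104   0.01221     99.98 0.9993        357
#>      otsu   0.042725   0.01221     99.95 0.9978         NA
#>       fcm   0.054932   0.01221     99.93 0.9974         NA
#>       tcv   0.000000   0.45166     99.55 0.9825       2115
```

The fusion weights say the CVA magnitude carried the most change variance
(0.373) but the index differences together outweigh it; `D = 5.67` means the
burn and unburn intensity distributions of the fused difference image are
separated by more than five pooled standard deviations (their histograms do
not overlap). The proposed pipeline converges in 357 iterations from the
automatic contour versus 2115 for the rectangle-initialized traditional
Chan–Vese, and scores the highest kappa of the four methods; `right_pct` is
the percentage of all pixels classified correctly, and the three alarm rates
sum to 100 by construction.

On real rasters, use `read_scene()` with a `band_roles()` preset (`"tm"`,
`"oli"`, or custom band indices) and `run_pipeline()`, which writes the
difference image, masks, energy trace and accuracy report to an output
directory. A thin command-line front end with `simulate`, `run` and
`compare` subcommands is installed at `inst/cli/burnscar.R`:

```sh
Rscript inst/cli/burnscar.R simulate --out scene --seed 7
Rscript inst/cli/burnscar.R run --pre scene/pre.tif --post scene/post.tif \
    --truth scene/truth.tif --sensor tm --method proposed --out run_out
Rscript inst/cli/burnscar.R compare --pre scene/pre.tif --post scene/post.tif \
    --truth scene/truth.tif --out cmp_out
```

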