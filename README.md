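# filatrace

Morphometric analysis of filament networks — above all F-actin in
fluorescence micrographs — from 2-D grayscale images. Confocal images of
phalloidin-labelled actin show bright curvilinear filaments over diffuse
background from unpolymerized actin and noise; questions like *how long
are the filaments and how many are there* require individual centerlines,
not pixel statistics. `filatrace` turns an intensity image into a list of
disambiguated filament paths with calibrated lengths, and ships a
synthetic network generator plus a validation harness that scores the
whole pipeline against known ground truth.

## Method

Four estimation–inference stages:

1. **Enhancement.** The image is correlated with a bank of artificial
   filament templates — constant-curvature arc ridges with Gaussian
   cross-section, enumerated over rotation θ ∈ [0, π), scale and signed
   curvature κ, each zero-mean and unit-norm. The filament likelihood is
   the pixelwise product of the min-max-normalized best response
   `max_k (I ⋆ T_k)` and the normalized intensity, which emphasizes
   filaments while suppressing background fluorescence.
2. **Foreground estimation.** Two-class clustering of likelihood values
   (1-D two-means; equivalently a threshold at the midpoint of the
   converged centroids) splits filament from non-filament pixels;
   8-connected components below `min_object_px` are removed.
3. **Thinning.** A topology-preserving parallel two-subiteration scheme
   reduces the mask to unit-width centerlines.
4. **Disambiguation and measurement.** Skeleton pixels are organized into
   a graph of endpoints, junction clusters and pixel-chain edges;
   bifurcations and crossings are resolved by tangent continuity (greedy
   pairing by smallest turn angle, compound junctions collapsed, shared
   segments bridged, end-to-end fusions split at corners). Each filament's
   length is the arc length of its smoothed centerline chain, in px or µm.

The length distribution is summarized by the count-weighted average length
across images with a propagated standard error, and groups of images are
compared by Welch's t-test on per-image mean lengths.

## Worked example

```r
library(filatrace)

spec <- network_spec(n_filaments = 8, seed = 101)   # 128 x 128 px synthetic image
net  <- render_network(spec)                        # image + ground truth
res  <- trace_filaments(net$image, template_bank(), pixel_size_um = 0.1)
print(res)
#> trace_result: 8 filaments
#> length_distribution: 8 filaments over 1 image(s)
#> weighted mean length: 4.53 +/- 0.54 um

m <- match_filaments(res$paths, net$truth)
length_rmse(m, res$paths, net$truth)
#> [1] 1.29
```

The tracer recovered all 8 planted filaments; their measured lengths agree
with the ground truth to 1.3 px RMSE, i.e. about 0.13 µm at the assumed
0.1 µm pixel size. For real micrographs, `read_intensity_image()` loads
8/16-bit TIFF or PNG and `max_project()` flattens confocal z-stacks before
tracing; `write_outputs()` writes the per-filament table, length histogram
and summary JSON.

A command-line front end over the same functions lives at
`inst/scripts/filatrace.R`:

```sh
Rscript inst/scripts/filatrace.R simulate --out sim --n-filaments 10 --seed 3
Rscript inst/scripts/filatrace.R trace --in sim/synthetic_001.tif --out traced
Rscript inst/scripts/filatrace.R validate --out report --seed 1
```

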