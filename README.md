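# visorient

Global orientation detection in binary images with a Hubel–Wiesel
feedforward model — for computational neuroscientists who want a fully
inspectable, training-free alternative to learned filters, and for
anyone studying the noise robustness of biologically constrained
feature detectors.

## The model

An M × N binary image is scanned by four McCulloch–Pitts simple cells
per pixel, each watching a 3 × 3 local receptive field. The cell
selective for orientation *o* fires when the three pixels of its ON line
(horizontal, vertical, or one of the two diagonals, always through the
centre) clear the threshold:

    y = 1  iff  w₁xₐ + w₂x_b + w₃x_c ≥ θ,   w = (1, 1, 1), θ = 2.5

so with the defaults it is an AND over the 3-pixel line; out-of-image
positions count as unstimulated, and the OFF region has weight 0. Four
complex cells pool all same-orientation simple cells over the image:

    z_o = Σᵢ yᵢ   (the cell's spike rate)

The detected global orientation is `argmax_o z_o`, with ties (e.g. a
filled square, where z₀ = z₉₀) and all-silent images reported as
ambiguous rather than resolved. For a 32 × 32 input this instantiates
1024 receptive fields, 4096 simple cells and 4 complex cells.

The package also ships the generators needed to reproduce the model's
evaluation: ideal oriented objects (lines/bars/rectangles with strict
length > width, plus elongated-blob stand-ins for natural shapes), the
two noise regimes (background-only lighting vs whole-image pixel
flips), an evaluation harness (accuracy tables, noise sweeps,
spike-rate curves, confusion matrices with an explicit ambiguous
column), PGM/PNG/text-grid I/O, and a CLI.

## Worked example

```r
library(visorient)

obj <- render_object(object_spec("bar", 135, length = 12, width = 2,
                                 position = c(8, 6)))
detect_orientation(obj$image)
#> Complex-cell spike rates (spikes):
#>   0°  45°  90° 135°
#>    0    0    0   20
#> Detected orientation: 135°
```

The 135°-selective complex cell collects W(L−2) = 2·10 = 20 spikes — one
per interior diagonal centre — and no other cell fires, so the bar is
labelled 135°. Background noise adds spurious spikes without touching
the object, and the winner survives:

```r
noisy <- add_noise(obj$image, obj$mask, "background", p = 0.05, seed = 7)
detect_orientation(noisy)
#> Complex-cell spike rates (spikes):
#>   0°  45°  90° 135°
#>    4    0    2   21
#> Detected orientation: 135°
```

Accuracy under both noise regimes on a generated 1000-image set of
elongated objects (≥ 32 lit pixels, aspect ratio ≥ 3):

```r
ds <- build_dataset(n_per_class = 250, min_pixels = 32, min_aspect = 3,
                    seed = 11)
noise_sweep(ds, proportions = c(0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
            seed = 12)
#> Recognition accuracy under noise:
#>         kind p = 0 p = 0.05 p = 0.1 p = 0.15 p = 0.2 p = 0.25 p = 0.3
#>   background 1.000    1.000   1.000    1.000   1.000    0.992   0.968
#>  whole_image 1.000    1.000   1.000    0.995   0.949    0.771   0.550
```

Recognition is perfect through 10% noise in both regimes, and
background noise (which can only add activations) degrades much more
slowly than whole-image noise (which erodes the object itself).

There is also a command-line interface:

```sh
Rscript inst/cli/visorient detect image.pgm --format json
Rscript inst/cli/visorient generate --config cfg.json --out data/
Rscript inst/cli/visorient evaluate --data data/
```

See the vignette (`vignettes/orientation-detection.Rmd`) for the model's
assumptions, the generator conventions and known limitations.

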