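---
title: "A Hubel–Wiesel feedforward model for global orientation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Hubel–Wiesel feedforward model for global orientation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visorient)
```

## The model

`visorient` implements the classical Hubel–Wiesel account of orientation
selectivity as a literal feedforward circuit over binary images. An
M × N image is a grid of photoreceptors: a pixel is 1 where light falls
and 0 elsewhere. Every pixel is the centre of a 3 × 3 **local receptive
field**, inspected by four **simple cells**, one per orientation class
(0°, 45°, 90°, 135°). A simple cell is a McCulloch–Pitts threshold unit:
its excitatory (ON) region is the 3-pixel line through the centre at its
preferred orientation, each ON input has connection weight 1, and the
cell fires iff the weighted input sum reaches the threshold θ:

$$y = \begin{cases}1, & w_1 x_a + w_2 x_b + w_3 x_c \ge \theta\\ 0, &
\text{otherwise}\end{cases}$$

With the default θ = 2.5 the cell fires exactly when all three ON pixels
are lit — θ sits strictly between 2 and 3, so the unit is a noise-proof
three-input AND. The OFF region is idealised away: its weights are 0, so
light outside the ON line can never inhibit the cell. Receptive-field
positions that extend past the image border count as unstimulated
(input 0); no other padding mode is offered, because the border rule is
part of the model, not an implementation convenience.

Four **complex cells** — one per orientation — each sum every
same-orientation simple-cell output over the whole image. The sum is the
cell's *spike rate* (one spike per firing simple cell), bounded above by
M × N and by the number of lit pixels. The global decision is
winner-take-all over the four spike rates. Two outcomes carry no label
and are flagged ambiguous rather than silently resolved: a tie (a filled
square drives the 0°- and 90°-selective cells identically — genuinely
undecidable, for the model as for a human observer) and total silence
(no cell fired). For a 32 × 32 input the instantiated system therefore
has 1024 receptive fields, 4096 simple cells and 4 complex cells.

### Coordinate and diagonal conventions

Coordinates are (row, column) with rows increasing downward. The 45°
class is the *anti-diagonal* triple {(−1,+1), (0,0), (+1,−1)} (running
from lower-left to upper-right) and the 135° class the *main-diagonal*
triple {(−1,−1), (0,0), (+1,+1)}. One convention had to be fixed;
everything in the package — generators, evaluation, spike records — uses
this one. Spike records replay the scan row-major over centres; the
order is a reporting convention (only the counts feed the decision).

### Parameters that matter

* `theta` (unitless, default 2.5): the firing threshold. Lowering it
  below 2 turns the AND into a 2-of-3 detector and destroys orientation
  selectivity; it is exposed so the threshold logic can be probed, not
  because other values are recommended.
* `weights` (unitless, default `c(1, 1, 1)`): ON-region connection
  weights. Defaults reproduce the model exactly; the comparison is
  implemented as a weighted sum against θ rather than a hard-coded AND
  so the perturbed variants remain expressible.

```{r}
m <- avs()
summary(m, dim = c(32, 32))
```

## What the generators emulate

The reference datasets are unpublished, so the package generates its own
inputs under recorded provenance (every dataset carries its full
configuration and master seed, and regeneration is bit-exact).

**Ideal objects** are lines (width 1), bars and rectangles with one
definite orientation. For 0°/90° an object is a filled L × W rectangle.
The 45°/135° rasterisation is not dictated by the source material; the
package draws W adjacent parallel diagonal runs of L pixels (a staircase
parallelogram), which keeps the closed-form response hierarchy: the
preferred complex cell sees W(L−2) spikes, the orthogonal one
(W−2)(L−2), so any strict L > W yields a unique winner on clean images.
This makes *perfect clean accuracy a provable property of the
construction*, which is exactly what the accuracy-by-stratum experiment
asserts: the strata (3, 4, 8, 12, 16, 32, ≥48 lit pixels in a 32 × 32
frame) sample the factorisations L × W with strict L > W uniformly, with
uniformly random positions. Squares are only constructible through an
explicit `allow_square` override, since they are undecidable by design.

**Noise** comes in the two regimes of the published robustness
experiments, both placing `round(p · M · N)` pixels sampled without
replacement from a seeded RNG:

* *background* noise lights background pixels only — the object is never
  touched, so noise can only add spurious activations;
* *whole-image* noise flips pixels anywhere (0→1, 1→0), so it can erase
  object pixels, change the object's shape and suppress the preferred
  response. Flip semantics were chosen because set-to-1 noise could
  never "change the object's shape" or inhibit activations, which is the
  defining feature of this regime.

**The noise-experiment preset** (≥ 32 lit pixels) restricts to markedly
elongated objects: widths 1–5 with aspect ratio L/W ≥ 3. Two
considerations fixed this choice. First, the elongation-morph experiment
shows the spike-rate margin between the preferred and orthogonal complex
cells is 2(L−W): near-square objects sit close to undecidability and are
not "objects with a specific orientation" in any useful sense. Second, a
worked spike-rate figure of the reference experiments (rate 65 for a 0°
bar) corresponds to a 15 × 5 bar — aspect ratio 3 — suggesting that is
the regime the robustness tables describe. The aspect floor guarantees a
margin of at least 16 spikes, which is what makes perfect accuracy under
5–10% background noise a reproducible property rather than a
dataset-composition accident.

**Blobs** stand in for the figure-only natural objects, which cannot be
recovered from the text. `render_blob()` rasterises a randomly jittered
ellipse (elongation ≥ 2, random position) whose principal axis is the
requested orientation class; it is labelled by construction and clearly
synthetic. It probes the detector on curved boundaries and ragged
diagonal runs, but it is *not* a natural-image benchmark: passing blob
tests says nothing about grayscale scenes, texture, or objects whose
principal axis falls between the four classes.

## Evaluation conventions

A classification is correct iff the detection has a unique winner equal
to the ground-truth label. Ambiguous outcomes are tallied in a dedicated
confusion-matrix column (beyond the conventional 4 × 4) and scored
incorrect — the conservative choice, and the separate tally keeps the
other convention recoverable. Accuracies print to three decimals.
`noise_sweep()` re-noises one clean base dataset per (regime,
proportion) cell with deterministic per-item seeds, so clean geometry is
shared across the whole sweep, as in the paired published datasets.

```{r}
ds <- build_dataset(n_per_class = 25, min_pixels = 32, min_aspect = 3,
                    seed = 11)
noise_sweep(ds, proportions = c(0, 0.1, 0.2, 0.3), seed = 12)
```

## Numerical and design notes

* All arithmetic is small-integer; the only floating-point comparison is
  the weighted sum against θ, exact for the default values.
* Ties are reported, never broken; "no cell fired" is distinguished from
  a tie (empty winner set vs. a multi-element one).
* Degenerate inputs: 1 × N and M × 1 images are legal (vertical/diagonal
  triples simply never complete); the all-zero image detects nothing.
* `build_dataset()` draws a per-item seed whether or not noise is
  requested, so clean and noisy builds from one master seed share
  identical object geometry.
* Problem sizes: the shipped experiments use 100 images per orientation
  per stratum for the clean accuracy table, and a 1000-image ≥32-pixel
  base for the noise sweeps — large enough that a per-image failure rate
  of 1% would be visible, small enough to re-run in seconds.

## Known limitations

Only the four axis/diagonal orientation classes are representable; there
is no OFF-region inhibition, no grayscale or colour support, and no
learning (the weights are fixed by the model, not trained). Clean ideal
objects are classified perfectly *by construction*, so those tests
validate the implementation, not the model's difficulty; the informative
regimes are the noise sweeps and blob experiments. Natural-object
results depend on the blob stand-in and should not be read as claims
about real imagery.
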