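Package: visorient
Title: Orientation Detection with a Hubel-Wiesel Artificial Visual System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a feedforward artificial visual system for global
    orientation detection in binary images, modelled on the Hubel-Wiesel
    account of primary visual cortex. McCulloch-Pitts simple cells detect
    3-pixel line segments at 0, 45, 90 and 135 degrees within 3x3 local
    receptive fields; four complex cells pool same-orientation activations
    over the whole image; the most activated complex cell labels the
    object's orientation, with ties reported as ambiguous. Includes
    seedable generators for ideal oriented objects (lines, bars,
    rectangles, elongated blobs), background and whole-image pixel noise,
    an evaluation harness (accuracy tables, noise sweeps, spike-rate
    curves, confusion matrices), readers and writers for PGM, PNG and
    text-grid images, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
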