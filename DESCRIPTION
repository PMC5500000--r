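Package: LCRtrack
Title: Motion Stabilization and Local Calcium Release Detection in 2D
    Fluorescence Movies of Pacemaker Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 2D time-lapse fluorescence recordings of
    spontaneously beating cardiac pacemaker (sinoatrial node) cells. A
    curvature-based tracker follows the contracting cell's midline and a
    piecewise-affine triangular-mesh warp renders the cell motionless, so
    that each pixel reports a fixed cytoplasmic location. A spatiotemporal
    differential filter then detects Local Calcium Releases (LCRs), tracks
    their lifecycle (birth, propagation, splitting, collision, and death by
    stochastic attrition or by merging into the whole-cell transient), and
    reports per-event parameters such as path area, duration, period and
    amplitude. Includes a ground-truthed movie simulator, detection scoring,
    and a false-positive-rate control based on off-cell substacks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    signal,
    yaml,
    EBImage,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
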