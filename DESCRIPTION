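Package: annotrack
Title: Headless Annotation of Time-Lapse Movies with Arrows, Arrowheads
    and Circles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates time-lapse movies with custom arrows, arrowheads and
    circles along trajectories built from sparse landmark clicks. Clicks on
    each frame are fused by a component-wise median (so repeated clicks at
    the right position override miss-clicks), a dense per-frame trajectory
    is obtained by piecewise-linear interpolation between labeled frames,
    and parameterized symbol glyphs (DELTA, THICK, THIN, CIRCLE, POINTY)
    are placed along the trajectory, kept in a non-destructive overlay, and
    flattened into the pixel data for export. Reads movies from multipage
    TIFF stacks or folders of numbered single-frame TIFFs; writes multipage
    TIFF or uncompressed AVI. Includes a plain-text trajectory interchange
    format, a synthetic-movie fixture generator, and a command-line
    interface for batch annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
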