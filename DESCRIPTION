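Package: trophica
Title: Quantitative Trophic Ecology from Stomach Contents and Stable Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trophic-ecology analyses of fish diet and
    stable-isotope data: prey-specific diet indices (%N, %W, %PN, %PW, %FO,
    %PSIRI), randomized cumulative prey curves with an endpoint-slope
    sample-sufficiency test, diet-based fractional trophic-level estimation,
    permutational multivariate analysis (PERMANOVA, multivariate dispersion
    tests, canonical analysis of principal coordinates) on Bray-Curtis
    dissimilarities, and bivariate isotopic niche metrics (carbon and nitrogen
    ranges, convex hull area, centroid distance, nearest-neighbour spacing).
    Includes readers and writers for per-stomach count, weight and isotope
    tables, a synthetic-data generator that emulates multi-site, multi-year
    stomach and muscle-tissue isotope sampling, and a YAML-driven pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
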