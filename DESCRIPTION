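Package: ngrscreen
Title: Normalized Growth Rate Metrics for Imaging-Based Drug Screens
Version: 0.1.0
Authors@R:
    person("NGR Screen", "Developers", email = "ngrscreen@example.org",
           role = c("aut", "cre"))
Description: Quantifies drug response in imaging-based 2D and 3D cell culture
    screens using the Normalized Growth Rate (NGR). Computes well-level
    viability from brightfield and dead-cell (fluorescence) areas, normalizes
    fractional growth against vehicle and positive (staurosporine) controls,
    fits the sigmoidal growth-rate-inhibition (GR) dose-response equation with
    a single outlier-removal refit, and derives NGR50 and the normalized
    area-over-curve (AOC) sensitivity score. Includes signed AOC fold changes
    between mutant and wild-type lines, two-way ANOVA with Dunnett-style
    contrasts against a reference line, a seeded synthetic 384-well plate
    generator emulating a 7-point logarithmic titration imaged every 24 h,
    and a command-line pipeline wiring the stages end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
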