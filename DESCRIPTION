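Package: lstdown
Title: Downscaling Gridded Daily Maximum Air Temperatures with Satellite
    Land Surface Temperature Departures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Disaggregates coarse (~12 km) gridded daily maximum 2 m air
    temperatures to a ~1 km grid by adding rescaled spatial departures of a
    robust warm-season satellite land-surface-temperature composite
    (t_dis = t_l + R * (t_h - t_h_mean), R = 0.5 for daily maxima).
    Includes daily-extrema derivation from hourly forcing in local standard
    time, cloud-tolerant upper-half compositing, per-coarse-cell departure
    fields, station validation (mean difference and root mean square
    difference), raster and station table input/output, a command-line
    pipeline driver, and a seeded synthetic-world generator for end-to-end
    testing of urban-heat and coastal-gradient scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
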