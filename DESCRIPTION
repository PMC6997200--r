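Package: topoclimvel
Title: Fine-Grained Climate-Analog Velocity and Exposure of Protected-Area Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes class-binned climate-analog velocities from gridded
    bioclimatic surfaces (growing degree days, mean January temperature,
    climatic water balance) at two spatial resolutions, and summarises the
    climatic exposure of protected-area polygons: per-polygon mean velocities,
    top-5 percent velocity hotspots and their cross-variable overlap,
    paired fine-vs-coarse resolution comparisons with a generalized linear
    model of relative differences, and present-versus-future within-polygon
    climate-range overlap and gap analysis. Includes a synthetic topoclimatic
    landscape generator (correlated-noise elevation models, lapse-rate and
    cold-air-pooling temperature terms, orographic precipitation, coarse
    scenario delta fields, and random reserve polygons) so the full pipeline
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
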