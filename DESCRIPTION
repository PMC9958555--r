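Package: chairsts
Title: Sit-to-Stand Trunk and Thigh Kinematics from Chair-Embedded Range Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Measures trunk and thigh segment angles during sit-to-stand (STS)
    motion from two chair-embedded time-of-flight range finders, using a
    two-link planar inverse-geometry model (seat beam to thigh, backrest beam
    to trunk). Provides the full concurrent-validity pipeline against
    marker-based reference angles: Butterworth low-pass filtering, spline
    resampling, STS onset and flexion/extension phase segmentation, angular
    excursions, per-phase waveform similarity with Fisher r-to-z averaging,
    and across-trial agreement. A synthetic trial generator renders
    minimum-jerk STS trajectories under seven movement conditions into virtual
    laser distances and virtual marker trajectories via exact ray-segment
    geometry, with configurable noise and model-violation terms (body-surface
    offset, posterior knee-axis translation), so every stage is testable
    without hardware or subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
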