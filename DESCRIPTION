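Package: sonoyeast
Title: Ultrasonic Pulse-Echo Characterization of Yeast Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of pulse-echo ultrasound measurements of
    yeast suspensions for non-invasive bioprocess monitoring. Provides a
    physics-based synthetic waveform generator (buffer-rod delay line,
    impedance-mismatch echoes with phase inversion, additive measurement
    noise), the signal-processing chain that converts waveform records into
    speed-of-sound and attenuation-coefficient estimates via water-reference
    calibration, and study-level statistics: concentration-gradient
    regressions, one-way ANOVA with Tukey-Kramer HSD post-hoc comparisons and
    compact letter displays, and volume-weighted median particle size (x50)
    from binned size distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
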