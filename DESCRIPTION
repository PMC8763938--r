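Package: dualpath
Title: Dual-Pathway Hippocampus-Prefrontal Circuit and Photometry Analysis
Version: 0.1.0
Authors@R: person("dualpath", "maintainers", email = "maintainers@dualpath.dev", role = c("aut", "cre"))
Description: Analysis stack for studies of radially segregated
    hippocampus-to-prefrontal projection neurons: Gaussian mixture model
    clustering of straightened-axis cell coordinates with BIC model
    selection, frequency-multiplexed dual-colour fiber-photometry
    demodulation and conditioning, peri-event window statistics,
    channelrhodopsin-assisted circuit mapping (CRACM) amplitude and
    connectivity quantification, intrinsic electrophysiology features,
    elevated-plus-maze zone analysis with closed-loop stimulation gating,
    and seeded synthetic-data generators for every input so the full
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
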