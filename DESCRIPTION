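Package: sockeica
Title: ICA-Based Denoising and Event-Related ICA for 4D fMRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for automated denoising of 4D fMRI by
    spatial independent component analysis followed by feature-based artifact
    classification (smoothness, edge activity, ventricular activity, and
    temporal-frequency noise), aggressive regression removal of artifact
    components, and event-related ICA: finite-impulse-response deconvolution
    of peri-event BOLD responses, ICA of those responses with run-stability
    clustering, and Gaussian mixture-model z-maps.  Includes a synthetic fMRI
    phantom generator with ground-truth event-locked sources and structured
    artifacts so that every pipeline stage can be tested offline, plus NIfTI-1
    and event-timing file input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
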