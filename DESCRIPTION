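Package: vitalcam
Title: Contactless Vital-Sign Estimation from RGB and Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates heart rate, respiration rate and forehead body
    temperature from paired RGB and thermal camera streams without skin
    contact. Facial landmarks define three regions of interest (forehead
    point for temperature, forehead box for the remote blood volume pulse,
    nostril box for respiration); a scale-plus-translation affine map
    registers RGB coordinates onto the thermal grid. The cardiac chain
    band-passes the per-frame colour-channel means, separates sources with
    JADE independent component analysis, isolates the pulse by empirical
    mode decomposition and converts peak intervals to beats per minute.
    The respiratory chain averages CLAHE-enhanced nostril pixels and
    converts breath-peak intervals to breaths per minute. A template
    correlation signal quality index screens unreliable 15-second windows,
    and a horizontal head-deflection gate discards non-frontal frames.
    Includes a synthetic fixture generator with known ground truth,
    sliding-window orchestration, evaluation utilities (MAE, Bland-Altman)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
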