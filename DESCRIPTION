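Package: qcucvp
Title: Central Venous Pressure Estimation from Quantitative Compression
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for noninvasive central venous pressure (CVP)
    estimation from quantitative compression ultrasound (QCU) of the internal
    jugular vein. Extracts the collapse force (the minimum probe force that
    fully occludes the vein's short-axis cross-section) and its uncertainty
    from synchronized force and segmented-area recordings, calibrates collapse
    force and hydrostatic offset against invasive CVP by ordinary least
    squares, converts bedside jugular venous pulsation height readings to
    pressure, computes uncertainty-overlap accuracy against the invasive
    standard, and reconstructs the venous pressure waveform from constant-force
    captures with a collapsible-tube inverse model. Includes a physiological
    simulator of CVP waveforms, carotid pressure, and full QCU captures, and
    the bundled 11-subject pilot-study table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
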