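Package: pmsagree
Title: Mean Systemic Filling Pressure Estimation and Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates mean systemic filling pressure (Pms) in ventilated
    patients by two routes and quantifies their agreement. The analogue
    estimate Pmsa is computed at the bedside from right atrial pressure,
    mean arterial pressure, cardiac output and patient anthropometrics
    (Parkin's algorithm); the reference estimate Pms-Insp is the zero-flow
    intercept of a venous return curve fitted to inspiratory-hold
    measurements at incremental airway plateau pressures. The package
    provides the hemodynamic calculations, venous-return-curve fitting with
    full fit diagnostics, a method-comparison suite (Bland-Altman limits of
    agreement, two-way mixed-model intraclass correlation with absolute
    agreement, exact rank tests, conversion coefficients, post-hoc ICC
    power), a Guytonian virtual-patient simulator with known ground truth,
    and CSV readers/writers plus a command-line interface for the full
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
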