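Package: heelpad
Title: Viscoelastic Material Properties of the Plantar Heel Pad from
    Stance-Phase Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates in vivo viscoelastic material properties of the
    plantar heel fat pad from synchronized stance-phase recordings of pad
    thickness and heel-ground contact force. Derives compressive strain,
    stress and strain rate per frame, fits a modified Kelvin-Voigt model
    (parallel linear elastic and nonlinear viscous element) by ordinary
    least squares, and quantifies hysteresis via the energy dissipation
    ratio of the stress-strain loop. Includes a forward simulator of
    stance-phase recordings for validation and power studies, a
    normality-routed group-comparison framework (Student/Welch t,
    Wilcoxon, ANOVA, Brown-Forsythe, Kruskal-Wallis with matched post hoc
    tests), Pearson correlation matrices, file dialects for pressure-plate
    XML and thickness/stance CSV exports, and a command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
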