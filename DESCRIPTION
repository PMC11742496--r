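Package: fameprops
Title: Fatty-Acid Profiling, Biodiesel Property Panels, and Microalgal
    Culture Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning GC-MS fatty acid methyl ester (FAME)
    composition tables into biodiesel fuel-property panels, and for
    analysing microalgal cultivation experiments. Parses fatty-acid
    shorthand nomenclature (e.g. "C20:5n3"), computes class totals and
    the mass-weighted average degree of unsaturation (ADU), maps ADU to
    kinematic viscosity, specific gravity, cloud point, cetane number,
    iodine value, and higher heating value through empirical linear
    correlations, and judges compliance against the EN 14214 and ASTM
    D6751 biodiesel standards. Also quantifies fucoxanthin from
    dual-wavelength extract absorbances, computes biomass, lipid and
    fucoxanthin productivities from culture time series, compares
    treatments by ANOVA with Tukey HSD compact letter displays, and
    simulates factorial cultivation experiments with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
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
    multcomp
Config/testthat/edition: 3
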