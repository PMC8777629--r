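Package: salb
Title: Thermodynamic Modeling of Solvent-Assisted Lipid Bilayer Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts supported lipid bilayer (SLB) coverage formed by the
    solvent-assisted (SALB) method from chamber, lipid, temperature and
    concentration parameters using a two-state free-energy model; converts
    QCM-D frequency shifts to areal mass via the Sauerbrey relation; infers
    the chemical-potential difference between suspended and supported lipids
    from coverage-versus-concentration endpoint data by through-origin least
    squares; and maps temperature-concentration phase diagrams of SLB quality
    regimes (incomplete, complete, supersaturated). Includes seeded synthetic
    data generators for endpoint datasets, temperature series and solvent
    washout traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
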