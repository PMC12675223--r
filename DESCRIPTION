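Package: banffdx
Title: Rule-Based Banff Classification of Kidney Allograft Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated assignment of Banff rejection categories to kidney
    allograft biopsies from ordinal lesion scores (t, i, v, g, ptc, C4d,
    cg, cv, ci, ct, ptcbm, t-IFTA, i-IFTA), C4d immunofluorescence, and
    donor-specific antibody status, with explicit handling of
    ABO-incompatible grafts in which peritubular-capillary C4d positivity
    does not count as evidence of antibody interaction. Classifies active
    and chronic active antibody-mediated rejection, acute (grades IA-III)
    and chronic active T-cell-mediated rejection, borderline changes,
    interstitial fibrosis and tubular atrophy, and C4d staining without
    rejection, selecting a primary category by a fixed clinical priority.
    Includes pathologist-versus-engine concordance analysis (flow tables,
    stratified agreement rates, Cohen's kappa, discrepancy extraction), a
    seeded synthetic-cohort generator driven by rejection sampling against
    the engine itself, CSV input/output, and packaged row-level fixtures
    of published discrepancy cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
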