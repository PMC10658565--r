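Package: xtaldepot
Title: Crystalline Protein Depots: Lattice Density, Dissolution
    Kinetics, and Thermal Crystallization Propensity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates crystalline protein suspensions as long-acting
    intravitreal depots. Computes unit-cell volumes, Matthews
    coefficients and solvent content for crystal polymorphs and ranks
    their packing density; couples Noyes-Whitney crystal dissolution to
    first-order vitreous elimination in a two-compartment
    pharmacokinetic model with zinc-dependent lattice solubility;
    measures crystal dissolution from time-lapse micrographs by
    projected-area tracking with one-way ANOVA group comparison;
    extracts thermal unfolding temperatures and aggregation onsets from
    calorimetry and static-light-scattering curves and classifies
    crystallization propensity; and generates seeded synthetic inputs
    (crystal-form tables, dissolving-crystal image stacks, thermograms,
    scattering traces) with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
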