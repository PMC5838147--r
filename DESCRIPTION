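Package: sapsa
Title: Ensemble Solvent-Accessible Polar Surface Area and Peptide
    Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the ensemble-averaged solvent-accessible polar
    surface area (SAPSA) of cyclic-peptide conformer ensembles by
    Shrake-Rupley integration on the probe-center (accessible) surface,
    classifies membrane permeability from the resulting descriptor, and
    decomposes side-chain effects into direct-shielding and
    conformational components via trajectory editing.  A second half of
    the package performs non-compartmental pharmacokinetic analysis
    (AUC, terminal half-life, clearance, steady-state volume, oral
    bioavailability) and hepatic first-pass quantification from paired
    portal/jugular-vein sampling.  Seeded synthetic generators for
    conformer ensembles (torsional Metropolis Monte Carlo) and
    concentration-time profiles (one-compartment with first-order
    absorption and hepatic extraction) support end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
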