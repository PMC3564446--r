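Package: redoxtime
Title: Quantitative Redox Proteomics of Chronologically Aging Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for time-resolved differential thiol-trapping (OxICAT)
    redox proteomics in postmitotic Saccharomyces cerevisiae. Quantifies
    per-peptide percent thiol oxidation from light/heavy isotope-coded
    affinity tag (ICAT) peak pairs in centroided spectra, aggregates
    biological replicates into per-day oxidation matrices, imputes missing
    values, clusters oxidation trajectories (k-means plus a rule-based
    classifier into seven trajectory classes), detects early-oxidation
    targets, computes amino-acid-type enrichment around identified cysteines
    with chi-square comparisons between classes, derives glutathione redox
    potentials via the Nernst equation and NADPH-decline onsets, and
    integrates all signals into an ordered timeline of redox events under
    standard, caloric-restriction and hypometabolic (water) cultivation.
    A synthetic-data generator produces trajectories, peptide libraries,
    label-pair spectra and metabolite curves with known ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
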