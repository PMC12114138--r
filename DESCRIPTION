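Package: oglyco
Title: O-Glycan Profiling and O-Glycosylation Site Localization for
    Mucin-Type Glycoproteins
Version: 0.1.0
Authors@R:
    person("FSH-CTP", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing mucin-type O-glycosylation of
    recombinant glycoproteins such as rhFSH-CTP. Implements monoisotopic
    mass arithmetic for peptides, glycans, 2-AB labeled glycan derivatives
    and glycopeptides; in-silico OpeRATOR O-glycoprotease plus sialidase
    digestion with missed cleavages and glycoform enumeration; theoretical
    HCD (b/y) and EThcD (c/z) fragment ion generation including
    glycan-retaining and HexNAc-remnant ions; ppm-tolerance peak matching
    and closed-search glycopeptide identification; tiered O-glycosylation
    site localization (direct bracketing, single-candidate, HexNAc-remnant
    and enzyme-specificity evidence); released 2-AB glycan chromatogram
    assignment and quantitation (normalized peak-area percentages,
    replicate RSD, linearity, recovery rate); and seeded synthetic data
    generators for MS/MS spectra and fluorescence area tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
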