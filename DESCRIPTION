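Package: sumoKGG
Title: Remnant-Based Profiling of SUMO and Ubiquitin Modification Sites
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Computational toolkit for diglycyl-lysine (KGG) remnant
        profiling of ubiquitin-like modifications. Models protease
        cleavage specificity (trypsin, wild-type alpha-lytic protease),
        predicts the remnant left on substrate lysines after digestion of
        a conjugated modifier, computes monoisotopic masses and fragment
        ions for branched remnant peptides, post-processes peptide-spectrum
        matches (heavy/light SILAC merging, target-decoy FDR, binomial
        site localization, collapsing to unique sites), aggregates
        site-level SILAC ratios with change flagging, classifies sites
        against SUMO consensus motifs, and generates seeded synthetic
        data (proteomes, planted sites, PSM tables, spectra) so the whole
        pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Biostrings
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
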