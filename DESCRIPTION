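Package: protrin
Title: Residue Interaction Networks, Surface Charge Profiles, and
    Differential-Residue Analysis for Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative structural analysis behind
    protein acid-stability studies: residue interaction networks built from
    PDB coordinates with six geometric contact types (hydrogen bonds, Van der
    Waals, disulfide, ionic, pi-pi stacking, pi-cation) at configurable
    distance cutoffs; Shrake-Rupley solvent-accessible surface area with
    relative-SASA surface classification and acidic/basic charge profiling;
    conservation-based differential-residue (group A/B) classification of
    alignment columns with substitution-set mutant design and single-linkage
    spatial region detection; clade branch-length statistics from phylogenies;
    and F-test-then-t-test cluster comparisons with compact letter displays.
    Includes seeded synthetic-data generators that plant ground-truth
    interactions, alignment columns, charge compositions, and clade rate
    contrasts so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ape,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
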