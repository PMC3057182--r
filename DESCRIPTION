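Package: cpassr
Title: Comparison of Protein Active-Site Structures (CPASS v.2)
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares experimentally ligand-defined protein binding sites to
    infer functional relationships in the absence of global sequence or
    structure similarity. Extracts binding sites (all residues within 6
    Angstrom of a bound ligand, or a manually supplied residue list) from
    PDB-format structures, aligns two sites without regard to sequence order,
    and scores their similarity with a distance-weighted BLOSUM62 replacement
    probability function augmented by per-residue solvent-accessible surface
    area differences, C-beta positions, and the root-mean-square deviation
    between the bound ligands (the CPASS v.2 similarity function). Includes a
    deduplicated binding-site database with pairwise, one-versus-all and
    list-based search modes, ROC and score-distribution evaluation against
    Enzyme Commission annotations, and a synthetic-structure generator for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    stats,
    utils,
    parallel,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
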