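Package: allopath
Title: Allosteric Communication Pipelines from Torsion Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for allosteric communication in proteins from
    conformational ensembles. Computes mutual information between residue
    torsion-angle distributions, builds a maximum-MI allosteric graph,
    extracts Dijkstra shortest pathways between distant residue pairs,
    clusters pathways into structurally proximal pipelines and derives
    per-residue hub scores. Also provides standard trajectory descriptors
    (RMSD, RMSF, GROMOS/Daura conformational clustering, C-alpha PCA),
    interface contact-frequency tables, pairwise nonbonded interaction
    energies, PDB structure and multi-model ensemble I/O, generic residue
    numbering, and synthetic ensemble generators with planted ground
    truth so every stage is testable without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
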