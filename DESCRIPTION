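Package: dimerlens
Title: Contact, Conformation and Secondary-Structure Analysis of Protein
    Dimerization Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for multi-model coordinate ensembles of
    protein monomers and dimers, built around the analyses used to
    characterize Josephin-Domain self-association: per-residue inter-monomer
    contact probability under a distance cutoff, residue-residue contact
    maps, Shrake-Rupley solvent-accessible surface and buried contact
    surface, Kabsch superposition with RMSD and RMSF profiles, radius of
    gyration with one- and two-component Gaussian decomposition of its
    distribution into open- and closed-hairpin states, backbone dihedrals
    with Ramachandran classification, and a hydrogen-bond based
    secondary-structure assigner with per-residue helix/sheet/coil
    occupancies. Includes a seeded synthetic two-chain trajectory generator
    that plants ground-truth contact schedules, compactness states,
    helix-coil switching and region-exposure events so every analysis stage
    is testable without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
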