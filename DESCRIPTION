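Package: driftfold
Title: Drift-Diffusion Kinetic Protein Folding at the C-Alpha Level
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based secondary-structure prediction driven by per-residue
    hydrophobicity and titration charge, a coarse-grained three-force field
    (Coulomb, dielectric displacement, isotropic thermal force) with an
    entropy-modified drift mobility, and a Markov pivot-torque folding
    simulator that records a per-step work/energy trace. Includes C-alpha
    PDB and FASTA input/output, Kabsch RMSD and per-residue secondary
    structure accuracy metrics, and a deterministic synthetic sequence
    generator for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
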