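Package: allopocket
Title: Allosteric Site Prediction from Elastic Network Perturbation and
    Residue Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates putative allosteric binding sites on protein
    complexes by combining two coarse-grained network views of a
    structure. An essential-site scan perturbs a Gaussian network model
    residue by residue (inserting side-chain heavy-atom nodes) and
    measures the mean percent shift of the ten slowest eigenvalues,
    z-scored across residues; a residue interaction network weighted by
    normalized heavy-atom contact counts yields betweenness hub
    residues. Surface pockets (detected on a grid or parsed from
    Fpocket output) that contain solvent-accessible residues flagged by
    both methods are reported as consensus allosteric-site candidates.
    Includes a seeded synthetic-structure generator with known
    hinge/bridge/cavity ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
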