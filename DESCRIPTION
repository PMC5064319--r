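Package: psnpath
Title: Dynamic Protein Structure Networks and Allosteric Pathway Analysis
    for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds persistence-filtered protein structure networks (PSNs)
    from molecular dynamics trajectories and analyses allosteric
    communication on them. Detects per-frame salt bridges, hydrogen bonds
    and hydrophobic contacts, reduces them to interaction-persistence
    fractions, estimates the significance threshold from the largest
    hydrophobic connected component, and scores residue-to-residue
    communication by shortest-path enumeration: the communication
    robustness (CR) index and selective betweenness (SB). Also provides
    sampling-convergence diagnostics (Calpha principal component analysis,
    cosine content, root-mean-square inner product across replicas),
    RMSD-matrix conformational clustering (GROMOS and single-linkage),
    and a seed-deterministic synthetic trajectory generator with planted
    collective modes, planted contact persistence and planted allosteric
    chains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    pracma,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
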