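Package: chromoswarm
Title: 3D Chromosome Structure Reconstruction from Hi-C Contact Matrices by Particle Swarm Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs three-dimensional chromosome structures from Hi-C
    interaction-frequency (IF) contact matrices using particle swarm
    optimization. Converts IF values to expected pairwise distances via
    D = 1/IF^beta, optimizes bead coordinates under a selectable loss
    (RMSE, MSE, SSE, or Huber), and scores final structures by Spearman and
    Pearson correlation between realized and expected distances. Includes
    readers and writers for square and three-column sparse plain-text
    contact matrices, a coarse-grained PDB writer, a synthetic ground-truth
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    jsonlite
Config/testthat/edition: 3
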