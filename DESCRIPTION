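Package: edjshape
Title: Geometric Morphometrics of the Enamel-Dentine Junction and
    Enamel Proteome Damage Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Shape analysis of 3D landmark and semilandmark
    configurations sampled on the enamel-dentine junction (EDJ) of
    lower molars: mirroring of left antimeres, generalized Procrustes
    superimposition, principal component analysis, canonical variate
    analysis on a cross-validation-selected subset of principal
    component scores, jackknife (leave-one-out) classification,
    typicality probabilities from Mahalanobis distances, a posteriori
    projection of held-out specimens, allometry tests against centroid
    size, and reconstruction of extreme shapes along canonical axes.
    A companion set of paleoproteomic post-processing tools computes
    deamidation and arginine-to-ornithine damage rates from peptide
    evidence tables, reconstructs per-sample consensus protein
    sequences from aligned peptide fragments, collapses the isobaric
    isoleucine/leucine ambiguity by parsimony, concatenates
    per-protein alignments into phylogeny-ready supermatrices, and
    reports single amino acid polymorphisms. Synthetic-data generators
    with known ground truth support testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    Biostrings,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
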