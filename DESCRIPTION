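Package: surfpatch
Title: Rotation-Invariant Residue Patch Descriptors for Protein Surface
    Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a protein chain's solvent-excluded surface by
    circular Calpha-centered patches summarized as residue-specific distance
    distributions (DD2), residue co-occurrences (RC) and their combination
    (DRC), plus the pooled distance-distribution baseline (DD1). Descriptors
    are invariant to rotation, translation, mirroring and residue input
    order, and have fixed length independent of chain size, so chains are
    compared by plain Euclidean distance. Includes PDB and MSMS vertex-file
    input with a Shrake-Rupley accessibility fallback for surface-residue
    selection, database ranking with enrichment-factor and precision-recall
    evaluation, a classification harness, and a synthetic surface generator
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
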