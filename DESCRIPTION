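Package: seqgauge
Title: Gauge Freedoms and Embedding Distillation for Linear
    Sequence-Function Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing the gauge freedoms of linear models of
    sequence-function relationships that are equivariant under
    position-specific character permutations (PSCP). Builds generalized
    one-hot and simplex models from position-set specifications, constructs
    the matrix representations under which their embeddings and parameters
    transform, and implements an embedding-distillation procedure (a Maschke
    decomposition followed by thinning and sorting similarity
    transformations) that counts gauge freedoms analytically, produces a
    sparse {-1,0,+1} basis for the gauge space, and yields a sparse
    gauge-fixing projection. A brute-force design-matrix oracle certifies
    every result on small sequence spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
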