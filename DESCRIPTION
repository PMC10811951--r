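Package: genopca
Title: Fast Principal Components of Genomic Similarity Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the leading eigenvectors (principal components) of five
    genomic similarity matrices -- covariance, Jaccard, approximate Jaccard,
    weighted Jaccard, and the robust/non-robust genomic relationship matrix --
    directly from a sparse loci-by-individuals genotype matrix. A unified
    factored-operator representation keeps the genotype matrix sparse, and a
    randomized SVD with power iteration extracts the top-k components without
    ever forming a similarity matrix or densifying the genotypes. The exact
    Jaccard matrix, which admits no Gram factorization interface, is replaced
    by a conservative approximation whose eigenvector error is controlled by
    Davis-Kahan sin(theta) bounds, with an a-priori variant based on
    Gershgorin discs. Includes a genotype simulator (Bernoulli, binomial
    dosage, and stratified Balding-Nichols populations), dense reference
    implementations of all similarity matrices used as oracles, Matrix Market
    and VCF readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
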