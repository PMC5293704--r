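Package: dfptools
Title: Database Fingerprints and Entropy-Based Diversity Analysis of
    Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compresses an entire compound library's binary molecular
    fingerprint matrix (MACCS-166, PubChem-881, or any fixed-length binary
    scheme) into a single database fingerprint (DFP) by thresholding per-bit
    set probabilities, and provides the surrounding diversity analytics:
    Shannon entropy of the per-bit probability profile as a library diversity
    metric, Differential Shannon Entropy for selecting informative bit
    positions across libraries, Tanimoto and city-block inter- and intra-set
    comparison, and k-means grouping of libraries in entropy-similarity space.
    Includes FPS v1 and CSV fingerprint I/O, an optional OpenBabel adapter for
    computing MACCS keys from structures, and seeded generators for synthetic
    Bernoulli fingerprint libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (optional, for computing MACCS keys from
    SMILES/SDF structure files)
Config/testthat/edition: 3
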