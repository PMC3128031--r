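Package: ssrkit
Title: Variety Identification from SSR Fingerprints with Nei-Li Kernels
    and Marker Kit Selection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for supervised variety identification from SSR
    (microsatellite) genotyping tables.  Encodes multi-allelic SSR
    genotypes through the Nei-Li (Dice) similarity, which forms a
    positive definite kernel over genotyped samples, and trains kernel
    discriminant classifiers (kernel Fisher discriminant analysis and
    kernel PCA followed by LDA) on the resulting Gram matrices.
    Selects minimal marker "kits" with a greedy filter driven by
    uncertainty-coefficient Z-scores, with MIFS and mRMR baselines,
    cross-validated benchmarking with in-loop selection, exhaustive
    subset search, and a synthetic genotype generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
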