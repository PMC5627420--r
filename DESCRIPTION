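Package: somatrio
Title: Somatic Mutation Landscape Analysis for Tumor-Normal Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome tumor-normal trios (one matched
    normal plus two tumors from the same patient), motivated by hypermutated,
    mismatch-repair-deficient cancers. Implements multi-caller consensus
    filtering of somatic variant calls with population-frequency removal,
    96-trinucleotide-context mutation spectra with cosine matching and
    non-negative least-squares refitting against a signature catalog,
    sliding-window minor-allele-frequency detection of arm-level copy-number
    loss and loss-of-heterozygosity counting from germline heterozygous SNVs,
    inter-tumor landscape comparison, and germline-versus-somatic
    truncating-mutation enrichment testing. A seeded synthetic-data generator
    produces tumor-normal trios with known ground truth (purity, planted arm
    losses, planted signature, caller error rates) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
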