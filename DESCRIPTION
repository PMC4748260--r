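Package: imorn
Title: Classification and Design of Immunomodulatory RNA Oligonucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Support-vector-machine classification of short single-stranded RNA
    oligonucleotides (17-27 nt) as immunomodulatory (IMORN) or
    non-immunomodulatory, from k-mer composition and terminal one-hot encodings.
    Includes the supporting analyses used to characterise the two classes:
    class-wise composition statistics with per-feature t-tests, two-sample-logo
    style position enrichment tables, discriminative gapped motif mining, and
    secondary-structure classification (extended linear vs stem-loop) from
    dot-bracket structures with hairpin-loop uridine summaries. Evaluation
    follows stratified five-fold cross-validation, external validation on a
    held-out split, and a repeated Monte-Carlo 80/20 sampling protocol with
    sensitivity, specificity, accuracy and Matthews correlation coefficient.
    Design utilities cover virtual screening of oligonucleotide libraries,
    exhaustive single-site analog generation, immunomodulatory-region scanning
    of longer RNAs, and per-strand siRNA immunotoxicity screening. A seeded
    synthetic-sequence generator (class-biased nucleotide frequencies, optional
    planted gapped motifs) makes every analysis reproducible without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
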