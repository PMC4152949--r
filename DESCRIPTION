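Package: psedhs
Title: Predicting DNase I Hypersensitive Sites from Pseudo Dinucleotide
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based classification of DNase I hypersensitive sites
    (DHS). DNA sequences are encoded as pseudo dinucleotide composition
    (PseDNC) vectors that combine the 16 overlapping dinucleotide
    frequencies with lambda sequence-order correlation factors derived
    from six dinucleotide structural properties (twist, tilt, roll,
    shift, slide, rise). Classification uses a radial-basis-function
    support vector machine with joint grid-search optimization of the
    encoding weight, tier count, cost and kernel width by stratified
    cross-validation. Includes greedy identity-threshold redundancy
    filtering of training sets, jackknife and k-fold evaluation
    reporting sensitivity, specificity, accuracy and the Matthews
    correlation coefficient, and a first-order Markov simulator of
    GC-dinucleotide-enriched sequence sets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
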