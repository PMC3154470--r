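Package: sirnadesign
Title: Design of Fully Complementary and Deliberately Mismatched siRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts silencing efficacy of 19- and 21-nt short interfering
    RNAs (siRNAs) with an epsilon support-vector regression over nucleotide
    composition, positional one-hot and thermodynamic sequence encodings, and
    designs deliberately mismatched (mutant) siRNAs by enumerating base
    substitutions, deducting experimentally derived mismatch penalties from
    the complementary predicted efficacy, and ranking candidates by the
    resulting mismatch efficacy (ME). Includes an mRNA scanning front-end,
    optional target-site accessibility via an RNAplfold-compatible backend,
    an allele-discrimination mode for SNP-selective silencing, and a
    synthetic-data generator with a planted sequence-to-efficacy signal for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
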