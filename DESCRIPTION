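Package: cisPatterns
Title: Mining Sequence Patterns Around cis Non-Proline Peptide Bonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 11-residue sequence windows around peptide bonds from
    omega-dihedral annotations, discovers maximal regular-expression-type
    patterns (TEIRESIAS-style) in the rare cis non-proline windows under
    optional chemical or structural residue-equivalency alphabets, scores
    each pattern's cis propensity against the large trans background with a
    class-imbalance-corrected score and a Markov-model log-likelihood,
    selects a non-redundant pattern set by greedy coverage with a false
    discovery rate, evaluates a pattern-based cis/trans classifier under a
    split-and-resample protocol, and compares retained patterns against a
    functional motif library with a chi-square enrichment test. Includes a
    synthetic-data generator with planted degenerate motifs so every stage
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
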