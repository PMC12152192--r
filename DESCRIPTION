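Package: ibmscreen
Title: Proteome-Wide Screening for IAP-Binding Motifs Unmasked by
    N-Terminal Dipeptidyl Peptidase Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to screen a protein-coding proteome (e.g. the NCBI CCDS
    set) for IAP-binding motifs (IBMs) that are hidden behind N-terminal
    processing sites of methionine aminopeptidase (MAP) and the dipeptidyl
    peptidases DPP8/9.  Processing rules and motif consensus patterns are
    data-driven residue-class patterns; the engine enumerates the possible
    neo-N-termini of each protein and tests the exposed tetrapeptide against
    a configurable IBM consensus.  The package also classifies observed MS
    N-terminal peptides (free or acetylated) into processing states, and
    implements a label-free interactomics enrichment workflow: min-valid
    filtering, lower-tail normal imputation of missing values, equal-variance
    two-sample t-tests and a -log10(p) significance cut-off.  A synthetic
    data generator plants proteomes, peptide sets and LFQ matrices with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
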