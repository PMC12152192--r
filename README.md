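# ibmscreen

Proteome-wide screening for IAP-binding motifs (IBMs) unmasked by N-terminal
dipeptidyl peptidase processing, plus the MS workflows that accompany such a
screen.

## The problem

An IBM is a four-residue motif that, when present free and unmodified at the
very N-terminus of a protein, binds inhibitor-of-apoptosis proteins (IAPs) —
E3 ubiquitin ligases such as XIAP and BIRC2 — and can thereby target the
protein for degradation. Most proteins never expose such a motif: it sits one
or two processing events below the surface. Methionine aminopeptidase (MAP)
removes the initiator methionine, and the cytosolic dipeptidyl peptidases
DPP8/9 can then remove a further X-P dipeptide, so a motif hidden at residues
3–7 of the coding sequence can suddenly become N-terminal. `ibmscreen` asks,
for every protein in a coding proteome (e.g. the NCBI CCDS set): *does a
DPP8/9-cleavable N-terminus conceal an IBM?*

## The model

N-terminal processing is modelled as three anchored residue-class patterns
with a cut point (`^` negates a class, `|` marks the scissile bond):

| rule | pattern | neo-terminus |
|---|---|---|
| MAP | `M \| [^D]` | offset 2 |
| DPP9 long | `M[^DE]P \| [^P]` | offset 4 (MXP start) |
| DPP9 short | `MP \| [^P]` | offset 3 (MP start) |

Each exposed neo-terminus is tested against the IBM consensus

```
[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILVWY]
```

so e.g. `SVPA`, `AVPI`, `AVPA` and `STPL` match while `SGLK` and `NVLA` do
not. A protein is a *hidden-IBM candidate* when a DPP9-exposed terminus
(offset 3 or 4) matches. Both rules and motif are data, not code, and can be
replaced from plain-text definition files.

The package also provides:

* **Peptide state classification** — assigns observed MS N-terminal peptides
  (free or acetylated) to `UNPROCESSED` / `MAP_ONLY` / `DPP9_SHORT` /
  `MAP_DPP9` / `INTERNAL` states of a protein, and summarizes per-state
  intensities across conditions.
* **Enrichment statistics** for peptide pull-downs / IPs — log2 transform,
  min-valid filtering (2-of-3 pull-down preset, 3-of-3 IP preset),
  Perseus-style lower-tail imputation of missing values (draws from
  `Normal(mu - downshift*sigma, (width*sigma)^2)`; downshift 1.8 / width 0.3
  for pull-downs, 2.0 / 0.3 for IPs), equal-variance two-sample t-tests, and
  the significance rule `-log10(p) >= 2` with positive difference.
* **Synthetic data generators** — planted proteomes, peptide sets and LFQ
  matrices with exact, machine-checkable ground truth.

## Worked example

```r
library(ibmscreen)

# AK2's N-terminus: MAP-cleavable, DPP9 "long" site, IBM hidden at offset 4
scan_record("MAPSVPAAEPEYPKG")[c("dpp9_long", "hidden_ibm")]
#> $dpp9_long
#> [1] TRUE
#> $hidden_ibm
#> [1] TRUE

# a planted proteome with 10% hidden-IBM entries screens to exactly 100/1000
pp <- gen_proteome(1000, c(ibm_p2 = 0.05, dpp9_long_hidden_ibm = 0.10,
                           dpp9_long_no_ibm = 0.05, dpp9_short_hidden_ibm = 0,
                           dpp9_short_no_ibm = 0.05, none = 0.75), seed = 7)
run_screen(pp$records, pp$gene_map)
#> Hidden-motif screen over 1000 entries (750 mapped genes)
#>   motif at P2:               50 entries (50 genes)
#>   DPP8/9 cleavage sites:    200 entries (150 MXP long + 50 MP short)
#>   hidden motif candidates:  100 entries (100 genes)

# the classical t-test oracle case: below the -log10 p cut-off of 2
x <- matrix(1:6, 1, dimnames = list("p", paste0("S", 1:6)))
t_test_two_sample(x, setNames(rep(c("A", "B"), each = 3), colnames(x)))
#>   protein difference         t df          p neg_log10_p ...
#> 1       p         -3 -3.674235  4 0.02131164    1.671383
```

`run_screen` counts proteome *entries* (one CCDS = one protein record) and,
separately, unique mapped gene symbols; `1787 + 1678`-style long/short
breakdowns appear in the summary as `n_dpp9_long` / `n_dpp9_short`. A full
genome screen takes a CCDS protein FASTA and a BioMart accession→gene TSV:

```sh
inst/exec/ibmscreen screen --fasta CCDS_protein.faa --gene-map biomart.tsv --out out/
inst/exec/ibmscreen compare --candidates out/candidates.tsv --external substrates.txt
```

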