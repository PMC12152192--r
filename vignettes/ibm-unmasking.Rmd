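---
title: "Screening proteomes for IAP-binding motifs hidden behind DPP8/9 cleavage sites"
author: "ibmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for IAP-binding motifs hidden behind DPP8/9 cleavage sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibmscreen)
```

## Background

IAP-binding motifs (IBMs) are short N-terminal signatures through which
proteins such as SMAC/DIABLO (`AVPI`) engage inhibitor-of-apoptosis proteins.
An IBM is only functional when it sits free and unmodified at the very
N-terminus; cells keep most IBMs inert by burying them behind upstream
residues or by N-terminal acetylation. Two ubiquitous processing activities
can change that: methionine aminopeptidase (MAP) removes the initiator
methionine, and the cytosolic dipeptidyl peptidases DPP8/9 remove an
additional dipeptide ending in proline. A protein whose coding sequence
carries an IBM at residues 3–7 therefore holds a *conditional* degron: it is
exposed only where DPP8/9 are active and the new terminus escapes
acetylation. `ibmscreen` implements the computational side of this biology:
a proteome-wide screen for such hidden motifs, a classifier for observed MS
N-terminal peptides, and the label-free enrichment statistics used to call
IAP interactors in peptide pull-downs.

## The processing model

Processing is modelled by three anchored patterns over the unmodified coding
sequence (position 1 = initiator Met). Each position holds either an allowed
residue set or an excluded set; `|` marks the cut:

* `MAP: M | [^D]` — Met excision whenever residue 2 is not Asp.
* `DPP9_LONG: M[^DE]P | [^P]` — an M-X-P start (X not D/E, residue 4 not P):
  after Met excision DPP8/9 remove the X-P dipeptide, exposing offset 4.
* `DPP9_SHORT: MP | [^P]` — an M-P start (residue 3 not P): DPP8/9 remove
  the M-P dipeptide directly, exposing offset 3.

Three consequences are worth making explicit, and are asserted as properties
in the test suite:

* any sequence with a long site is MAP-cleavable (the long rule's position-2
  class is a subset of MAP's), so the long state is reported with the rule
  chain `MAP, DPP9_LONG`;
* long and short sites are mutually exclusive (residue 3 must be P for one
  and not-P for the other), so site counts add exactly;
* the rules are *anchored full-sequence patterns*. Sequential composition —
  e.g. DPP9 acting repeatedly, or acting on some other peptidase's product —
  is deliberately not modelled; the screen walks exactly the state space
  {unprocessed, MAP, DPP9 short, MAP+DPP9 long}.

The MAP rule is a knowing simplification of true MAP specificity (which
depends on the size of residue 2, not only on Asp). It is kept as stated
because the screen's point is reproducible rule application, not peptidase
biochemistry; users can load alternative rules from a text file in the same
notation (`read_rules()`).

Non-standard residues (B, J, O, U, X, Z) satisfy *no* position constraint,
not even negated classes. A negated class is interpreted as "any standard
residue except ...". This is the conservative choice: an uncertain residue
never creates a cleavage site or a motif match.

## The motif and the screen

The default IBM consensus is
`[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILVWY]`, a deliberately loose
four-position pattern. `SVPA`, `AVPI`, `AVPA` and `STPL` match; `SGLK` and
`NVLA` do not. One documented edge: HtrA2's `AVPS`, routinely called an IBM
in the literature, fails this consensus (Ser is not in the position-4
class). We keep the consensus as defined and expose the motif as data —
`motif_pattern("IBM_S4", "[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILSVWY]")`
admits it — rather than silently widening the default.

`run_screen()` computes per record:

* `ibm_at_p2`: residues 2–5 match the motif — the terminus exposed by Met
  excision alone. No explicit MAP-cleavability check is made because the
  motif's first class {A, S} already satisfies `M | [^D]`; the equivalence
  is asserted in tests.
* `dpp9_long`, `dpp9_short`: the site is present.
* `hidden_ibm`: a DPP9-exposed terminus (offset 3 or 4) matches the motif.

Counting conventions: protein-level counts are per proteome entry (one CCDS
record = one protein), gene-level counts are unique mapped symbols; records
absent from the accession→gene map contribute to protein counts, are
excluded from gene counts, and are listed explicitly. "Unique entries" means
unique (accession, sequence) pairs — identical duplicates collapse, while
two different sequences under one accession abort the parse, so entry counts
are auditable. Candidate overlap with external substrate lists
(`compare_candidates()`) is an exact case-insensitive symbol intersection;
no ortholog mapping is attempted, so mouse symbols in an external list
simply do not match human candidates.

## Peptide state classification

`classify_peptide()` locates an observed peptide in its protein by exact
string match (upper-cased; Ile/Leu are *not* merged, since nothing in the
upstream search output justifies merging) and maps the smallest match offset
to a state: 1 → `UNPROCESSED`, 2 → `MAP_ONLY`, 3 → `DPP9_SHORT`, 4 →
`MAP_DPP9` — each only if the corresponding rule actually applies to the
protein, otherwise `INTERNAL`; non-substring peptides are `UNMATCHED`.
Repeated peptides take the smallest offset, with all offsets retained for
audit. Acetylation is an input flag carried through from the search engine,
never predicted. `summarize_states()` aggregates intensities per
(state, acetylation, condition), with `INTERNAL` peptides forming the
"peptides without N-terminus" abundance baseline.

## Enrichment statistics

The pull-down / IP workflow follows the standard label-free pattern:

1. **Filter**: a protein is kept iff quantified in at least `min_valid` of
   the replicates of at least one group (default 2-of-3; the IP preset uses
   3-of-3). "At least one group" is the right default for pull-downs, where
   specific interactors are legitimately absent from the control; an
   "each group" mode is available.
2. **Transform**: log2 of present values. The base is a convention — it
   rescales differences, never p-values — and is configurable.
3. **Impute**: each missing cell is drawn independently from
   `Normal(mu - downshift * sigma, (width * sigma)^2)` with `mu`, `sigma`
   the mean and SD of *all* present values in scope (whole matrix by
   default; per-column optional). Pull-down preset: downshift 1.8,
   width 0.3; IP preset: downshift 2.0, width 0.3. Fewer than two present
   values, or zero spread, in a scope is an error rather than a silent
   degenerate draw. The draw is seeded and bit-reproducible.
4. **Test**: equal-variance two-sample Student t per protein, two-sided p
   with `nA + nB - 2` degrees of freedom, difference = mean(A) − mean(B).
5. **Call**: significant iff `-log10(p) >= 2` and (by default) the
   difference is positive. No multiple-testing correction enters the call —
   that is the documented operating rule of this workflow — but a BH-FDR
   column is emitted for reference.

## The synthetic generators

`gen_proteome()` plants records in six N-terminal classes (IBM at P2, long
site with/without hidden IBM, short site with/without hidden IBM, none) by
*constructing* the first 1–7 residues to realize the class and filling the
rest uniformly over the 20 standard residues. Because every screen flag
depends only on residues 1–7, the constructed prefix pins the class exactly;
class counts use largest-remainder apportionment, so a 10% hidden-IBM class
in 1000 records yields exactly 100 flagged proteins. Every record is
additionally verified against an independent regex-based checker at
generation time. Uniform background composition is a simplification — real
proteomes are not compositionally uniform — but composition only affects
accidental match rates, which the constructive prefix neutralizes where it
matters.

`gen_peptides()` emits the exact N-terminal peptide of each requested
processing state plus internal peptides. All N-terminal peptides of one
protein share a C-terminal anchor placed 13 residues after the smallest
requested offset, mimicking a shared tryptic boundary; for a protein with
states at offsets 1/2/4 this reproduces the canonical 14/13/11-mer triple.

`gen_lfq()` simulates a pull-down intensity matrix on the log2 scale: null
proteins scatter around a common `baseline` (default 25.5, a typical log2
LFQ magnitude) with within-group SD 0.5; enriched proteins are shifted by
`effect_log2` (default 3) in group A; 3 replicates per group. Missingness is
intensity-dependent: cell `v` is masked with probability
`plogis(missing_slope * (missing_threshold - v))`, i.e. missing not at
random in the lower tail; defaults (threshold 21.5, slope 1) put ~2% of
cells below water. An optional `protein_sd` adds a per-protein abundance
level, emulating the dynamic range of real pull-downs; with it, enriched
proteins whose level falls below the missingness threshold become genuinely
undetectable, and recall of the fixed-cutoff rule drops accordingly (measured:
about 0.88 at `protein_sd = 2` versus about 0.94 under the single-baseline
default). The default stays with the single-baseline model so that the
planted effect size is the only systematic difference between hit and null
proteins.

What passing tests on these fixtures do *not* show: performance on real MS
data, with its correlated missingness across fractions, contaminant and
reverse hits (assumed removed upstream), protein-level intensity summation
artefacts, and non-normal tails.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 10^5 random 9-mers for
engine-versus-independent-checker equivalence; 1000-record planted proteomes
for exact count recovery; 200 planted LFQ matrices of 300 proteins (15
enriched) for recall and null false-hit calibration; and ≥10^4 imputed cells
for imputation calibration (empirical mean within 3 SE of
`mu - 1.8 * sigma`, SD within 5% of `0.3 * sigma`). Ties and degenerate
inputs are resolved explicitly: zero pooled variance yields t = 0 (p = 1)
rather than NaN; peptides shorter than the motif return `FALSE`; sequences
shorter than a rule pattern never match; imputation refuses scopes with
fewer than two present values or zero spread.

## Limitations

* The screen reproduces rule application, not peptidase kinetics: no
  cleavage probabilities, no competition with acetylation, no subcellular
  context (a mitochondrial protein's hidden motif may never meet DPP8/9).
* Acetylation is an input annotation; NatA specificity is not modelled.
* Running the screen at genome scale requires the user to supply the CCDS
  protein FASTA and a BioMart accession→gene export; the package ships only
  programmatically generated fixtures.
* Whether published gene-level counts were taken before or after dropping
  unmapped accessions is ambiguous in general; `run_screen()` therefore
  reports both mapped-gene counts and the unmapped list.

```{r example}
scan_record("MAPSVPAAEPEYPKG")[c("dpp9_long", "hidden_ibm")]

pp <- gen_proteome(1000, c(ibm_p2 = 0.05, dpp9_long_hidden_ibm = 0.10,
                           dpp9_long_no_ibm = 0.05, dpp9_short_hidden_ibm = 0,
                           dpp9_short_no_ibm = 0.05, none = 0.75), seed = 7)
run_screen(pp$records, pp$gene_map)
```
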