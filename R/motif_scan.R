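#' Tetrapeptide consensus motifs
#'
#' A motif pattern is an ordered list of allowed-residue sets tested against
#' the first residues of an exposed N-terminus.  The default is the IBM
#' (IAP-binding motif) consensus `[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILVWY]`:
#' the loose four-residue signature by which proteins such as SMAC/DIABLO
#' (AVPI) bind inhibitor-of-apoptosis proteins.  Only standard residues can
#' satisfy a class, so B/J/O/U/X/Z never match.
#'
#' @param name motif name.
#' @param pattern character-class string, one `[...]` group (or bare letter)
#'   per position, e.g. `"[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILVWY]"`.
#' @return An object of class `motif_pattern` with fields `name` and
#'   `classes`.
#' @export
motif_pattern <- function(name, pattern) {
  classes <- parse_residue_classes(pattern)
  if (!length(classes)) stop("empty motif pattern")
  structure(list(name = name, classes = classes), class = "motif_pattern")
}

#' @rdname motif_pattern
#' @export
ibm_pattern <- function() {
  motif_pattern("IBM", "[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILVWY]")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern %s: %s>\n", x$name,
              paste0("[", vapply(x$classes, paste, "", collapse = ""), "]",
                     collapse = "")))
  invisible(x)
}

#' Read a motif definition file
#'
#' One motif per line, `NAME: [..][..]...` in the same character-class
#' notation as [motif_pattern()].  Returns the first motif unless
#' `all = TRUE`.
#'
#' @param path path to the motif file.
#' @param all return all motifs as a named list instead of the first.
#' @export
read_motif <- function(path, all = FALSE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motifs <- lapply(lines, function(l) {
    m <- regexpr(":", l, fixed = TRUE)
    if (m < 0) stop("motif line without ':': ", l)
    motif_pattern(trimws(substr(l, 1, m - 1)), substr(l, m + 1, nchar(l)))
  })
  names(motifs) <- vapply(motifs, `[[`, character(1), "name")
  if (all) motifs else motifs[[1L]]
}

#' Test peptides against a motif consensus
#'
#' Only the first `length(pattern$classes)` residues are tested; peptides
#' shorter than the pattern return `FALSE`.
#'
#' @param peptide character vector of amino-acid strings.
#' @param pattern a [motif_pattern()]; default the IBM consensus.
#' @return Logical vector, one element per peptide.
#' @examples
#' matches_motif(c("SVPA", "AVPI", "SGLK", "NVLA"))
#' @export
matches_motif <- function(peptide, pattern = ibm_pattern()) {
  stopifnot(inherits(pattern, "motif_pattern"))
  rule_matches(toupper(peptide), pattern$classes)
}

# Vectorized screen core: per-sequence flags for one rule set + motif.
# Exposure semantics: a rule with cut_after == 1 exposes position 2 (the
# "motif at P2" channel); rules with cut_after >= 2 expose deeper offsets
# and define the "hidden motif" channel.
screen_flags <- function(seqs, rules = builtin_rules(), pattern = ibm_pattern()) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  k <- length(pattern$classes)
  matched <- matrix(FALSE, n, length(rules),
                    dimnames = list(NULL, names(rules)))
  hidden <- rep(FALSE, n)
  hidden_rule <- rep(NA_character_, n)
  hidden_offset <- rep(NA_integer_, n)
  for (rn in names(rules)) {
    rule <- rules[[rn]]
    m <- rule_matches(seqs, rule)
    matched[, rn] <- m
    if (rule$cut_after >= 2L) {
      off <- rule$cut_after + 1L
      hit <- m & rule_matches(substr(seqs, off, off + k - 1L), pattern$classes)
      new <- hit & !hidden
      hidden_rule[new] <- rn
      hidden_offset[new] <- off
      hidden <- hidden | hit
    }
  }
  data.frame(
    ibm_at_p2 = rule_matches(substr(seqs, 2L, 1L + k), pattern$classes),
    dpp9_long = if ("DPP9_LONG" %in% colnames(matched)) matched[, "DPP9_LONG"] else FALSE,
    dpp9_short = if ("DPP9_SHORT" %in% colnames(matched)) matched[, "DPP9_SHORT"] else FALSE,
    hidden_ibm = hidden,
    hidden_rule = hidden_rule,
    hidden_offset = hidden_offset,
    stringsAsFactors = FALSE
  )
}

#' Scan one protein for exposed and hidden motifs
#'
#' Flags computed from the unmodified sequence:
#' \describe{
#'   \item{ibm_at_p2}{residues 2-5 match the motif — the terminus exposed by
#'     methionine excision alone.  The motif's first class (`A`/`S` for the
#'     IBM) already satisfies the MAP rule `M | [^D]`, so no explicit MAP
#'     check is made.}
#'   \item{dpp9_long / dpp9_short}{the corresponding DPP9 site is present.}
#'   \item{hidden_ibm}{some DPP9-exposed neo-terminus (offset 3 or 4)
#'     matches the motif.}
#' }
#'
#' @param record a single-row protein record data frame (see [read_fasta()])
#'   or a bare sequence string.
#' @param rules named list of [cleavage_rule()]s.
#' @param pattern a [motif_pattern()].
#' @return List with the logical flags above plus `exposing_states`, the
#'   [enumerate_neo_termini()] states whose neo-terminus matches the motif.
#' @examples
#' scan_record("MAPSVPAAEPEYPKG")$hidden_ibm   # AK2: TRUE via "SVPA"
#' @export
scan_record <- function(record, rules = builtin_rules(), pattern = ibm_pattern()) {
  seq <- if (is.character(record)) record else record$sequence
  stopifnot(length(seq) == 1L)
  flags <- screen_flags(seq, rules, pattern)
  states <- enumerate_neo_termini(toupper(seq), rules)
  exposing <- Filter(function(s) {
    s$start_offset >= 3L && matches_motif(s$neo_seq, pattern)
  }, states)
  list(
    ibm_at_p2 = flags$ibm_at_p2,
    dpp9_long = flags$dpp9_long,
    dpp9_short = flags$dpp9_short,
    hidden_ibm = flags$hidden_ibm,
    exposing_states = exposing
  )
}
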