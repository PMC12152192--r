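#' @importFrom stats aggregate p.adjust pt rnorm sd setNames runif plogis
#' @importFrom utils read.delim write.table
NULL

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' N-terminal cleavage rules as residue-class patterns
#'
#' A cleavage rule is an anchored, position-wise pattern over the first
#' residues of a protein, plus a cut point.  Each position constraint is
#' either an allowed set (e.g. `[AS]`) or an excluded set (e.g. `[^P]`)
#' of one-letter residues; a position is satisfied only by a *standard*
#' residue permitted there, so non-standard residues (B, J, O, U, X, Z)
#' never match, not even against negated classes.  When the pattern matches
#' residues 1..length(pattern), the first `cut_after` residues are removed
#' and the residue at `cut_after + 1` becomes the neo-N-terminus.  Rules are
#' anchored at residue 1 and never applied internally.
#'
#' @param name rule name.
#' @param pattern pattern string in cut-point notation, e.g. `"M[^DE]P | [^P]"`:
#'   a bare letter is a one-residue allowed set, `[...]` an allowed set,
#'   `[^...]` an excluded set (extra carets as in `[^D^E]` are tolerated),
#'   and `|` marks the scissile bond.
#' @return An object of class `cleavage_rule` with fields `name`, `classes`
#'   (list of per-position constraints) and `cut_after`.
#' @examples
#' r <- cleavage_rule("DPP9_LONG", "M[^DE]P | [^P]")
#' apply_rule("MAPSVPAAEPEYPKG", r)
#' @export
cleavage_rule <- function(name, pattern) {
  parts <- strsplit(pattern, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("rule pattern must contain exactly one cut point '|': ", pattern)
  left <- parse_residue_classes(parts[1])
  right <- parse_residue_classes(parts[2])
  if (length(left) < 1L || length(right) < 1L)
    stop("at least one residue class required on each side of '|': ", pattern)
  structure(
    list(name = name, classes = c(left, right), cut_after = length(left)),
    class = "cleavage_rule"
  )
}

# Tokenize a residue-class string: bare letters and [...]/[^...] groups.
parse_residue_classes <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  classes <- list()
  i <- 1L
  n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(x, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated residue class in pattern: ", x)
      body <- substr(x, i + 1L, i + j - 2L)
      negated <- startsWith(body, "^")
      body <- gsub("^", "", body, fixed = TRUE)
      res <- strsplit(toupper(body), "")[[1]]
      bad <- setdiff(res, AA_STANDARD)
      if (length(bad))
        stop("non-standard residue(s) in class: ", paste(bad, collapse = ""))
      if (!negated && length(res) == 0L)
        stop("empty allowed class in pattern: ", x)
      allowed <- if (negated) setdiff(AA_STANDARD, res) else res
      classes[[length(classes) + 1L]] <- allowed
      i <- i + j
    } else if (toupper(ch) %in% AA_STANDARD) {
      classes[[length(classes) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in pattern: ", x)
    }
  }
  classes
}

#' @export
print.cleavage_rule <- function(x, ...) {
  fmt <- vapply(x$classes, function(cl) {
    if (length(cl) == 1L) cl
    else if (length(cl) > 10L) paste0("[^", paste(setdiff(AA_STANDARD, cl), collapse = ""), "]")
    else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1))
  cat(sprintf("<cleavage_rule %s: %s | %s>\n", x$name,
              paste(fmt[seq_len(x$cut_after)], collapse = ""),
              paste(fmt[-seq_len(x$cut_after)], collapse = "")))
  invisible(x)
}

#' Built-in processing rules: MAP and DPP9 long/short
#'
#' The three rules modelled by the screen:
#' \describe{
#'   \item{MAP}{`M | [^D]` — methionine aminopeptidase removes the initiator
#'     methionine when residue 2 is not aspartate; neo-terminus at offset 2.}
#'   \item{DPP9_LONG}{`M[^DE]P | [^P]` — DPP8/9 remove the X-P dipeptide of an
#'     M-X-P start (X not D/E, residue 4 not P) after methionine excision;
#'     neo-terminus at offset 4.}
#'   \item{DPP9_SHORT}{`MP | [^P]` — DPP8/9 remove the M-P dipeptide directly
#'     (residue 3 not P); neo-terminus at offset 3.}
#' }
#' The long and short DPP9 sites are mutually exclusive (residue 3 must be P
#' for the long form and must not be P for the short form), and any sequence
#' with a long site is also MAP-cleavable.
#'
#' @return Named list of [cleavage_rule()] objects.
#' @export
builtin_rules <- function() {
  list(
    MAP        = cleavage_rule("MAP", "M | [^D]"),
    DPP9_LONG  = cleavage_rule("DPP9_LONG", "M[^DE]P | [^P]"),
    DPP9_SHORT = cleavage_rule("DPP9_SHORT", "MP | [^P]")
  )
}

#' Read cleavage rules from a definition file
#'
#' One rule per line, `NAME: PATTERN` in the cut-point notation of
#' [cleavage_rule()]; blank lines and `#` comments are ignored.
#'
#' @param path path to the rule file.
#' @return Named list of `cleavage_rule` objects.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- lapply(lines, function(l) {
    m <- regexpr(":", l, fixed = TRUE)
    if (m < 0) stop("rule line without ':': ", l)
    cleavage_rule(trimws(substr(l, 1, m - 1)), substr(l, m + 1, nchar(l)))
  })
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  rules
}

# Vectorized anchored match of a rule (or any list of residue classes)
# over a character vector of sequences.
rule_matches <- function(seqs, rule) {
  classes <- if (inherits(rule, "cleavage_rule")) rule$classes else rule
  ok <- nchar(seqs) >= length(classes)
  for (i in seq_along(classes)) {
    if (!any(ok)) break
    ok <- ok & substr(seqs, i, i) %in% classes[[i]]
  }
  ok
}

#' Apply a cleavage rule to a sequence
#'
#' @param seq amino-acid string (position 1 is the initiator methionine).
#' @param rule a [cleavage_rule()].
#' @return A `neo_terminus` (list with `rule_chain`, `start_offset`,
#'   `neo_seq`) on match, or `NULL` when the rule does not apply.  A
#'   sequence shorter than the pattern never matches.
#' @export
apply_rule <- function(seq, rule) {
  stopifnot(inherits(rule, "cleavage_rule"), length(seq) == 1L)
  if (!rule_matches(seq, rule)) return(NULL)
  neo_terminus(rule$name, rule$cut_after + 1L, seq)
}

neo_terminus <- function(rule_chain, start_offset, seq) {
  structure(
    list(rule_chain = rule_chain, start_offset = start_offset,
         neo_seq = substr(seq, start_offset, nchar(seq))),
    class = "neo_terminus"
  )
}

#' Enumerate the possible N-terminal processing states of a protein
#'
#' Returns the unprocessed state (offset 1) plus one state per matching
#' rule.  A DPP9 "long" site subsumes MAP cleavability, so its state is
#' recorded with the chain `MAP, DPP9_LONG`; the rule itself is still the
#' single anchored pattern applied to the unmodified sequence.
#'
#' @param seq amino-acid string.
#' @param rules named list of rules, default [builtin_rules()].
#' @return List of `neo_terminus` states ordered by increasing offset.
#' @examples
#' vapply(enumerate_neo_termini("MAPSVPAAEPEYPKG"), `[[`, 1L, "start_offset")
#' @export
enumerate_neo_termini <- function(seq, rules = builtin_rules()) {
  states <- list(neo_terminus("none", 1L, seq))
  for (rule in rules) {
    nt <- apply_rule(seq, rule)
    if (!is.null(nt)) {
      if (identical(rule$name, "DPP9_LONG"))
        nt$rule_chain <- c("MAP", "DPP9_LONG")
      states[[length(states) + 1L]] <- nt
    }
  }
  states[order(vapply(states, `[[`, integer(1), "start_offset"))]
}
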