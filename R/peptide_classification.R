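PEPTIDE_STATES <- c("UNPROCESSED", "MAP_ONLY", "DPP9_SHORT", "MAP_DPP9",
                    "INTERNAL", "UNMATCHED")

#' Classify an observed N-terminal peptide against a protein
#'
#' Locates the peptide in the protein by exact string match (upper-cased;
#' I and L are not merged) and assigns a processing state from the smallest
#' match offset:
#' offset 1 -> `UNPROCESSED`; offset 2 with the MAP rule applicable ->
#' `MAP_ONLY`; offset 3 with the DPP9 short rule applicable -> `DPP9_SHORT`;
#' offset 4 with the DPP9 long rule applicable -> `MAP_DPP9`; any other
#' offset (including rule-inapplicable 2/3/4) -> `INTERNAL`; no match ->
#' `UNMATCHED`.  All match offsets are retained for audit.  The acetylation
#' flag is carried through from the input (as produced by the search
#' engine), never predicted.
#'
#' @param protein_seq full protein sequence (position 1 = initiator Met).
#' @param peptide observed peptide sequence.
#' @param nterm_acetyl logical, N-terminally acetylated.
#' @param rules named list of rules; state mapping uses the names `MAP`,
#'   `DPP9_SHORT`, `DPP9_LONG`.
#' @return List of class `peptide_state_call`: `state`, `acetylated`,
#'   `offset` (1-based, `NA` if unmatched), `all_offsets`.
#' @examples
#' ak2 <- "MAPSVPAAEPEYPKGIRAVLLGPPGAG"
#' classify_peptide(ak2, "SVPAAEPEYPK")$state      # "MAP_DPP9"
#' classify_peptide(ak2, "APSVPAAEPEYPK")$state    # "MAP_ONLY"
#' @export
classify_peptide <- function(protein_seq, peptide, nterm_acetyl = FALSE,
                             rules = builtin_rules()) {
  stopifnot(length(protein_seq) == 1L, length(peptide) == 1L, nzchar(peptide))
  protein_seq <- toupper(protein_seq)
  peptide <- toupper(peptide)
  hits <- gregexpr(peptide, protein_seq, fixed = TRUE)[[1]]
  offsets <- if (hits[1] == -1L) integer() else as.integer(hits)
  if (!length(offsets)) {
    return(structure(list(state = "UNMATCHED", acetylated = nterm_acetyl,
                          offset = NA_integer_, all_offsets = integer()),
                     class = "peptide_state_call"))
  }
  off <- min(offsets)
  applicable <- function(rule_name) {
    !is.null(rules[[rule_name]]) && rule_matches(protein_seq, rules[[rule_name]])
  }
  state <-
    if (off == 1L) "UNPROCESSED"
    else if (off == 2L && applicable("MAP")) "MAP_ONLY"
    else if (off == 3L && applicable("DPP9_SHORT")) "DPP9_SHORT"
    else if (off == 4L && applicable("DPP9_LONG")) "MAP_DPP9"
    else "INTERNAL"
  structure(list(state = state, acetylated = nterm_acetyl, offset = off,
                 all_offsets = offsets),
            class = "peptide_state_call")
}

#' Classify a table of observed peptides
#'
#' @param peptides data frame with columns `accession`, `peptide`,
#'   `nterm_acetyl` (logical or 0/1) and optionally `sample`, `intensity`.
#' @param records protein record data frame providing the sequences.
#' @param rules named list of rules.
#' @return The input data frame with added columns `state` and `offset`.
#' @export
classify_peptides <- function(peptides, records, rules = builtin_rules()) {
  seq_of <- setNames(records$sequence, records$accession)
  missing_acc <- setdiff(unique(peptides$accession), names(seq_of))
  if (length(missing_acc))
    stop("accession(s) not in proteome: ", paste(missing_acc, collapse = ", "))
  calls <- Map(function(acc, pep, ac) {
    classify_peptide(seq_of[[acc]], pep, as.logical(ac), rules)
  }, peptides$accession, peptides$peptide, peptides$nterm_acetyl)
  peptides$state <- vapply(calls, `[[`, "", "state")
  peptides$offset <- vapply(calls, `[[`, NA_integer_, "offset")
  peptides
}

#' Summarize peptide intensities per processing state
#'
#' Aggregates intensities per (state, acetylated, condition): sum, mean and
#' peptide count.  `INTERNAL` peptides form the "peptides w/o N-terminus"
#' baseline row of raw-intensity bar charts.
#'
#' @param calls classified peptide data frame ([classify_peptides()]) with
#'   `sample` and `intensity` columns.
#' @param groups named vector mapping sample id -> condition label.
#' @return Data frame with columns `state`, `acetylated`, `condition`,
#'   `n_peptides`, `sum_intensity`, `mean_intensity`, ordered by state.
#' @export
summarize_states <- function(calls, groups) {
  stopifnot(all(c("state", "intensity", "sample") %in% names(calls)))
  if (!all(calls$sample %in% names(groups)))
    stop("sample(s) without a group assignment: ",
         paste(setdiff(calls$sample, names(groups)), collapse = ", "))
  df <- data.frame(
    state = calls$state,
    acetylated = as.logical(calls$nterm_acetyl),
    condition = unname(groups[calls$sample]),
    intensity = calls$intensity,
    stringsAsFactors = FALSE
  )
  agg <- aggregate(intensity ~ state + acetylated + condition, data = df,
                   FUN = function(v) c(n = length(v), sum = sum(v), mean = mean(v)))
  out <- data.frame(
    state = agg$state,
    acetylated = agg$acetylated,
    condition = agg$condition,
    n_peptides = as.integer(agg$intensity[, "n"]),
    sum_intensity = agg$intensity[, "sum"],
    mean_intensity = agg$intensity[, "mean"],
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$state, PEPTIDE_STATES), out$acetylated,
                   out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an observed-peptide TSV
#'
#' Expected columns: `accession`, `peptide`, `nterm_acetyl` (0/1),
#' optionally `sample` and `intensity`.
#' @param path TSV path.
#' @export
read_peptides <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "peptide", "nterm_acetyl")
  if (!all(need %in% names(x)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  x$nterm_acetyl <- as.logical(as.integer(x$nterm_acetyl))
  x
}
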