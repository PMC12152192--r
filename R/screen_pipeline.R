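#' Run the proteome-wide hidden-motif screen
#'
#' Applies [scan_record()] semantics to every record (vectorized), counts
#' proteins and unique genes per flag, and builds the candidate table of
#' proteins whose DPP9-exposed neo-terminus matches the motif.  Protein
#' counts are per proteome entry (e.g. per CCDS), not per gene; gene counts
#' are the size of the mapped-gene set for the flagged entries.  Records
#' unmapped in the gene map contribute to protein counts but not gene
#' counts, and are listed in the `unmapped` element.  Output is
#' deterministic: candidates are ordered by accession.
#'
#' @param records protein record data frame from [read_fasta()].
#' @param gene_map a [load_gene_map()] result, or `NULL` for no mapping.
#' @param rules named list of [cleavage_rule()]s.
#' @param pattern a [motif_pattern()].
#' @return List of class `screen_result` with elements
#'   \describe{
#'     \item{summary}{one-row data frame: `n_ccds`, `n_genes`, `n_ibm_p2`,
#'       `n_ibm_p2_genes`, `n_dpp9_long`, `n_dpp9_short`, `n_dpp9_total`,
#'       `n_hidden_ibm`, `n_hidden_ibm_genes`.}
#'     \item{candidates}{data frame: `accession`, `gene`, `rule`, `offset`,
#'       `tetrapeptide`, `neo_nterm10` (first 10 residues of the
#'       neo-terminus).}
#'     \item{flags}{per-record flag data frame (row order = input order).}
#'     \item{unmapped}{accessions absent from the gene map.}
#'   }
#' @export
run_screen <- function(records, gene_map = NULL, rules = builtin_rules(),
                       pattern = ibm_pattern()) {
  empty_map <- structure(setNames(character(), character()),
                         errors = integer(), class = "gene_map")
  if (is.null(gene_map)) gene_map <- empty_map
  flags <- screen_flags(records$sequence, rules, pattern)
  k <- length(pattern$classes)

  gene_count <- function(idx) unique_genes(records[idx, , drop = FALSE], gene_map)

  all_g <- gene_count(seq_len(nrow(records)))
  p2_g <- gene_count(which(flags$ibm_at_p2))
  hid_g <- gene_count(which(flags$hidden_ibm))

  summary <- data.frame(
    n_ccds = nrow(records),
    n_genes = all_g$n_genes,
    n_ibm_p2 = sum(flags$ibm_at_p2),
    n_ibm_p2_genes = p2_g$n_genes,
    n_dpp9_long = sum(flags$dpp9_long),
    n_dpp9_short = sum(flags$dpp9_short),
    n_dpp9_total = sum(flags$dpp9_long) + sum(flags$dpp9_short),
    n_hidden_ibm = sum(flags$hidden_ibm),
    n_hidden_ibm_genes = hid_g$n_genes
  )

  idx <- which(flags$hidden_ibm)
  off <- flags$hidden_offset[idx]
  candidates <- data.frame(
    accession = records$accession[idx],
    gene = gene_for(gene_map, records$accession[idx]),
    rule = flags$hidden_rule[idx],
    offset = off,
    tetrapeptide = substring(records$sequence[idx], off, off + k - 1L),
    neo_nterm10 = substring(records$sequence[idx], off, off + 9L),
    stringsAsFactors = FALSE
  )
  candidates <- candidates[order(candidates$accession), , drop = FALSE]
  rownames(candidates) <- NULL

  structure(list(summary = summary, candidates = candidates, flags = flags,
                 unmapped = all_g$unmapped),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("Hidden-motif screen over %d entries (%d mapped genes)\n",
           "  motif at P2:            %5d entries (%d genes)\n",
           "  DPP8/9 cleavage sites:  %5d entries (%d MXP long + %d MP short)\n",
           "  hidden motif candidates:%5d entries (%d genes)\n"),
    s$n_ccds, s$n_genes, s$n_ibm_p2, s$n_ibm_p2_genes,
    s$n_dpp9_total, s$n_dpp9_long, s$n_dpp9_short,
    s$n_hidden_ibm, s$n_hidden_ibm_genes))
  invisible(x)
}

#' Compare screen candidates to an external gene list
#'
#' Exact, case-insensitive symbol intersection (no ortholog mapping — mouse
#' symbols in an external list are compared as given).
#'
#' @param candidates candidate data frame from [run_screen()] (needs a
#'   `gene` column), or a character vector of gene symbols.
#' @param external character vector of gene symbols, or a path to a
#'   one-symbol-per-line text file.
#' @return List with `matched`, `candidate_only`, `external_only` (symbols
#'   in the candidates' original case where available) and `n_matched`.
#' @export
compare_candidates <- function(candidates, external) {
  cand <- if (is.character(candidates)) candidates else candidates$gene
  cand <- unique(cand[!is.na(cand) & nzchar(cand)])
  if (is.character(external) && length(external) == 1L && file.exists(external))
    external <- readLines(external, warn = FALSE)
  external <- unique(trimws(external))
  external <- external[nzchar(external)]
  if (!length(external)) warning("external gene list is empty")
  hit <- tolower(cand) %in% tolower(external)
  ext_hit <- tolower(external) %in% tolower(cand)
  list(matched = sort(cand[hit]),
       candidate_only = sort(cand[!hit]),
       external_only = sort(external[!ext_hit]),
       n_matched = sum(hit))
}

#' Write a screen report to disk
#'
#' Writes `summary.tsv` (key/value), `candidates.tsv` (fixed column order:
#' accession, gene, rule, offset, tetrapeptide, neo_nterm10),
#' `unmapped.tsv` and a human-readable `summary.txt`.  Byte-identical for
#' identical inputs.
#'
#' @param result a `screen_result` from [run_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- result$summary
  write.table(data.frame(key = names(s), value = unlist(s)),
              file.path(dir, "summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$candidates, file.path(dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write.table(data.frame(accession = result$unmapped),
              file.path(dir, "unmapped.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  txt <- utils::capture.output(print(result))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Read back a candidates table written by [write_report()]
#' @param path path to `candidates.tsv`.
#' @export
read_candidates <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = c(accession = "character", gene = "character",
                                 rule = "character", offset = "integer",
                                 tetrapeptide = "character",
                                 neo_nterm10 = "character"))
  x
}
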