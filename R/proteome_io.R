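#' Read a protein FASTA into a protein record table
#'
#' Parses an amino-acid FASTA via [Biostrings::readAAStringSet()] and returns
#' a data frame with one row per entry: `accession`, `gene` (`NA` until a
#' gene map is applied), `sequence` (upper-cased, trailing stop `*`
#' stripped) and `source_header` (the raw header text).  For
#' `dialect = "ccds"` the accession is the first `|`-delimited header token
#' (CCDS FASTA headers vary across releases; only the accession is needed
#' downstream, the rest is kept verbatim in `source_header`); for
#' `dialect = "generic"` it is the first whitespace-delimited token.
#'
#' Deduplication: entries sharing accession *and* sequence are collapsed to
#' one (first occurrence kept); entries sharing an accession but differing
#' in sequence are a hard error, so that "unique entry" counts over the
#' parsed proteome are auditable.
#'
#' @param path FASTA file path.
#' @param dialect header dialect, `"generic"` or `"ccds"`.
#' @param dedupe collapse exact duplicates (default `TRUE`).
#' @return A `data.frame` with columns `accession`, `gene`, `sequence`,
#'   `source_header`.
#' @export
read_fasta <- function(path, dialect = c("generic", "ccds"), dedupe = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(
    Biostrings::readAAStringSet(path, format = "fasta"),
    error = function(e) {
      # locate the offending line for a useful parse error
      lines <- readLines(path, warn = FALSE)
      first <- which(nzchar(trimws(lines)))[1]
      if (!is.na(first) && !startsWith(trimws(lines[first]), ">"))
        stop("malformed FASTA (line ", first, "): expected '>' header, got: ",
             substr(lines[first], 1, 40), call. = FALSE)
      stop("malformed FASTA: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(aa) == 0L)
    return(data.frame(accession = character(), gene = character(),
                      sequence = character(), source_header = character(),
                      stringsAsFactors = FALSE))
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for entry: ", headers[which(!nzchar(seqs))[1]])
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad))
    stop("non-alphabetic residue in entry: ", headers[which(bad)[1]])
  acc <- switch(dialect,
    ccds    = vapply(strsplit(headers, "|", fixed = TRUE), `[[`, "", 1L),
    generic = vapply(strsplit(headers, "[[:space:]]+"), `[[`, "", 1L)
  )
  acc <- trimws(acc)
  rec <- data.frame(accession = acc, gene = NA_character_, sequence = seqs,
                    source_header = headers, stringsAsFactors = FALSE)
  if (dedupe) rec <- dedupe_records(rec)
  rownames(rec) <- NULL
  rec
}

dedupe_records <- function(rec) {
  dup_pair <- duplicated(paste(rec$accession, rec$sequence, sep = "\r"))
  rec <- rec[!dup_pair, , drop = FALSE]
  conflict <- duplicated(rec$accession)
  if (any(conflict))
    stop("duplicate accession with conflicting sequence: ",
         paste(unique(rec$accession[conflict]), collapse = ", "))
  rec
}

#' Write protein records to FASTA
#'
#' Headers are the stored `source_header` (falling back to the accession),
#' so `read_fasta(write_fasta(x))` round-trips.
#'
#' @param records protein record data frame.
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(is.na(records$source_header) | !nzchar(records$source_header),
                      records$accession, records$source_header)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Load an accession-to-gene mapping table
#'
#' Two-column TSV (accession, gene symbol), as exported from Ensembl
#' BioMart.  A header row is auto-detected: a first row whose second field
#' looks like a column label ("gene", "symbol", "name") is skipped.
#' Version suffixes (`.n`) on accessions are stripped for lookup, so
#' `CCDS1.2` resolves through a map keyed `CCDS1`.  Many accessions may map
#' to the same gene.  Rows without exactly two non-empty fields are
#' collected into the `errors` attribute rather than aborting the load.
#'
#' @param path TSV path.
#' @return A named character vector (accession-without-version -> gene
#'   symbol) of class `gene_map`, with attribute `errors` (malformed row
#'   numbers, possibly empty).
#' @export
load_gene_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(structure(setNames(character(), character()),
                     errors = integer(), class = "gene_map"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, trimws)
  start <- 1L
  if (length(fields[[1]]) >= 2L &&
      grepl("gene|symbol|name", tolower(fields[[1]][2])))
    start <- 2L
  ok <- vapply(fields, function(f) length(f) == 2L && all(nzchar(f)), logical(1))
  ok[seq_len(start - 1L)] <- FALSE
  bad_rows <- setdiff(which(!ok), seq_len(start - 1L))
  if (length(bad_rows))
    warning(length(bad_rows), " malformed gene-map row(s), e.g. line ",
            bad_rows[1])
  acc <- vapply(fields[ok], `[[`, "", 1L)
  gene <- vapply(fields[ok], `[[`, "", 2L)
  acc <- sub("\\.[0-9]+$", "", acc)
  keep <- !duplicated(acc)
  structure(setNames(gene[keep], acc[keep]),
            errors = bad_rows, class = "gene_map")
}

#' Look up gene symbols for accessions
#'
#' @param map a [load_gene_map()] result.
#' @param accession character vector; version suffixes are ignored.
#' @return Character vector of gene symbols, `NA` where unmapped.
#' @export
gene_for <- function(map, accession) {
  key <- sub("\\.[0-9]+$", "", accession)
  unname(unclass(map)[key])
}

#' Count unique mapped genes over a set of protein records
#'
#' Gene symbols are compared case-preserving and exactly.  Records whose
#' accession has no entry in the map are reported separately, never dropped
#' silently.
#'
#' @param records protein record data frame.
#' @param map a `gene_map`.
#' @return List with `n_genes`, `genes` (sorted unique symbols),
#'   `n_unmapped` and `unmapped` (accessions without a map entry).
#' @export
unique_genes <- function(records, map) {
  if (nrow(records) == 0L)
    return(list(n_genes = 0L, genes = character(),
                n_unmapped = 0L, unmapped = character()))
  g <- gene_for(map, records$accession)
  unmapped <- records$accession[is.na(g)]
  genes <- sort(unique(g[!is.na(g)]))
  list(n_genes = length(genes), genes = genes,
       n_unmapped = length(unmapped), unmapped = unmapped)
}
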