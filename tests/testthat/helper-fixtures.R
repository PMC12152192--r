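# N-terminal sequences used throughout the tests (padded with an arbitrary
# downstream stretch where full-length behaviour matters).
AK2_NT    <- "MAPSVPAAEPEYPKG"
AK2_SEQ   <- "MAPSVPAAEPEYPKGIRAVLLGPPGAGKGTQAPRLAENFCVCHLA"
EIF2A_NT  <- "MAPSTPLLTVRSIRLNKGH"
STXBP2_NT <- "MAPSGLKSVVGQKV"

write_tmp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(seq_along(entries), function(i) {
    c(paste0(">", names(entries)[i]), entries[[i]])
  })), path)
  path
}

toy_proteome <- function() {
  data.frame(
    accession = c("AK2.1", "EIF2A.1", "STXBP2.1", "MD1.1", "MPST.1", "CTRL.1"),
    gene = NA_character_,
    sequence = c(AK2_SEQ, EIF2A_NT, STXBP2_NT,
                 "MDGKLVRSTAQWE", "MPSTAKGHLVRE", "KLVRSTGAQWEHN"),
    source_header = "",
    stringsAsFactors = FALSE
  )
}
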