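# Independent position-by-position checker for the built-in MAP/DPP9 rules
# and the IBM consensus.  Deliberately written with explicit per-residue
# comparisons on split character vectors -- no shared code with the package's
# residue-class engine or its regex checker.

ORACLE_STD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_flags_one <- function(seq) {
  aa <- strsplit(toupper(seq), "")[[1]]
  at <- function(i, allowed) !is.na(aa[i]) && aa[i] %in% allowed
  map   <- at(1, "M") && at(2, setdiff(ORACLE_STD, "D"))
  long  <- at(1, "M") && at(2, setdiff(ORACLE_STD, c("D", "E"))) &&
           at(3, "P") && at(4, setdiff(ORACLE_STD, "P"))
  short <- at(1, "M") && at(2, "P") && at(3, setdiff(ORACLE_STD, "P"))
  ibm_at <- function(i) {
    at(i,     c("A", "S")) &&
    at(i + 1, strsplit("DEFGILMQRSTV", "")[[1]]) &&
    at(i + 2, strsplit("ACGKMPRSV", "")[[1]]) &&
    at(i + 3, strsplit("ADEFGILVWY", "")[[1]])
  }
  list(map = map, dpp9_long = long, dpp9_short = short,
       ibm_p2 = ibm_at(2),
       hidden_ibm = (long && ibm_at(4)) || (short && ibm_at(3)))
}

oracle_flags <- function(seqs) {
  do.call(rbind, lapply(seqs, function(s) as.data.frame(oracle_flags_one(s))))
}

rand_seqs <- function(n, len = 30L, seed = NULL,
                      alphabet = ORACLE_STD, bias_nterm = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    aa <- sample(alphabet, len, replace = TRUE)
    # enrich informative N-termini so rule/motif branches are actually hit
    if (bias_nterm && runif(1) < 0.5) aa[1] <- "M"
    if (bias_nterm && runif(1) < 0.3) aa[3] <- "P"
    if (bias_nterm && runif(1) < 0.3) aa[2] <- sample(c("A", "S", "P"), 1)
    paste(aa, collapse = "")
  }, character(1))
}
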