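# Regex-based reference checker for the built-in MAP/DPP9 rules and the IBM
# consensus.  Written independently of the residue-class engine on purpose:
# the generator asserts every planted record against it, so planted truth is
# backed by two separate implementations.  Assumes standard residues only
# (all the generator emits).
naive_screen_flags <- function(seqs) {
  seqs <- toupper(seqs)
  ibm_re <- "^[AS][DEFGILMQRSTV][ACGKMPRSV][ADEFGILVWY]"
  long <- grepl("^M[ACFGHIKLMNPQRSTVWY]P[ACDEFGHIKLMNQRSTVWY]", seqs)
  short <- grepl("^MP[ACDEFGHIKLMNQRSTVWY]", seqs)
  data.frame(
    ibm_p2 = grepl(ibm_re, substr(seqs, 2, 5)),
    dpp9_long = long,
    dpp9_short = short,
    hidden_ibm = (long & grepl(ibm_re, substr(seqs, 4, 7))) |
                 (short & grepl(ibm_re, substr(seqs, 3, 6))),
    stringsAsFactors = FALSE
  )
}

rand_aa <- function(n, exclude = character()) {
  pool <- setdiff(AA_STANDARD, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

sample_motif_tetra <- function(pattern = ibm_pattern()) {
  paste(vapply(pattern$classes, function(cl) sample(cl, 1L), character(1)),
        collapse = "")
}

PROTEOME_CLASSES <- c("ibm_p2", "dpp9_long_hidden_ibm", "dpp9_long_no_ibm",
                      "dpp9_short_hidden_ibm", "dpp9_short_no_ibm", "none")

# Largest-remainder apportionment: exact integer counts summing to n.
exact_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Constructive prefix realizing one planted class; flags of the built-in
# screen depend only on residues 1-7, so the suffix is free.
planted_prefix <- function(class, pattern = ibm_pattern()) {
  switch(class,
    ibm_p2 = paste0("M", sample_motif_tetra(pattern)),
    dpp9_long_hidden_ibm = paste0("M", rand_aa(1, exclude = c("D", "E")),
                                  "P", sample_motif_tetra(pattern)),
    dpp9_long_no_ibm = paste0("M", rand_aa(1, exclude = c("D", "E")), "P",
                              rand_aa(1, exclude = c("P", "A", "S"))),
    dpp9_short_hidden_ibm = paste0("MP", sample_motif_tetra(pattern)),
    dpp9_short_no_ibm = paste0("MP", rand_aa(1, exclude = c("P", "A", "S"))),
    none = paste0(rand_aa(1, exclude = "M"), rand_aa(1, exclude = c("A", "S"))),
    stop("unknown planted class: ", class)
  )
}

class_truth <- function(class) {
  list(
    ibm_p2 = c(class == "ibm_p2"),
    dpp9_long = class %in% c("dpp9_long_hidden_ibm", "dpp9_long_no_ibm"),
    dpp9_short = class %in% c("dpp9_short_hidden_ibm", "dpp9_short_no_ibm"),
    hidden_ibm = class %in% c("dpp9_long_hidden_ibm", "dpp9_short_hidden_ibm")
  )
}

#' Generate a planted proteome with known screen ground truth
#'
#' Each record is assigned one of six N-terminal classes and its first 1-7
#' residues are constructed to realize exactly that class: an IBM at P2, a
#' DPP9 long (MXP) or short (MP) site with or without a hidden IBM behind
#' it, or none of these.  Hidden-IBM tetrapeptides are drawn uniformly from
#' the class product of the motif.  Remaining residues are uniform over the
#' 20 standard amino acids; since every flag of the built-in screen depends
#' only on residues 1-7, the constructed prefix pins the class, and every
#' record is additionally verified against an independent regex-based
#' checker (resampled in the rare event of a mismatch under a custom
#' motif).  Class counts are exact (largest-remainder apportionment), so
#' downstream screen counts are exactly checkable.
#'
#' A deterministic accession-to-gene map with a known many-to-one structure
#' (every fourth record shares its gene with the previous record) is
#' generated alongside.
#'
#' @param n number of records.
#' @param class_fractions named fractions over
#'   `ibm_p2, dpp9_long_hidden_ibm, dpp9_long_no_ibm, dpp9_short_hidden_ibm,
#'   dpp9_short_no_ibm, none`; must be nonnegative and sum to 1.  The
#'   defaults approximate the rates seen in a human coding proteome
#'   (roughly 7% IBM at P2, 5% each DPP9 site class, hidden IBMs rare).
#' @param length_range protein length range (uniform).
#' @param pattern motif used for the planted tetrapeptides.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return List of class `planted_proteome`: `records`, `truth` (accession,
#'   class, four flags), `gene_map`, `params`.
#' @export
gen_proteome <- function(n,
                         class_fractions = c(ibm_p2 = 0.070,
                                             dpp9_long_hidden_ibm = 0.002,
                                             dpp9_long_no_ibm = 0.048,
                                             dpp9_short_hidden_ibm = 0.002,
                                             dpp9_short_no_ibm = 0.045,
                                             none = 0.833),
                         length_range = c(100L, 600L),
                         pattern = ibm_pattern(),
                         seed = 1L) {
  stopifnot(n >= 1)
  if (!setequal(names(class_fractions), PROTEOME_CLASSES))
    stop("class_fractions must be named: ",
         paste(PROTEOME_CLASSES, collapse = ", "))
  class_fractions <- class_fractions[PROTEOME_CLASSES]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must be nonnegative and sum to 1")
  set.seed(seed)
  counts <- exact_counts(n, class_fractions)
  classes <- sample(rep(PROTEOME_CLASSES, counts))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      prefix <- planted_prefix(classes[i], pattern)
      seq <- paste0(prefix, rand_aa(max(lens[i] - nchar(prefix), 0L)))
      got <- naive_screen_flags(seq)
      want <- class_truth(classes[i])
      if (got$ibm_p2 == want$ibm_p2 && got$dpp9_long == want$dpp9_long &&
          got$dpp9_short == want$dpp9_short && got$hidden_ibm == want$hidden_ibm) {
        seqs[i] <- seq
        break
      }
    }
    if (!nzchar(seqs[i]))
      stop("could not realize planted class '", classes[i],
           "' under the given motif")
  }
  acc <- sprintf("SYN%05d.1", seq_len(n))
  gene_idx <- seq_len(n) - seq_len(n) %/% 4L
  genes <- sprintf("SYNG%04d", gene_idx)
  records <- data.frame(
    accession = acc, gene = NA_character_, sequence = seqs,
    source_header = paste0(acc, "|planted|", classes),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    accession = acc, class = classes,
    ibm_p2 = classes == "ibm_p2",
    dpp9_long = classes %in% c("dpp9_long_hidden_ibm", "dpp9_long_no_ibm"),
    dpp9_short = classes %in% c("dpp9_short_hidden_ibm", "dpp9_short_no_ibm"),
    hidden_ibm = classes %in% c("dpp9_long_hidden_ibm", "dpp9_short_hidden_ibm"),
    stringsAsFactors = FALSE
  )
  gene_map <- structure(setNames(genes, sub("\\.[0-9]+$", "", acc)),
                        errors = integer(), class = "gene_map")
  structure(list(records = records, truth = truth, gene_map = gene_map,
                 params = list(n = n, class_fractions = class_fractions,
                               length_range = length_range, seed = seed)),
            class = "planted_proteome")
}

#' Write a planted proteome to disk (FASTA + truth TSV + gene map + manifest)
#' @param pp a [gen_proteome()] result.
#' @param dir output directory.
#' @export
write_planted_proteome <- function(pp, dir) {
  stopifnot(inherits(pp, "planted_proteome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(pp$records, file.path(dir, "proteome.fasta"))
  write.table(pp$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(accession = names(pp$gene_map),
                         gene = unname(unclass(pp$gene_map))),
              file.path(dir, "gene_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  p <- pp$params
  writeLines(c(
    paste0("n\t", p$n),
    paste0("seed\t", p$seed),
    paste0("length_range\t", paste(p$length_range, collapse = "-")),
    paste0("class_fractions\t",
           paste(names(p$class_fractions), p$class_fractions,
                 sep = "=", collapse = ","))
  ), file.path(dir, "manifest.tsv"))
  invisible(dir)
}

STATE_OFFSETS <- c(UNPROCESSED = 1L, MAP_ONLY = 2L, DPP9_SHORT = 3L,
                   MAP_DPP9 = 4L)

#' Generate observed N-terminal and internal peptides with known states
#'
#' For each protein, emits the exact N-terminal peptide of every requested
#' processing state that is applicable under the built-in rules (states
#' whose rule does not match are skipped with a warning), plus `n_internal`
#' internal peptides.  All N-terminal peptides of one protein share a
#' C-terminal anchor (as tryptic peptides from one N-terminal region do);
#' the anchor sits 13 residues after the smallest requested offset, so
#' peptide lengths fall in 8-14 across offsets 1-4.  Generated peptides are
#' verified to classify back to their planted state.
#'
#' @param records protein record data frame (or a [gen_proteome()] result).
#' @param states data frame with columns `state` and `acetyl`, or a
#'   character vector of states (acetyl `FALSE`).  Default: the three
#'   canonical observed forms — acetylated unprocessed, free MAP-only, free
#'   MAP+DPP9.
#' @param n_internal internal peptides per protein.
#' @param seed integer seed.
#' @return Data frame: `accession`, `peptide`, `nterm_acetyl`, `sample`,
#'   `intensity`, `state_truth`.
#' @export
gen_peptides <- function(records,
                         states = data.frame(
                           state = c("UNPROCESSED", "MAP_ONLY", "MAP_DPP9"),
                           acetyl = c(TRUE, FALSE, FALSE)),
                         n_internal = 2L, seed = 1L) {
  if (inherits(records, "planted_proteome")) records <- records$records
  if (is.character(states))
    states <- data.frame(state = states, acetyl = FALSE)
  stopifnot(all(states$state %in% names(STATE_OFFSETS)))
  set.seed(seed)
  rules <- builtin_rules()
  rows <- list()
  for (i in seq_len(nrow(records))) {
    seq <- records$sequence[i]
    acc <- records$accession[i]
    applicable <- c(
      UNPROCESSED = TRUE,
      MAP_ONLY = rule_matches(seq, rules$MAP),
      DPP9_SHORT = rule_matches(seq, rules$DPP9_SHORT),
      MAP_DPP9 = rule_matches(seq, rules$DPP9_LONG)
    )
    keep <- applicable[states$state]
    if (any(!keep))
      warning("skipping inapplicable state(s) for ", acc, ": ",
              paste(states$state[!keep], collapse = ", "))
    st <- states[keep, , drop = FALSE]
    if (!nrow(st)) next
    offs <- STATE_OFFSETS[st$state]
    anchor <- min(offs) + 13L
    if (anchor > nchar(seq) || anchor < max(offs) + 7L) {
      warning("sequence too short for requested states: ", acc)
      next
    }
    nt <- data.frame(
      accession = acc,
      peptide = substring(seq, offs, anchor),
      nterm_acetyl = st$acetyl,
      state_truth = st$state,
      stringsAsFactors = FALSE
    )
    internal <- NULL
    if (n_internal > 0 && nchar(seq) >= anchor + 10L) {
      internal <- do.call(rbind, lapply(seq_len(n_internal), function(k) {
        for (try in 1:20) {
          start <- sample(seq(anchor + 2L, nchar(seq) - 7L), 1L)
          len <- sample(8:14, 1L)
          pep <- substr(seq, start, min(start + len - 1L, nchar(seq)))
          if (nchar(pep) >= 8L &&
              classify_peptide(seq, pep)$state == "INTERNAL")
            return(data.frame(accession = acc, peptide = pep,
                              nterm_acetyl = FALSE, state_truth = "INTERNAL",
                              stringsAsFactors = FALSE))
        }
        NULL
      }))
    }
    rows[[length(rows) + 1L]] <- rbind(nt, internal)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(accession = character(), peptide = character(),
                      nterm_acetyl = logical(), sample = character(),
                      intensity = numeric(), state_truth = character()))
  out$sample <- "S1"
  out$intensity <- 2^rnorm(nrow(out), mean = 20, sd = 1)
  # planted states must classify back exactly
  chk <- classify_peptides(out, records)
  stopifnot(identical(chk$state, out$state_truth))
  rownames(out) <- NULL
  out[, c("accession", "peptide", "nterm_acetyl", "sample", "intensity",
          "state_truth")]
}

#' Generate a planted LFQ matrix with lower-tail missingness
#'
#' Emulates a label-free pull-down experiment on the log2 scale: null
#' proteins scatter around `baseline` in both groups with within-group
#' standard deviation `sd`; `n_enriched` randomly chosen proteins are
#' shifted up by `effect_log2` in group A.  Setting `protein_sd > 0` adds a
#' per-protein abundance level drawn from `Normal(baseline, protein_sd^2)`,
#' emulating the dynamic range of real pull-downs; note that enriched
#' proteins whose level falls below the missingness threshold then become
#' genuinely undetectable, which lowers attainable recall.  Each cell is then masked
#' missing with probability `plogis(missing_slope * (missing_threshold -
#' value))` — non-increasing in the true intensity, i.e. missing not at
#' random in the lower tail.  `missing_slope = 0` disables missingness.
#' Returned intensities are on the raw scale (`2^value`), ready for
#' [prepare()].
#'
#' @param n_proteins,n_enriched matrix size and number of planted hits.
#' @param effect_log2 enrichment effect in group A, log2 units.
#' @param sd within-group replicate standard deviation (log2).
#' @param baseline mean log2 abundance over proteins.
#' @param protein_sd between-protein abundance spread (log2).
#' @param n_per_group replicates per group.
#' @param missing_threshold log2 intensity at which a cell is 50% likely to
#'   be missing.
#' @param missing_slope steepness of the missingness logistic (0 = none).
#' @param seed integer seed.
#' @return List of class `planted_lfq`: `intensity` (raw-scale matrix with
#'   `NA`), `groups` (named sample -> A/B), `truth` (enriched protein ids),
#'   `params`.
#' @export
gen_lfq <- function(n_proteins, n_enriched, effect_log2 = 3, sd = 0.5,
                    baseline = 25.5, protein_sd = 0, n_per_group = 3L,
                    missing_threshold = 21.5, missing_slope = 1,
                    seed = 1L) {
  stopifnot(n_enriched <= n_proteins, sd > 0, protein_sd >= 0,
            n_per_group >= 2L)
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  samples <- paste0("S", seq_len(2L * n_per_group))
  groups <- setNames(rep(c("A", "B"), each = n_per_group), samples)
  level <- rnorm(n_proteins, baseline, protein_sd)
  enriched <- sort(sample(n_proteins, n_enriched))
  mu <- matrix(level, n_proteins, 2L * n_per_group)
  mu[enriched, seq_len(n_per_group)] <- mu[enriched, seq_len(n_per_group)] +
    effect_log2
  val <- mu + matrix(rnorm(length(mu), 0, sd), nrow(mu), ncol(mu))
  if (missing_slope > 0) {
    p_miss <- plogis(missing_slope * (missing_threshold - val))
    miss <- matrix(runif(length(val)) < p_miss, nrow(val), ncol(val))
  } else {
    miss <- matrix(FALSE, nrow(val), ncol(val))
  }
  if (any(colSums(!miss) == 0))
    stop("missingness parameters produced an all-missing sample column")
  raw <- 2^val
  raw[miss] <- NA
  dimnames(raw) <- list(ids, samples)
  structure(list(
    intensity = raw, groups = groups, truth = ids[enriched],
    params = list(n_proteins = n_proteins, n_enriched = n_enriched,
                  effect_log2 = effect_log2, sd = sd, baseline = baseline,
                  protein_sd = protein_sd, n_per_group = n_per_group,
                  missing_threshold = missing_threshold,
                  missing_slope = missing_slope, seed = seed)),
    class = "planted_lfq")
}

#' Write a planted LFQ fixture (intensity TSV + groups TSV + truth + manifest)
#' @param lfq a [gen_lfq()] result.
#' @param dir output directory.
#' @export
write_planted_lfq <- function(lfq, dir) {
  stopifnot(inherits(lfq, "planted_lfq"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(protein = rownames(lfq$intensity), lfq$intensity,
                    check.names = FALSE)
  write.table(tab, file.path(dir, "lfq.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(data.frame(sample = names(lfq$groups),
                         group = unname(lfq$groups)),
              file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(protein = lfq$truth),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  p <- lfq$params
  writeLines(paste(names(p), vapply(p, paste, "", collapse = ","), sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}
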