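test_that("planted proteomes realize exact class counts with verified truth", {
  fr <- c(ibm_p2 = 0.05, dpp9_long_hidden_ibm = 0.10, dpp9_long_no_ibm = 0.05,
          dpp9_short_hidden_ibm = 0.04, dpp9_short_no_ibm = 0.05, none = 0.71)
  pp <- gen_proteome(500, fr, seed = 3)
  expect_equal(nrow(pp$records), 500L)
  expect_equal(sum(pp$truth$class == "dpp9_long_hidden_ibm"), 50L)  # exact
  expect_equal(sum(pp$truth$hidden_ibm), 70L)
  expect_equal(sum(pp$truth$ibm_p2), 25L)
  # truth equals the independent position-by-position checker on every record
  ora <- oracle_flags(pp$records$sequence)
  expect_equal(pp$truth$ibm_p2, ora$ibm_p2)
  expect_equal(pp$truth$dpp9_long, ora$dpp9_long)
  expect_equal(pp$truth$dpp9_short, ora$dpp9_short)
  expect_equal(pp$truth$hidden_ibm, ora$hidden_ibm)
  # length range respected
  expect_true(all(nchar(pp$records$sequence) >= 100 &
                  nchar(pp$records$sequence) <= 600))
})

test_that("proteome generation is seed-deterministic down to the FASTA bytes", {
  d1 <- file.path(tempdir(), "pp1"); d2 <- file.path(tempdir(), "pp2")
  write_planted_proteome(gen_proteome(120, seed = 7), d1)
  write_planted_proteome(gen_proteome(120, seed = 7), d2)
  for (f in c("proteome.fasta", "truth.tsv", "gene_map.tsv", "manifest.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_false(identical(
    gen_proteome(120, seed = 7)$records$sequence,
    gen_proteome(120, seed = 8)$records$sequence))
})

test_that("an all-background proteome screens to zero", {
  fr <- c(ibm_p2 = 0, dpp9_long_hidden_ibm = 0, dpp9_long_no_ibm = 0,
          dpp9_short_hidden_ibm = 0, dpp9_short_no_ibm = 0, none = 1)
  pp <- gen_proteome(100, fr, seed = 2)
  s <- run_screen(pp$records, pp$gene_map)$summary
  expect_equal(s$n_ibm_p2 + s$n_dpp9_total + s$n_hidden_ibm, 0L)
  expect_error(gen_proteome(100, replace(fr, 1, -0.1), seed = 2), "sum to 1")
})

test_that("generated peptides reproduce the canonical AK2 triple and recover truth", {
  rec <- data.frame(accession = "AK2.1", gene = NA, sequence = AK2_SEQ,
                    source_header = "")
  peps <- gen_peptides(rec, n_internal = 3, seed = 4)
  nterm <- peps[peps$state_truth != "INTERNAL", ]
  expect_setequal(nterm$peptide,
                  c("MAPSVPAAEPEYPK", "APSVPAAEPEYPK", "SVPAAEPEYPK"))
  expect_true(nterm$nterm_acetyl[nterm$state_truth == "UNPROCESSED"])
  # classification recovers every planted state, internals included
  out <- classify_peptides(peps, rec)
  expect_equal(out$state, peps$state_truth)
  expect_equal(sum(peps$state_truth == "INTERNAL"), 3L)
})

test_that("inapplicable states are skipped with a warning", {
  rec <- data.frame(accession = "MD1.1", gene = NA,
                    sequence = "MDGKLVRSTAQWEHNPLYTRGAKDEFI", source_header = "")
  expect_warning(peps <- gen_peptides(rec, seed = 4), "inapplicable")
  expect_false(any(peps$state_truth %in% c("MAP_ONLY", "MAP_DPP9")))
  expect_true(any(peps$state_truth == "UNPROCESSED"))
})

test_that("planted LFQ matrices carry the promised structure", {
  lfq <- gen_lfq(200, 10, seed = 6)
  expect_equal(dim(lfq$intensity), c(200L, 6L))
  expect_equal(unname(lfq$groups), rep(c("A", "B"), each = 3))
  expect_length(lfq$truth, 10L)
  expect_true(all(lfq$intensity > 0, na.rm = TRUE))
  # enriched proteins really are shifted: compare group means on hits
  m <- log2(lfq$intensity)
  diffs <- rowMeans(m[, 1:3], na.rm = TRUE) - rowMeans(m[, 4:6], na.rm = TRUE)
  expect_gt(min(diffs[lfq$truth], na.rm = TRUE), 1)
  # determinism
  expect_identical(lfq$intensity, gen_lfq(200, 10, seed = 6)$intensity)
})

test_that("missingness is lower-tail and switches off at slope zero", {
  none <- gen_lfq(100, 5, missing_slope = 0, seed = 13)
  expect_false(anyNA(none$intensity))
  # with a wide abundance spread, low-level proteins lose more cells
  lfq <- gen_lfq(400, 0, protein_sd = 3, missing_threshold = 24, seed = 14)
  obs_level <- rowMeans(log2(lfq$intensity), na.rm = TRUE)
  miss <- rowMeans(is.na(lfq$intensity))
  miss <- miss[is.finite(obs_level)]
  obs_level <- obs_level[is.finite(obs_level)]
  lo <- miss[obs_level < quantile(obs_level, 0.3, na.rm = TRUE)]
  hi <- miss[obs_level > quantile(obs_level, 0.7, na.rm = TRUE)]
  expect_gt(mean(lo), mean(hi) + 0.2)
  # raising the threshold can only increase missingness
  more <- gen_lfq(400, 0, protein_sd = 3, missing_threshold = 27, seed = 14)
  expect_gt(mean(is.na(more$intensity)), mean(is.na(lfq$intensity)))
})

test_that("planted LFQ fixtures round-trip through the TSV readers", {
  lfq <- gen_lfq(50, 5, seed = 17)
  dir <- file.path(tempdir(), "lfqfix")
  write_planted_lfq(lfq, dir)
  back <- read_lfq(file.path(dir, "lfq.tsv"), file.path(dir, "groups.tsv"))
  expect_equal(back$groups, lfq$groups)
  expect_equal(is.na(back$intensity), is.na(lfq$intensity))
  expect_equal(back$intensity, lfq$intensity, tolerance = 1e-6)
})
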