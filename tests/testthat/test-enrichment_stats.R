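make_matrix <- function(vals, samples = paste0("S", seq_len(ncol(vals)))) {
  colnames(vals) <- samples
  rownames(vals) <- sprintf("P%02d", seq_len(nrow(vals)))
  vals
}
GRP <- c(S1 = "A", S2 = "A", S3 = "A", S4 = "B", S5 = "B", S6 = "B")

test_that("min-valid filtering keeps the documented protein sets", {
  x <- make_matrix(rbind(
    c(10, 12, 14, NA, NA, NA),   # 3/3 in A, 0/3 in B
    c(10, NA, NA, 12, NA, NA),   # 1/3 in both
    c(10, 12, NA, 14, 16, NA),   # 2/3 in both
    c(10, 12, 14, 16, 18, 20)    # complete
  ))
  any_mode <- prepare(x, GRP, min_valid = 2, groups_mode = "any")
  expect_equal(rownames(any_mode), c("P01", "P03", "P04"))
  all_mode <- prepare(x, GRP, min_valid = 2, groups_mode = "all")
  expect_equal(rownames(all_mode), c("P03", "P04"))
  ip_mode <- prepare(x, GRP, min_valid = 3, groups_mode = "any")
  expect_equal(rownames(ip_mode), c("P01", "P04"))
  # values are log2 of the raw intensities
  expect_equal(unname(all_mode["P04", "S1"]), log2(10))
  expect_error(prepare(make_matrix(rbind(c(-1, 2, 3, 4, 5, 6))), GRP),
               "strictly positive")
})

test_that("filtering matches a brute-force reimplementation on planted matrices", {
  lfq <- gen_lfq(150, 10, protein_sd = 2, missing_threshold = 24, seed = 9)
  kept <- rownames(prepare(lfq$intensity, lfq$groups))
  brute <- rownames(lfq$intensity)[apply(lfq$intensity, 1, function(r) {
    sum(!is.na(r[1:3])) >= 2 || sum(!is.na(r[4:6])) >= 2
  })]
  expect_equal(kept, brute)
})

test_that("lower-tail imputation draws where and only where values are missing", {
  set.seed(77)
  x <- make_matrix(matrix(rnorm(600, 25, 1), 100, 6))
  x[sample(length(x), 120)] <- NA
  done <- impute_lower_tail(x, 1.8, 0.3, seed = 42)
  expect_false(anyNA(done))
  expect_identical(done[!is.na(x)], x[!is.na(x)])        # present cells untouched
  expect_identical(attr(done, "imputed"), is.na(x))
  again <- impute_lower_tail(x, 1.8, 0.3, seed = 42)
  expect_identical(done, again)                          # bit-reproducible
  other <- impute_lower_tail(x, 1.8, 0.3, seed = 43)
  expect_false(identical(done[is.na(x)], other[is.na(x)]))
  # no missing cells: matrix unchanged
  full <- make_matrix(matrix(rnorm(60, 25, 1), 10, 6))
  expect_equal(unname(impute_lower_tail(full)[, ]), unname(full[, ]))
})

test_that("imputation scope and degenerate inputs behave as documented", {
  x <- make_matrix(rbind(c(10, 20, NA), c(12, 22, NA), c(14, 24, 30),
                         c(16, 26, 31)), samples = c("S1", "S2", "S3"))
  bycol <- impute_lower_tail(x, 1.8, 0.3, scope = "column", seed = 1)
  # column S3 imputes from its own (30, 31) distribution, far above S1's
  expect_true(all(bycol[1:2, "S3"] > 25))
  const <- make_matrix(matrix(5, 3, 3), samples = c("S1", "S2", "S3"))
  const[1, 1] <- NA
  expect_error(impute_lower_tail(const), "zero spread")
  tiny <- make_matrix(matrix(c(1, NA, NA, NA), 2, 2), samples = c("S1", "S2"))
  expect_error(impute_lower_tail(tiny), "fewer than 2")
})

test_that("imputed values are calibrated to the down-shifted normal", {
  set.seed(5)
  x <- make_matrix(matrix(rnorm(3000 * 6, 25, 1), 3000, 6))
  x[sample(length(x), 12000)] <- NA
  mu <- mean(x, na.rm = TRUE); sigma <- sd(as.vector(x), na.rm = TRUE)
  done <- impute_lower_tail(x, 1.8, 0.3, seed = 8)
  imp <- done[is.na(x)]
  se <- 0.3 * sigma / sqrt(length(imp))
  expect_lt(abs(mean(imp) - (mu - 1.8 * sigma)), 3 * se)
  expect_lt(abs(sd(imp) - 0.3 * sigma) / (0.3 * sigma), 0.05)
})

test_that("the pooled t-test agrees with the closed form and stats::t.test", {
  x <- make_matrix(rbind(c(1, 2, 3, 4, 5, 6)))
  row <- t_test_two_sample(x, GRP)
  expect_equal(row$t, -3.6742, tolerance = 1e-4)
  expect_equal(row$p, 0.02131, tolerance = 1e-3)
  expect_equal(row$df, 4)
  expect_equal(row$difference, -3)

  set.seed(99)
  y <- make_matrix(matrix(rnorm(50 * 6, 20, 2), 50, 6))
  rows <- t_test_two_sample(y, GRP)
  for (i in c(1, 7, 25, 50)) {
    ref <- t.test(y[i, 1:3], y[i, 4:6], var.equal = TRUE)
    expect_equal(rows$t[i], unname(ref$statistic))
    expect_equal(rows$p[i], ref$p.value)
    expect_equal(rows$difference[i], unname(diff(rev(ref$estimate))))
  }
  # symmetry: putting the other group first flips t and difference, not p
  swapped <- t_test_two_sample(y[, c(4:6, 1:3)], GRP)
  expect_equal(swapped$t, -rows$t)
  expect_equal(swapped$difference, -rows$difference)
  expect_equal(swapped$p, rows$p)
  # identical groups: t = 0, p = 1
  z <- make_matrix(matrix(rep(c(3, 4, 5), 2), 1, 6))
  expect_equal(t_test_two_sample(z, GRP)$t, 0)
  expect_equal(t_test_two_sample(z, GRP)$p, 1)
  expect_error(t_test_two_sample(make_matrix(rbind(c(1, NA, 3, 4, 5, 6))), GRP),
               "impute")
})

test_that("hit classification applies the -log10 p cut-off and sign rule", {
  rows <- data.frame(protein = c("a", "b", "c", "d"),
                     difference = c(3, -3, 1, 2),
                     t = c(8, -8, 1, 5), df = 4,
                     p = c(0.001, 0.001, 0.4, 0.02131),
                     neg_log10_p = -log10(c(0.001, 0.001, 0.4, 0.02131)),
                     n_imputed_A = 0L, n_imputed_B = 0L)
  out <- classify_hits(rows)
  expect_equal(out$protein[out$significant], "a")        # b fails the sign rule
  both <- classify_hits(rows, require_positive_difference = FALSE)
  expect_setequal(both$protein[both$significant], c("a", "b"))
  # the worked t-test example sits below the cut-off: -log10(0.02131) ~ 1.67
  expect_false(out$significant[out$protein == "d"])
  expect_equal(out$p, sort(rows$p))                      # volcano order: by p
  expect_true(all(c("q") %in% names(out)))               # BH column emitted only
})

test_that("presets wire the documented parameter sets through the pipeline", {
  expect_equal(enrichment_preset("pulldown")[c("min_valid", "downshift", "width")],
               list(min_valid = 2L, downshift = 1.8, width = 0.3))
  expect_equal(enrichment_preset("ip")[c("min_valid", "downshift", "width")],
               list(min_valid = 3L, downshift = 2.0, width = 0.3))
  lfq <- gen_lfq(120, 6, seed = 21)
  res <- enrichment_pipeline(lfq$intensity, lfq$groups, preset = "pulldown",
                             seed = 22)
  expect_true(all(res$table$significant == (res$table$neg_log10_p >= 2 &
                                            res$table$difference > 0)))
  expect_gt(mean(lfq$truth %in% res$hits), 0.5)
})
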