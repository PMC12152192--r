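#' Analysis presets for pull-down and IP experiments
#'
#' The two documented parameter sets of the quantitative workflow:
#' \describe{
#'   \item{pulldown}{min-valid filter 2 of 3 (in at least one group),
#'     imputation downshift 1.8, width 0.3.}
#'   \item{ip}{min-valid filter 3 of 3, downshift 2.0, width 0.3.}
#' }
#' @param name `"pulldown"` or `"ip"`.
#' @return List of parameters consumed by [enrichment_pipeline()].
#' @export
enrichment_preset <- function(name = c("pulldown", "ip")) {
  name <- match.arg(name)
  switch(name,
    pulldown = list(min_valid = 2L, of = 3L, groups_mode = "any",
                    downshift = 1.8, width = 0.3),
    ip = list(min_valid = 3L, of = 3L, groups_mode = "any",
              downshift = 2.0, width = 0.3)
  )
}

check_groups <- function(x, groups) {
  if (is.null(names(groups))) names(groups) <- colnames(x)
  if (!setequal(names(groups), colnames(x)))
    stop("group labels must cover exactly the matrix columns")
  groups <- groups[colnames(x)]
  lv <- unique(unname(groups))
  if (length(lv) != 2L) stop("exactly two groups required, got: ",
                             paste(lv, collapse = ", "))
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  groups
}

#' Filter and log-transform an LFQ intensity matrix
#'
#' Raw intensities must be strictly positive where present (`NA` = missing).
#' Present values are log-transformed (base 2 by default — the base only
#' rescales differences, never p-values) and a protein is retained iff it
#' has at least `min_valid` present values in at least one group
#' (`groups_mode = "any"`, the pull-down default) or in each group
#' (`"all"`).
#'
#' @param x numeric matrix, proteins x samples, `NA` for missing.
#' @param groups named vector mapping sample (column) -> group label; must
#'   contain exactly two levels with >= 2 samples each.
#' @param min_valid minimum number of quantified replicates.
#' @param groups_mode `"any"` or `"all"`.
#' @param log_base logarithm base for the transform.
#' @return The filtered, log-transformed matrix; attribute `groups` carries
#'   the (reordered) group vector.
#' @export
prepare <- function(x, groups, min_valid = 2L, groups_mode = c("any", "all"),
                    log_base = 2) {
  groups_mode <- match.arg(groups_mode)
  stopifnot(is.matrix(x), is.numeric(x))
  groups <- check_groups(x, groups)
  if (any(x[!is.na(x)] <= 0))
    stop("intensities must be strictly positive before log transform")
  lv <- unique(unname(groups))
  valid <- vapply(lv, function(g)
    rowSums(!is.na(x[, names(groups)[groups == g], drop = FALSE])),
    numeric(nrow(x)))
  if (!is.matrix(valid)) valid <- matrix(valid, nrow = nrow(x))
  pass <- valid >= min_valid
  keep <- if (groups_mode == "any") rowSums(pass) >= 1L
          else rowSums(pass) == ncol(pass)
  out <- log(x[keep, , drop = FALSE], base = log_base)
  attr(out, "groups") <- groups
  out
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Perseus-style lower-tail imputation: with `mu` and `sigma` the mean and
#' standard deviation of all present (log-scale) values in scope, each
#' missing cell is replaced by an independent draw from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)`.  The default scope
#' is the whole matrix ("the distribution of all measured and quantified
#' proteins"); `scope = "column"` computes `mu`/`sigma` per sample instead.
#' Present cells are never touched.
#'
#' @param x log-transformed matrix with `NA` for missing.
#' @param downshift shift of the imputation distribution, in units of
#'   `sigma` (1.8 for pull-downs, 2.0 for IPs).
#' @param width standard deviation of the imputation distribution, in units
#'   of `sigma` (0.3).
#' @param scope `"matrix"` or `"column"`.
#' @param seed optional integer; when given the draw is reproducible
#'   (`set.seed` is called).
#' @return The completed matrix, with a logical attribute `imputed` marking
#'   the filled cells.  Fewer than 2 present values in any scope, or zero
#'   spread (`sigma` = 0), is an error.
#' @export
impute_lower_tail <- function(x, downshift = 1.8, width = 0.3,
                              scope = c("matrix", "column"), seed = NULL) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(x), downshift > 0, width > 0)
  if (!is.null(seed)) set.seed(seed)
  miss <- is.na(x)
  out <- x
  draw <- function(vals, k) {
    if (sum(!is.na(vals)) < 2L)
      stop("cannot impute: fewer than 2 present values in scope")
    mu <- mean(vals, na.rm = TRUE)
    sigma <- sd(vals, na.rm = TRUE)
    if (sigma == 0)
      stop("cannot impute: zero spread of present values in scope")
    rnorm(k, mean = mu - downshift * sigma, sd = width * sigma)
  }
  if (scope == "matrix") {
    k <- sum(miss)
    if (k > 0) out[miss] <- draw(as.vector(x), k)
  } else {
    for (j in seq_len(ncol(x))) {
      k <- sum(miss[, j])
      if (k > 0) out[miss[, j], j] <- draw(x[, j], k)
    }
  }
  attr(out, "imputed") <- miss
  attr(out, "groups") <- attr(x, "groups")
  out
}

#' Row-wise equal-variance two-sample t-tests
#'
#' Classical pooled-variance (Student) two-sample t-test per protein on a
#' completed log-intensity matrix; two-sided p from the t distribution with
#' `nA + nB - 2` degrees of freedom.  The reported difference is
#' `mean(A) - mean(B)`.
#'
#' @param x completed numeric matrix (no `NA`), proteins x samples.
#' @param groups named sample -> group vector; the *first* unique label is
#'   taken as group A (enriched side).
#' @return Data frame: `protein`, `difference`, `t`, `df`, `p`,
#'   `neg_log10_p`, `n_imputed_A`, `n_imputed_B` (zero when `x` carries no
#'   `imputed` attribute).
#' @export
t_test_two_sample <- function(x, groups = attr(x, "groups")) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("matrix still contains missing values; impute first")
  groups <- check_groups(x, groups)
  lv <- unique(unname(groups))
  ia <- which(unname(groups) == lv[1])
  ib <- which(unname(groups) == lv[2])
  na <- length(ia); nb <- length(ib)
  A <- x[, ia, drop = FALSE]
  B <- x[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se == 0, 0, (ma - mb) / se)
  df <- na + nb - 2
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  imp <- attr(x, "imputed")
  n_imp_a <- if (is.null(imp)) 0L else rowSums(imp[, ia, drop = FALSE])
  n_imp_b <- if (is.null(imp)) 0L else rowSums(imp[, ib, drop = FALSE])
  data.frame(
    protein = if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x),
    difference = ma - mb,
    t = tstat,
    df = df,
    p = p,
    neg_log10_p = -log10(p),
    n_imputed_A = as.integer(n_imp_a),
    n_imputed_B = as.integer(n_imp_b),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Call significant enrichment hits
#'
#' Fixed-cutoff rule: significant iff `-log10(p) >= cutoff` and (optionally)
#' the difference is positive, i.e. enriched on the A side.  No multiple
#' testing correction enters the call; a Benjamini-Hochberg `q` column is
#' emitted for reference only.
#'
#' @param rows output of [t_test_two_sample()].
#' @param cutoff_neg_log10_p cut-off on the decadal log of the p value
#'   (default 2, i.e. p <= 0.01).
#' @param require_positive_difference restrict hits to positive differences.
#' @return `rows` sorted by p, with added `q` and `significant` columns.
#' @export
classify_hits <- function(rows, cutoff_neg_log10_p = 2,
                          require_positive_difference = TRUE) {
  rows$q <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$neg_log10_p >= cutoff_neg_log10_p
  if (require_positive_difference)
    rows$significant <- rows$significant & rows$difference > 0
  rows <- rows[order(rows$p), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Run the full enrichment workflow
#'
#' Chains [prepare()] -> [impute_lower_tail()] -> [t_test_two_sample()] ->
#' [classify_hits()] under a named preset.
#'
#' @param x raw intensity matrix (positive or `NA`), proteins x samples.
#' @param groups named sample -> group vector (first level = enriched side).
#' @param preset preset name, see [enrichment_preset()].
#' @param cutoff_neg_log10_p significance cut-off on -log10(p).
#' @param scope imputation scope.
#' @param seed seed for the imputation draw.
#' @return List with `table` (the classified volcano table), `hits`
#'   (significant protein ids) and `params`.
#' @export
enrichment_pipeline <- function(x, groups, preset = "pulldown",
                                cutoff_neg_log10_p = 2,
                                scope = "matrix", seed = NULL) {
  p <- enrichment_preset(preset)
  m <- prepare(x, groups, min_valid = p$min_valid, groups_mode = p$groups_mode)
  m <- impute_lower_tail(m, downshift = p$downshift, width = p$width,
                         scope = scope, seed = seed)
  tab <- classify_hits(t_test_two_sample(m),
                       cutoff_neg_log10_p = cutoff_neg_log10_p)
  list(table = tab, hits = tab$protein[tab$significant],
       params = c(p, list(cutoff_neg_log10_p = cutoff_neg_log10_p,
                          scope = scope, seed = seed)))
}

#' Read an LFQ intensity TSV and group table
#'
#' `path`: TSV with a `protein` id column and one numeric column per
#' sample; empty cells, `NA` or `0` are treated as missing.  `group_path`:
#' two-column TSV (sample, group).
#'
#' @param path intensity TSV path.
#' @param group_path group TSV path.
#' @return List with `intensity` (matrix) and `groups` (named vector).
#' @export
read_lfq <- function(path, group_path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"protein" %in% names(tab)) stop("intensity TSV needs a 'protein' column")
  m <- as.matrix(tab[, setdiff(names(tab), "protein"), drop = FALSE])
  storage.mode(m) <- "double"
  m[m == 0] <- NA
  rownames(m) <- tab$protein
  g <- read.delim(group_path, stringsAsFactors = FALSE)
  groups <- setNames(as.character(g[[2]]), as.character(g[[1]]))
  list(intensity = m, groups = groups)
}

#' Write a volcano table to TSV
#' @param table classified table from [classify_hits()].
#' @param path output TSV path.
#' @export
write_volcano <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Volcano plot of an enrichment table
#'
#' @param table classified table from [classify_hits()].
#' @param cutoff_neg_log10_p horizontal cut-off line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(table, cutoff_neg_log10_p = 2) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$difference, y = .data$neg_log10_p,
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cutoff_neg_log10_p, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "difference (log2, A - B)", y = "-log10 p") +
    ggplot2::theme_classic()
}
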