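# The core method: pooled two-sample t-statistics computed per probe on
# normalized intensities, aggregated per gene by the median, and genes ranked
# by |median t|. Because the t-statistic is scale- and location-invariant,
# the per-probe t on intensities Y = B + phi * theta equals the t on the
# underlying concentration theta, so neither background correction nor
# summarization is needed. A standard gene-level t-test on summarized
# expression values is provided as the comparison baseline.

# Vectorized pooled t over the rows of Y. Zero pooled variance yields t = 0
# when the group means are equal and a signed infinity sentinel otherwise.
pooled_t_rows <- function(y, idx_a, idx_b) {
  n_a <- length(idx_a)
  n_b <- length(idx_b)
  m_a <- rowMeans(y[, idx_a, drop = FALSE])
  m_b <- rowMeans(y[, idx_b, drop = FALSE])
  ss_a <- rowSums((y[, idx_a, drop = FALSE] - m_a)^2)
  ss_b <- rowSums((y[, idx_b, drop = FALSE] - m_b)^2)
  a <- (1 / n_a + 1 / n_b) / (n_a + n_b - 2)
  s <- sqrt(a * (ss_a + ss_b))
  d <- m_a - m_b
  t <- d / s
  zero <- s == 0
  t[zero & d == 0] <- 0
  t[zero & d > 0] <- Inf
  t[zero & d < 0] <- -Inf
  list(t = t, df = n_a + n_b - 2, mean_a = m_a, mean_b = m_b, s = s)
}

#' Pooled two-sample t-statistic
#'
#' Computes t = (mean(A) - mean(B)) / s with the pooled empirical standard
#' deviation s = sqrt(a * (SS_A + SS_B)), a = (1/n_A + 1/n_B)/(n_A + n_B - 2)
#' and SS the within-group sums of squared deviations. Equal-variance pooled
#' form only (no Welch variant). With zero pooled variance, t is 0 if the
#' group means are equal and a signed infinity sentinel otherwise.
#'
#' @param values_A,values_B numeric vectors, each of length `>= 2`.
#' @return An object of class `pooled_t`: fields `t`, `df`
#'   (`= n_A + n_B - 2`), `group_means` (named pair), `pooled_sd_term`.
#' @examples
#' pooled_t(c(4, 6), c(1, 3))  # t = 3/sqrt(2)
#' @export
pooled_t <- function(values_A, values_B) {
  if (length(values_A) < 2L || length(values_B) < 2L) {
    pt_validation_error("each group needs >= 2 values")
  }
  y <- matrix(c(values_A, values_B), nrow = 1L)
  st <- pooled_t_rows(y, seq_along(values_A),
                      length(values_A) + seq_along(values_B))
  structure(list(t = st$t, df = st$df,
                 group_means = c(A = st$mean_a, B = st$mean_b),
                 pooled_sd_term = st$s),
            class = "pooled_t")
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("pooled t = %.6g on %d df (mean A = %.6g, mean B = %.6g)\n",
              x$t, x$df, x$group_means[["A"]], x$group_means[["B"]]))
  invisible(x)
}

match_design <- function(pm, design) {
  idx_a <- match(intersect(samples_of(design, "A"), pm$sample_ids),
                 pm$sample_ids)
  idx_b <- match(intersect(samples_of(design, "B"), pm$sample_ids),
                 pm$sample_ids)
  unlabeled <- setdiff(pm$sample_ids,
                       c(samples_of(design, "A"), samples_of(design, "B")))
  if (length(unlabeled)) {
    pt_validation_error(paste0("sample '", unlabeled[[1L]],
                               "' has no condition label"))
  }
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    pt_validation_error("need >= 2 matrix samples per condition")
  }
  list(a = idx_a, b = idx_b)
}

#' Per-probe t-statistics, grouped by gene
#'
#' Applies [pooled_t()] to every probe row of a (normalized) intensity
#' matrix. Within each gene the t-values are returned ordered by probe id.
#'
#' @param pm a [probe_matrix()], normally the output of
#'   [quantile_normalize()]. If the matrix does not look quantile-normalized
#'   a warning is emitted (the test is still computed).
#' @param design a [two_group_design()] labeling all matrix samples.
#' @param check_normalized emit the warning above (default `TRUE`).
#' @return Named list, gene id -> numeric vector of probe t-values (named by
#'   probe id, ordered by probe id).
#' @export
probe_t_values <- function(pm, design, check_normalized = TRUE) {
  validate_probe_matrix(pm)
  idx <- match_design(pm, design)
  if (check_normalized && !sanity_check_normalized(pm)) {
    warning("matrix does not look quantile-normalized; ",
            "per-probe t-tests assume comparable arrays", call. = FALSE)
  }
  t <- pooled_t_rows(pm$values, idx$a, idx$b)$t
  names(t) <- pm$probe_ids
  o <- order(pm$probe_to_gene[pm$probe_ids], pm$probe_ids, method = "radix")
  split(t[o], pm$probe_to_gene[pm$probe_ids][o])
}

# |median t| per gene without building per-gene lists; vectorized via one
# radix sort when all genes share a probe count (the common platform case).
median_t_scores <- function(pm, design) {
  idx <- match_design(pm, design)
  t <- pooled_t_rows(pm$values, idx$a, idx$b)$t
  gene_of <- if (identical(names(pm$probe_to_gene), pm$probe_ids)) {
    unname(pm$probe_to_gene)
  } else {
    pm$probe_to_gene[pm$probe_ids]
  }
  o <- order(gene_of, method = "radix")
  g_sorted <- gene_of[o]
  counts <- rle(g_sorted)
  if (length(unique(counts$lengths)) == 1L) {
    med <- col_medians(matrix(t[o], nrow = counts$lengths[[1L]]))
    names(med) <- counts$values
  } else {
    med <- vapply(split(t[o], g_sorted), median_extended, numeric(1))
  }
  abs(med)
}

#' Median t-value per gene
#'
#' The per-gene aggregate of the probe-level t-statistics: the sample median,
#' chosen over the mean for robustness to outlying probes. Even-length
#' vectors use the mean of the two central order statistics. Infinite
#' sentinels participate in the ordering (extended real line); an opposite
#' (-Inf, Inf) central pair is defined as 0.
#'
#' @param probe_ts named list, gene id -> non-empty numeric vector, as
#'   returned by [probe_t_values()].
#' @return Named numeric vector of median t-values.
#' @export
median_t_per_gene <- function(probe_ts) {
  if (any(lengths(probe_ts) == 0L)) {
    pt_validation_error("every gene needs >= 1 probe t-value")
  }
  vapply(probe_ts, median_extended, numeric(1))
}

#' Rank genes by the magnitude of their median t-value
#'
#' Sorts genes by descending `|median_t|` (differential expression in either
#' direction counts as evidence; infinite sentinels rank above all finite
#' values), breaking ties by gene id, and assigns ranks 1..n.
#'
#' @param median_ts named numeric vector, gene id -> median t.
#' @param p_values named numeric vector on the same key set (may be `NA` when
#'   p-values were not computed).
#' @param n_probes optional named integer vector of per-gene probe counts.
#' @return A `gene_test_results` data frame with columns `gene_id`,
#'   `n_probes`, `median_t`, `p_value`, `rank`, ordered by rank.
#' @export
rank_genes <- function(median_ts, p_values = NULL, n_probes = NULL) {
  genes <- names(median_ts)
  if (is.null(genes)) pt_validation_error("median_ts must be named by gene id")
  if (is.null(p_values)) {
    p_values <- rep(NA_real_, length(genes))
    names(p_values) <- genes
  }
  if (!setequal(genes, names(p_values))) {
    pt_validation_error("median_ts and p_values must share one gene id set")
  }
  o <- order(-abs(median_ts), genes, method = "radix")
  out <- data.frame(
    gene_id = genes[o],
    n_probes = if (is.null(n_probes)) NA_integer_ else
      as.integer(n_probes[genes[o]]),
    median_t = unname(median_ts[o]),
    p_value = unname(p_values[genes[o]]),
    rank = seq_along(genes),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_test_results", "data.frame")
  out
}

#' Gene-level pooled t-test on summarized expression (comparison baseline)
#'
#' The standard approach the probe-level test is compared against: one
#' pooled two-sample t-statistic per gene computed on expression values
#' summarized by a preprocessing method. Unlike the probe-level test, its
#' result changes under monotone transforms (e.g. log2) of the expression
#' scale.
#'
#' @param expression numeric matrix, rows = genes, columns = samples, with
#'   dimnames.
#' @param design a [two_group_design()].
#' @return Data frame with columns `gene_id`, `t`, `df`, `mean_A`, `mean_B`,
#'   `pooled_sd_term`, in the row order of `expression`.
#' @export
gene_level_t_baseline <- function(expression, design) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    pt_validation_error("expression matrix needs gene and sample dimnames")
  }
  idx_a <- match(intersect(samples_of(design, "A"), colnames(expression)),
                 colnames(expression))
  idx_b <- match(intersect(samples_of(design, "B"), colnames(expression)),
                 colnames(expression))
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    pt_validation_error("need >= 2 expression columns per condition")
  }
  st <- pooled_t_rows(expression, idx_a, idx_b)
  data.frame(gene_id = rownames(expression), t = st$t, df = st$df,
             mean_A = st$mean_a, mean_B = st$mean_b, pooled_sd_term = st$s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full probe-level differential expression test
#'
#' The package's main pipeline: (optionally) quantile-normalize, compute the
#' per-probe pooled t-statistics, take the per-gene median, assign analytic
#' p-values from the null distribution of the median of n i.i.d. t-variates
#' ([median_t_distribution()]), and rank genes by `|median_t|`. For fixed
#' probe count and degrees of freedom the `|median_t|` ranking and the
#' ascending two-sided p-value ranking coincide.
#'
#' @param pm a [probe_matrix()] of raw intensities.
#' @param design a [two_group_design()].
#' @param normalize quantile-normalize before testing (default `TRUE`).
#' @param sided `"two"` (default) or `"one"`; see [p_value()].
#' @param p_values compute analytic p-values (default `TRUE`); skip for
#'   speed when only the ranking is needed.
#' @return A `gene_test_results` data frame (see [rank_genes()]) with the
#'   per-gene probe t-vectors attached as attribute `"probe_t"`.
#' @export
probe_level_test <- function(pm, design, normalize = TRUE,
                             sided = c("two", "one"), p_values = TRUE) {
  sided <- match.arg(sided)
  if (normalize) pm <- quantile_normalize(pm)
  probe_ts <- probe_t_values(pm, design, check_normalized = !normalize)
  med <- median_t_per_gene(probe_ts)
  n_per_gene <- lengths(probe_ts)
  pv <- NULL
  if (p_values) {
    idx <- match_design(pm, design)
    df <- length(idx$a) + length(idx$b) - 2L
    pv <- median_t_p_values(med, n_per_gene, df, sided = sided)
  }
  out <- rank_genes(med, pv, n_probes = n_per_gene)
  attr(out, "probe_t") <- probe_ts
  out
}

#' Write ranked gene results as tab-separated text
#'
#' Columns `gene_id`, `n_probes`, `median_t`, `p_value`, `rank`, ordered by
#' rank ascending; numeric columns rendered with at least 6 significant
#' digits.
#'
#' @param results a `gene_test_results` data frame ([rank_genes()]).
#' @param path output path.
#' @return `results`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!all(c("gene_id", "median_t", "p_value", "rank") %in% names(results))) {
    pt_validation_error("results must have gene_id, median_t, p_value, rank")
  }
  res <- results[order(results$rank), , drop = FALSE]
  fmt <- function(x) formatC(x, digits = 9, format = "g", width = 1)
  lines <- c(
    "gene_id\tn_probes\tmedian_t\tp_value\trank",
    if (nrow(res)) paste(res$gene_id, res$n_probes, fmt(res$median_t),
                         fmt(res$p_value), res$rank, sep = "\t")
  )
  write_lines_checked(lines, path)
  invisible(results)
}

#' Read a results table written by [write_results()]
#'
#' @param path results TSV path.
#' @return A `gene_test_results` data frame.
#' @export
read_results <- function(path) {
  out <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) pt_io_error(paste0("cannot read ", path, ": ",
                                           conditionMessage(e))))
  class(out) <- c("gene_test_results", "data.frame")
  out
}
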