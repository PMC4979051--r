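# Figures of merit: average ROC over the rearranged spike-in experiments
# (sensitivity) and mean top-N list overlap across random sample subsets
# (robustness).

#' ROC curve of a gene ranking against a truth set
#'
#' Sweeps descending score thresholds; at each threshold the called set is
#' every gene with score >= threshold. TP rate = |truth called| / |truth|,
#' FP rate = |non-truth called| / |non-truth|. Genes in `excluded` are
#' removed before computing rates. AUC by the trapezoid rule.
#'
#' @param scores named numeric vector, gene id -> ranking score (higher =
#'   more significant; e.g. `abs(median_t)`).
#' @param truth character vector of truly differential gene ids (non-empty
#'   after exclusions).
#' @param excluded gene ids removed from evaluation.
#' @return An object of class `roc_curve`: `thresholds`, `fp_rate`,
#'   `tp_rate` (aligned, starting at (0,0) and ending at (1,1)), `auc`, and
#'   the per-called-count sweeps `tp_count`/`fp_count` used for averaging.
#' @export
roc_curve <- function(scores, truth, excluded = character(0)) {
  if (is.null(names(scores))) {
    pt_validation_error("scores must be named by gene id")
  }
  keep <- setdiff(names(scores), excluded)
  s <- scores[keep]
  truth <- setdiff(truth, excluded)
  is_pos <- keep %in% truth
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L) pt_validation_error("truth set is empty after exclusions")
  if (n_neg == 0L) pt_validation_error("no non-truth genes to estimate FP rate")
  o <- order(s, decreasing = TRUE)
  tp <- cumsum(is_pos[o])
  fp <- cumsum(!is_pos[o])
  # collapse ties: a threshold realizes only the last point of a tie block
  last_of_block <- c(s[o][-1L] != s[o][-length(o)], TRUE)
  structure(list(
    thresholds = c(Inf, s[o][last_of_block]),
    fp_rate = c(0, fp[last_of_block] / n_neg),
    tp_rate = c(0, tp[last_of_block] / n_pos),
    auc = trapezoid_auc(c(0, fp[last_of_block] / n_neg),
                        c(0, tp[last_of_block] / n_pos)),
    tp_count = c(0L, tp), fp_count = c(0L, fp),
    n_truth = n_pos, n_null = n_neg
  ), class = "roc_curve")
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Average several ROC curves
#'
#' Averages TP and FP rates index-wise over a common grid of called-gene
#' counts (the only parameterization that makes curves from different
#' experiments commensurable without interpolation assumptions); curves of
#' unequal length are linearly resampled onto the longest grid by called
#' fraction. The AUC of the averaged polyline is reported.
#'
#' @param curves list of `roc_curve` objects (length >= 1).
#' @return A `roc_curve` (thresholds are `NA`: an averaged curve has none).
#' @export
average_roc <- function(curves) {
  if (length(curves) == 0L) pt_validation_error("need >= 1 curve")
  if (length(curves) == 1L) return(curves[[1L]])
  sweeps <- lapply(curves, function(cv) {
    if (!is.null(cv$tp_count)) {
      list(tpr = cv$tp_count / cv$n_truth, fpr = cv$fp_count / cv$n_null)
    } else {
      list(tpr = cv$tp_rate, fpr = cv$fp_rate)
    }
  })
  len <- max(vapply(sweeps, function(sw) length(sw$tpr), integer(1)))
  grid <- seq(0, 1, length.out = len)
  res <- lapply(sweeps, function(sw) {
    at <- seq(0, 1, length.out = length(sw$tpr))
    list(tpr = stats::approx(at, sw$tpr, grid)$y,
         fpr = stats::approx(at, sw$fpr, grid)$y)
  })
  tpr <- rowMeans(vapply(res, `[[`, numeric(len), "tpr"))
  fpr <- rowMeans(vapply(res, `[[`, numeric(len), "fpr"))
  structure(list(thresholds = rep(NA_real_, len), fp_rate = fpr,
                 tp_rate = tpr, auc = trapezoid_auc(fpr, tpr)),
            class = "roc_curve")
}

#' Top-N gene list from ranked results
#'
#' @param results a `gene_test_results` data frame ([rank_genes()]).
#' @param n_top list length, `<=` number of genes.
#' @return Character vector of the `n_top` best-ranked gene ids, in rank
#'   order.
#' @export
top_n <- function(results, n_top) {
  if (n_top > nrow(results)) {
    pt_validation_error(sprintf("n_top = %d exceeds the %d ranked genes",
                                n_top, nrow(results)))
  }
  results$gene_id[order(results$rank)][seq_len(n_top)]
}

#' Fraction of genes shared by two equally sized gene lists
#'
#' @param list_a,list_b duplicate-free gene id vectors of equal length.
#' @return `|A intersect B| / N` in `[0, 1]`.
#' @export
overlap_fraction <- function(list_a, list_b) {
  if (length(list_a) != length(list_b)) {
    pt_validation_error("lists must have equal length")
  }
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    pt_validation_error("lists must be duplicate-free")
  }
  length(intersect(list_a, list_b)) / length(list_a)
}

#' Top-N list overlap under random subsampling (robustness)
#'
#' Draws `n_subsamples` random sample subsets (without replacement,
#' stratified proportionally by condition so every subset keeps >= 2 samples
#' per condition), reruns the ranking method on each, takes its top `n_top`
#' genes, and averages the pairwise overlap fraction f over all unordered
#' pairs of subsets. The mean f is the robustness figure of merit: 1 means
#' perfectly stable lists.
#'
#' @param pm a [probe_matrix()].
#' @param design a [two_group_design()] for all samples of `pm`.
#' @param subsample_size total samples per subset (allocated to conditions
#'   proportionally to their full-data sizes).
#' @param n_subsamples number of subsets, `>= 2`.
#' @param n_top list length (100 in the reference analyses).
#' @param method ranking procedure: `"median-t"` (the probe-level pipeline,
#'   [probe_level_test()] without p-values) or a
#'   `function(pm, design) -> gene_test_results` for custom rankers such as
#'   a gene-level baseline closure.
#' @param seed integer seed driving the subset draws.
#' @return An object of class `overlap_result`: `n_top`,
#'   `per_pair_fractions`, `mean_overlap`, `n_subsamples`.
#' @export
robustness <- function(pm, design, subsample_size, n_subsamples = 100L,
                       n_top = 100L, method = "median-t", seed = 1L) {
  if (n_subsamples < 2L) pt_config_error("need n_subsamples >= 2")
  ranker <- if (is.function(method)) {
    method
  } else if (identical(method, "median-t")) {
    function(pm, design) probe_level_test(pm, design, p_values = FALSE)
  } else {
    pt_config_error(paste0("unknown method '", method, "'"))
  }
  s_a <- intersect(samples_of(design, "A"), pm$sample_ids)
  s_b <- intersect(samples_of(design, "B"), pm$sample_ids)
  n_tot <- length(s_a) + length(s_b)
  if (subsample_size > n_tot) {
    pt_config_error("subsample_size exceeds the number of samples")
  }
  k_a <- round(subsample_size * length(s_a) / n_tot)
  k_b <- subsample_size - k_a
  if (k_a < 2L || k_b < 2L) {
    pt_config_error(sprintf(
      "subsample_size = %d leaves a condition with < 2 samples (A=%d, B=%d)",
      subsample_size, k_a, k_b))
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n_subsamples), function(b) {
      c(sample(s_a, k_a), sample(s_b, k_b))
    })
  })
  lists <- lapply(draws, function(ids) {
    sub_pm <- subset_samples(pm, ids)
    sub_design <- two_group_design(design$condition_of[ids])
    top_n(ranker(sub_pm, sub_design), n_top)
  })
  pairs <- utils::combn(n_subsamples, 2L)
  f_ab <- vapply(seq_len(ncol(pairs)), function(i) {
    overlap_fraction(lists[[pairs[1L, i]]], lists[[pairs[2L, i]]])
  }, numeric(1))
  structure(list(n_top = as.integer(n_top), per_pair_fractions = f_ab,
                 mean_overlap = mean(f_ab),
                 n_subsamples = as.integer(n_subsamples)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: mean f = %.4f over %d pairs (n_top = %d, %d subsets)\n",
    x$mean_overlap, length(x$per_pair_fractions), x$n_top, x$n_subsamples))
  invisible(x)
}

#' Average ROC of a ranking method over rearranged spike-in experiments
#'
#' Convenience wrapper used by the sensitivity benchmark: quantile-normalizes
#' the simulated matrix once, then for every rearranged experiment ranks
#' genes with `score_fun` and computes the ROC against that experiment's
#' truth/excluded sets, returning the average curve.
#'
#' @param sim a `latin_square_sim` ([simulate_latin_square()]).
#' @param score_fun `function(pm, design) -> named numeric scores` (higher =
#'   more significant). Default: `abs` median t of the probe-level test.
#' @param normalize quantile-normalize the matrix first (default `TRUE`).
#' @return A list: `average` (a `roc_curve`), `curves` (per experiment).
#' @export
spikein_average_roc <- function(sim, score_fun = NULL, normalize = TRUE) {
  stopifnot(inherits(sim, "latin_square_sim"))
  if (is.null(score_fun)) score_fun <- median_t_scores
  pm <- if (normalize) quantile_normalize(sim$matrix) else sim$matrix
  experiments <- rearrange_latin_square(sim$design)
  curves <- lapply(experiments, function(ex) {
    ids <- c(ex$condition_A_samples, ex$condition_B_samples)
    scores <- score_fun(subset_samples(pm, ids), ex$design)
    # unspiked genes are the negatives; the wrap group is excluded
    roc_curve(scores, truth = ex$truth, excluded = ex$excluded)
  })
  list(average = average_roc(curves), curves = curves)
}
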