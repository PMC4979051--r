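# Shared fixtures and independent oracles for the test suite.

# small probe matrix with g genes x p probes x s samples, tie-free w.h.p.
make_pm <- function(n_genes = 4, probes_per_gene = 3, n_samples = 6,
                    seed = 1) {
  probes <- sprintf("g%02d_p%d", rep(seq_len(n_genes), each = probes_per_gene),
                    rep(seq_len(probes_per_gene), n_genes))
  genes <- sprintf("g%02d", rep(seq_len(n_genes), each = probes_per_gene))
  vals <- with_seed(seed, matrix(stats::rlnorm(length(probes) * n_samples,
                                               meanlog = 5, sdlog = 0.6),
                                 length(probes), n_samples))
  probe_matrix(vals, probe_ids = probes,
               sample_ids = sprintf("s%02d", seq_len(n_samples)),
               probe_to_gene = stats::setNames(genes, probes))
}

make_design <- function(n_samples = 6) {
  half <- n_samples %/% 2
  cond <- c(rep("A", half), rep("B", n_samples - half))
  names(cond) <- sprintf("s%02d", seq_len(n_samples))
  two_group_design(cond)
}

# KS distance between the analytic median-t cdf and an empirical sample,
# via quadrature cdf values on a quantile grid + linear interpolation
# (grid resolution error << the 0.01 acceptance tolerance).
ks_vs_analytic <- function(n, df, n_draws, seed, n_grid = 401) {
  x <- sort(median_t_mc_oracle(n, df, n_draws, seed))
  grid <- unique(c(x[1] - 1,
                   stats::quantile(x, seq(0, 1, length.out = n_grid)),
                   x[n_draws] + 1))
  gg <- median_t_cdf(median_t_distribution(n, df), grid)
  gx <- stats::approx(grid, gg, x)$y
  i <- seq_along(x)
  max(i / n_draws - gx, gx - (i - 1) / n_draws)
}

# toy spike-in design small enough for exhaustive checks
toy_design <- function(n_groups = 4, genes_per_group = 2,
                       replicates_per_group = 2, probes_per_gene = 2,
                       n_null_genes = 10) {
  spikein_design(n_groups = n_groups, genes_per_group = genes_per_group,
                 replicates_per_group = replicates_per_group,
                 concentrations = c(0, 2^(0:(n_groups - 2))),
                 n_null_genes = n_null_genes,
                 probes_per_gene = probes_per_gene)
}

# deterministic unit model: no noise, B = 0, phi = 1
unit_model <- function(noise_cv = 0) {
  spikein_model(noise_cv = noise_cv, background = 0, affinity = 1)
}
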