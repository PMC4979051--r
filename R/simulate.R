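# Synthetic spike-in data under the intensity model
#   Y_ijg = (B_jg + phi_jg * theta_ig) * eps_ij
# with probe-specific, sample-independent background B, probe affinities phi,
# known transcript concentrations theta, and multiplicative lognormal noise
# eps (mean 1, coefficient of variation noise_cv). The Latin-square design
# emulates the Affymetrix HG-U133 spike-in layout: gene groups cycle through
# an ordered doubling concentration series across sample groups, so any pair
# of consecutive sample groups differs by a fold change of 2 in every gene
# group except the one wrapping from the maximum concentration back to 0 pM.

#' Latin-square spike-in design
#'
#' Defaults reproduce the HG-U133 spike-in layout: 14 concentration groups x
#' 3 genes x 3 replicate arrays, concentrations 0 and a doubling series
#' 0.125..512 pM, and (by default) enough unspiked genes for a total of
#' 23,000.
#'
#' @param n_groups number of concentration groups (and of sample groups).
#' @param genes_per_group spiked genes per group.
#' @param replicates_per_group replicate arrays per sample group.
#' @param concentrations ordered vector of `n_groups` concentrations in pM;
#'   must contain 0 (by convention first, followed by the doubling series).
#' @param n_null_genes unspiked genes, constant concentration across samples.
#' @param probes_per_gene probes per probe set (HG-U133 typical: 11).
#' @return An object of class `spikein_design`.
#' @export
spikein_design <- function(n_groups = 14L, genes_per_group = 3L,
                           replicates_per_group = 3L,
                           concentrations = c(0, 0.125 * 2^(0:12)),
                           n_null_genes = 23000L -
                             n_groups * genes_per_group,
                           probes_per_gene = 11L) {
  if (length(concentrations) != n_groups) {
    pt_config_error("need exactly one concentration per group")
  }
  if (!any(concentrations == 0)) {
    pt_config_error("the concentration series must contain 0 pM")
  }
  if (any(concentrations < 0) || anyDuplicated(concentrations)) {
    pt_config_error("concentrations must be distinct and >= 0")
  }
  if (n_groups < 2L || genes_per_group < 1L || replicates_per_group < 2L ||
      n_null_genes < 0L || probes_per_gene < 1L) {
    pt_config_error("invalid spike-in design sizes")
  }
  structure(list(n_groups = as.integer(n_groups),
                 genes_per_group = as.integer(genes_per_group),
                 replicates_per_group = as.integer(replicates_per_group),
                 concentrations = as.numeric(concentrations),
                 n_null_genes = as.integer(n_null_genes),
                 probes_per_gene = as.integer(probes_per_gene)),
            class = "spikein_design")
}

#' Probe intensity model parameters
#'
#' Hyperparameters from which probe-level background and affinity maps are
#' realized (lognormal, per probe), plus the multiplicative noise level.
#' Defaults put low-concentration spikes near the background level, the
#' regime where background-correction errors hurt the most: background
#' median 100 a.u., affinity median 1, noise coefficient of variation 0.2.
#'
#' @param noise_cv coefficient of variation of the lognormal noise, `>= 0`.
#' @param background_meanlog,background_sdlog lognormal parameters of the
#'   sample-independent background `B_jg`.
#' @param affinity_meanlog,affinity_sdlog lognormal parameters of the probe
#'   affinity `phi_jg > 0`.
#' @param background,affinity optional pre-realized per-probe maps (named
#'   numeric vectors); filled in by the simulators otherwise.
#' @return An object of class `spikein_model`.
#' @export
spikein_model <- function(noise_cv = 0.2,
                          background_meanlog = log(100),
                          background_sdlog = 0.5,
                          affinity_meanlog = 0,
                          affinity_sdlog = 0.5,
                          background = NULL, affinity = NULL) {
  if (noise_cv < 0) pt_validation_error("noise_cv must be >= 0")
  if (!is.null(affinity) && any(affinity <= 0)) {
    pt_validation_error("affinities must be > 0")
  }
  if (!is.null(background) && any(background < 0)) {
    pt_validation_error("background must be >= 0")
  }
  structure(list(noise_cv = noise_cv,
                 background_meanlog = background_meanlog,
                 background_sdlog = background_sdlog,
                 affinity_meanlog = affinity_meanlog,
                 affinity_sdlog = affinity_sdlog,
                 background = background, affinity = affinity),
            class = "spikein_model")
}

# realize per-probe background/affinity maps under the current RNG state
realize_model <- function(model, probe_ids) {
  np <- length(probe_ids)
  bg <- model$background
  if (is.null(bg)) {
    bg <- stats::rlnorm(np, model$background_meanlog, model$background_sdlog)
    names(bg) <- probe_ids
  } else if (is.null(names(bg)) && length(bg) == 1L) {
    bg <- stats::setNames(rep(bg, np), probe_ids)     # constant background
  } else {
    bg <- bg[probe_ids]
    if (anyNA(bg)) pt_validation_error("background map does not cover all probes")
  }
  af <- model$affinity
  if (is.null(af)) {
    af <- stats::rlnorm(np, model$affinity_meanlog, model$affinity_sdlog)
    names(af) <- probe_ids
  } else if (is.null(names(af)) && length(af) == 1L) {
    af <- stats::setNames(rep(af, np), probe_ids)     # constant affinity
  } else {
    af <- af[probe_ids]
    if (anyNA(af)) pt_validation_error("affinity map does not cover all probes")
  }
  model$background <- bg
  model$affinity <- af
  model
}

# lognormal noise with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

ls_gene_ids <- function(design) {
  spiked <- as.vector(t(outer(seq_len(design$n_groups),
                              seq_len(design$genes_per_group),
                              function(g, m) sprintf("spike_%02d_%d", g, m))))
  nulls <- if (design$n_null_genes > 0L) {
    sprintf("null_%05d", seq_len(design$n_null_genes))
  } else {
    character(0)
  }
  list(spiked = spiked, nulls = nulls,
       group_of = rep(seq_len(design$n_groups),
                      each = design$genes_per_group))
}

ls_sample_ids <- function(design) {
  as.vector(t(outer(seq_len(design$n_groups),
                    seq_len(design$replicates_per_group),
                    function(s, r) sprintf("grp%02d_rep%d", s, r))))
}

# concentration index of gene group g on sample group s (cyclic shift)
ls_conc_index <- function(design, s, g) {
  ((s + g - 2L) %% design$n_groups) + 1L
}

probe_ids_for <- function(gene_ids, probes_per_gene) {
  paste0(rep(gene_ids, each = probes_per_gene), "_p",
         sprintf("%02d", rep(seq_len(probes_per_gene), length(gene_ids))))
}

#' Simulate a Latin-square spike-in experiment
#'
#' Generates probe intensities under the model above. Spiked genes follow
#' the cyclic Latin-square concentration schedule; each unspiked gene gets a
#' concentration drawn once (lognormal, median 4 pM, sdlog 1.5) and held
#' constant across samples. All randomness flows from `seed`; the global RNG
#' state is left untouched.
#'
#' @param design a [spikein_design()].
#' @param model a [spikein_model()].
#' @param seed integer seed.
#' @return A list of class `latin_square_sim`: `matrix` (a
#'   [probe_matrix()]), `model` (with realized `background`/`affinity`
#'   maps), `design`, `theta` (gene x sample concentration matrix),
#'   `sample_group` (named), `spiked_genes`, `gene_group` (named, spiked
#'   genes only).
#' @export
simulate_latin_square <- function(design, model, seed) {
  stopifnot(inherits(design, "spikein_design"),
            inherits(model, "spikein_model"))
  ids <- ls_gene_ids(design)
  genes <- c(ids$spiked, ids$nulls)
  samples <- ls_sample_ids(design)
  sample_group <- rep(seq_len(design$n_groups),
                      each = design$replicates_per_group)
  names(sample_group) <- samples
  probes <- probe_ids_for(genes, design$probes_per_gene)
  gene_of_probe <- rep(genes, each = design$probes_per_gene)
  names(gene_of_probe) <- probes

  with_seed(seed, {
    theta <- matrix(0, nrow = length(genes), ncol = length(samples),
                    dimnames = list(genes, samples))
    for (g in seq_along(ids$spiked)) {
      grp <- ids$group_of[g]
      conc <- design$concentrations[ls_conc_index(design, sample_group, grp)]
      theta[ids$spiked[g], ] <- conc
    }
    if (length(ids$nulls)) {
      theta0 <- stats::rlnorm(length(ids$nulls), meanlog = log(4), sdlog = 1.5)
      theta[ids$nulls, ] <- matrix(theta0, nrow = length(ids$nulls),
                                   ncol = length(samples))
    }
    model <- realize_model(model, probes)
    mu <- model$background[probes] +
      model$affinity[probes] * theta[gene_of_probe, , drop = FALSE]
    eps <- matrix(rlnorm_mean1(length(mu), model$noise_cv),
                  nrow = nrow(mu), ncol = ncol(mu))
    y <- mu * eps
  })
  pm <- probe_matrix(y, probe_ids = probes, sample_ids = samples,
                     probe_to_gene = gene_of_probe)
  gene_group <- ids$group_of
  names(gene_group) <- ids$spiked
  structure(list(matrix = pm, model = model, design = design, theta = theta,
                 sample_group = sample_group, spiked_genes = ids$spiked,
                 gene_group = gene_group),
            class = "latin_square_sim")
}

#' Rearranged two-condition experiments from a Latin-square design
#'
#' Forms one two-condition "experiment" per cyclic pairing of consecutive
#' sample groups: group k's replicates are condition A and group k+1's
#' (mod n_groups) are condition B. In every experiment exactly one gene
#' group wraps from the maximum concentration back to 0 pM; its genes are
#' excluded from evaluation, and the remaining spiked genes (fold change 2
#' between consecutive doubling concentrations, plus the 0 pM to lowest-dose
#' transition) form the truth set. With the default design this yields 14
#' experiments with |truth| = 39 and |excluded| = 3 each.
#'
#' @param design a [spikein_design()] whose concentrations are ordered with
#'   0 first, then the ascending doubling series.
#' @return A list of `rearranged_experiment` objects, each with fields
#'   `name`, `condition_A_samples`, `condition_B_samples`, `design`
#'   (a [two_group_design()]), `truth`, `excluded`.
#' @export
rearrange_latin_square <- function(design) {
  stopifnot(inherits(design, "spikein_design"))
  if (!any(design$concentrations == 0)) {
    pt_config_error("design has no 0 pM concentration group")
  }
  ids <- ls_gene_ids(design)
  samples <- ls_sample_ids(design)
  sample_group <- rep(seq_len(design$n_groups),
                      each = design$replicates_per_group)
  g_seq <- seq_len(design$n_groups)
  lapply(g_seq, function(k) {
    nxt <- (k %% design$n_groups) + 1L
    a <- samples[sample_group == k]
    b <- samples[sample_group == nxt]
    idx_a <- ls_conc_index(design, k, g_seq)
    wrap_group <- g_seq[idx_a == design$n_groups]   # max conc -> wraps to 0
    excl <- ids$spiked[ids$group_of %in% wrap_group]
    truth <- setdiff(ids$spiked, excl)
    cond <- c(rep("A", length(a)), rep("B", length(b)))
    names(cond) <- c(a, b)
    structure(list(name = sprintf("exp%02d", k),
                   condition_A_samples = a, condition_B_samples = b,
                   design = two_group_design(cond),
                   truth = truth, excluded = excl),
              class = "rearranged_experiment")
  })
}

#' Simulate a generic two-condition dataset with known truth
#'
#' Baseline concentrations are drawn per gene from a lognormal (median 50
#' a.u., sdlog 1, spanning the below-background to well-above-background
#' range); a random subset of `n_deg` genes has its concentration multiplied
#' by `fold_change` in condition B. Intensities follow the same model as
#' [simulate_latin_square()].
#'
#' @param n_genes total genes.
#' @param n_deg number of differentially expressed genes, `0 <= n_deg <=
#'   n_genes`.
#' @param fold_change concentration ratio B/A for DEG, `> 0`.
#' @param n_A,n_B samples per condition (`>= 2`).
#' @param model a [spikein_model()].
#' @param probes_per_gene probes per gene.
#' @param seed integer seed.
#' @return A list of class `two_condition_sim`: `matrix`, `design` (a
#'   [two_group_design()]), `truth` (gene ids), `model` (realized), `theta`.
#' @export
simulate_two_condition <- function(n_genes = 2000L, n_deg = 100L,
                                   fold_change = 2, n_A = 20L, n_B = 20L,
                                   model = spikein_model(),
                                   probes_per_gene = 11L, seed = 1L) {
  if (n_deg < 0L || n_deg > n_genes) {
    pt_validation_error("need 0 <= n_deg <= n_genes")
  }
  if (fold_change <= 0) pt_validation_error("fold_change must be > 0")
  if (n_A < 2L || n_B < 2L) pt_validation_error("need n_A >= 2 and n_B >= 2")
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- c(sprintf("A%03d", seq_len(n_A)), sprintf("B%03d", seq_len(n_B)))
  cond <- c(rep("A", n_A), rep("B", n_B))
  names(cond) <- samples
  probes <- probe_ids_for(genes, probes_per_gene)
  gene_of_probe <- rep(genes, each = probes_per_gene)
  names(gene_of_probe) <- probes

  with_seed(seed, {
    theta0 <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1)
    truth <- sort(sample(genes, n_deg))
    theta <- matrix(theta0, nrow = n_genes, ncol = length(samples),
                    dimnames = list(genes, samples))
    theta[truth, cond == "B"] <- theta[truth, cond == "B"] * fold_change
    model <- realize_model(model, probes)
    mu <- model$background[probes] +
      model$affinity[probes] * theta[gene_of_probe, , drop = FALSE]
    eps <- matrix(rlnorm_mean1(length(mu), model$noise_cv),
                  nrow = nrow(mu), ncol = ncol(mu))
    y <- mu * eps
  })
  pm <- probe_matrix(y, probe_ids = probes, sample_ids = samples,
                     probe_to_gene = gene_of_probe)
  structure(list(matrix = pm, design = two_group_design(cond), truth = truth,
                 model = model, theta = theta),
            class = "two_condition_sim")
}

#' Background-correct-then-summarize with deliberate background error
#'
#' The imperfect preprocessing baseline: subtracts a misestimated background
#' `Bhat_jg = B_jg + N(0, misestimation_sd)` from every probe, clamps at a
#' small positive floor, and summarizes each gene as the median over its
#' probes per sample. Because the misestimation is largest relative to the
#' signal for weakly expressed genes, their recovered expression is
#' distorted the most - the regime motivating the probe-level test. The
#' output feeds [gene_level_t_baseline()].
#'
#' @param pm a [probe_matrix()] generated under `model`.
#' @param model a realized [spikein_model()] (with per-probe `background`).
#' @param misestimation_sd standard deviation of the background estimation
#'   error, in intensity units, `>= 0`.
#' @param seed integer seed.
#' @param floor clamping floor for background-subtracted intensities.
#' @return A gene x sample numeric matrix of summarized expression values.
#' @export
summarize_with_background_error <- function(pm, model, misestimation_sd = 50,
                                            seed = 1L, floor = 1) {
  validate_probe_matrix(pm)
  if (misestimation_sd < 0) {
    pt_validation_error("misestimation_sd must be >= 0")
  }
  if (is.null(model$background)) {
    pt_validation_error("model must carry a realized per-probe background map")
  }
  b <- model$background[pm$probe_ids]
  if (anyNA(b)) pt_validation_error("background map does not cover all probes")
  bhat <- with_seed(seed,
                    b + stats::rnorm(length(b), 0, misestimation_sd))
  s <- pmax(pm$values - bhat, floor)
  gene_of <- pm$probe_to_gene[pm$probe_ids]
  counts <- table(gene_of)
  genes <- sort(unique(gene_of))
  if (length(unique(counts)) == 1L) {
    # equal probe counts: vectorized median via one radix sort
    p <- as.integer(counts[[1L]])
    o <- order(gene_of, pm$probe_ids, method = "radix")
    expr <- vapply(seq_len(ncol(s)), function(j) {
      col_medians(matrix(s[o, j], nrow = p))
    }, numeric(length(genes)))
    dimnames(expr) <- list(genes, pm$sample_ids)
  } else {
    rows_of <- split(seq_len(nrow(s)), gene_of)
    expr <- t(vapply(rows_of, function(r) {
      col_medians(s[r, , drop = FALSE])
    }, numeric(ncol(s))))
    dimnames(expr) <- list(names(rows_of), pm$sample_ids)
  }
  expr
}
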