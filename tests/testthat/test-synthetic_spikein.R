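test_that("design and model constructors validate their inputs", {
  expect_error(spikein_design(n_groups = 4, concentrations = c(1, 2, 4, 8)),
               "0 pM", class = "pt_config_error")
  expect_error(spikein_design(n_groups = 3, concentrations = c(0, 1)),
               class = "pt_config_error")
  expect_error(spikein_model(noise_cv = -0.1), class = "pt_validation_error")
  des <- spikein_design()
  expect_identical(des$n_groups, 14L)
  expect_identical(des$genes_per_group * des$n_groups, 42L)
  expect_identical(des$n_null_genes + 42L, 23000L)
  expect_equal(max(des$concentrations), 512)
})

test_that("noiseless unit simulation reproduces the concentration schedule", {
  des <- toy_design(n_null_genes = 0, probes_per_gene = 1)
  sim <- simulate_latin_square(des, unit_model(), seed = 1)
  # with B = 0, phi = 1, cv = 0: Y is exactly theta
  expect_identical(unname(sim$matrix$values),
                   unname(sim$theta[sim$matrix$probe_to_gene[sim$matrix$probe_ids], ]))
  # each spiked gene's concentrations across sample groups are exactly the
  # design's concentration multiset (Latin-square property, per gene)
  first_rep <- sim$matrix$sample_ids[seq(1, ncol(sim$theta),
                                         by = des$replicates_per_group)]
  for (g in sim$spiked_genes) {
    expect_equal(sort(unname(sim$theta[g, first_rep])), sort(des$concentrations))
  }
})

test_that("Latin-square property holds exhaustively for the default design", {
  des <- spikein_design(n_null_genes = 0L)
  # concentration index table: rows = sample groups, cols = gene groups
  idx <- outer(seq_len(des$n_groups), seq_len(des$n_groups),
               function(s, g) probetest:::ls_conc_index(des, s, g))
  for (g in seq_len(des$n_groups)) {
    expect_identical(sort(idx[, g]), seq_len(des$n_groups))  # every conc once
  }
  for (s in seq_len(des$n_groups)) {
    expect_identical(sort(idx[s, ]), seq_len(des$n_groups))
  }
})

test_that("simulation is deterministic per seed and noise model is honest", {
  des <- toy_design()
  s1 <- simulate_latin_square(des, spikein_model(), seed = 42)
  s2 <- simulate_latin_square(des, spikein_model(), seed = 42)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$model$background, s2$model$background)
  s3 <- simulate_latin_square(des, spikein_model(), seed = 43)
  expect_false(identical(s1$matrix$values, s3$matrix$values))

  # with theta = 0 the probe intensity is B * eps: replicate mean ~ B
  des_rep <- spikein_design(n_groups = 4, genes_per_group = 1,
                            replicates_per_group = 60,
                            concentrations = c(0, 1, 2, 4),
                            n_null_genes = 0, probes_per_gene = 1)
  model <- spikein_model(noise_cv = 0.3, background = 100, affinity = 1)
  sim <- simulate_latin_square(des_rep, model, seed = 7)
  g <- sim$spiked_genes[1]
  zero_samples <- colnames(sim$theta)[sim$theta[g, ] == 0]
  probe <- sim$matrix$probe_ids[sim$matrix$probe_to_gene == g]
  y0 <- sim$matrix$values[probe, zero_samples]
  se <- 0.3 * 100 / sqrt(length(y0))
  expect_lt(abs(mean(y0) - 100), 3 * se)
})

test_that("rearrangement yields the printed experiment and truth counts", {
  ex <- rearrange_latin_square(spikein_design())
  expect_length(ex, 14L)
  for (e in ex) {
    expect_length(e$truth, 39L)
    expect_length(e$excluded, 3L)
    expect_length(intersect(e$truth, e$excluded), 0L)
    expect_setequal(c(e$truth, e$excluded),
                    probetest:::ls_gene_ids(spikein_design())$spiked)
    expect_identical(e$design$n_A, 3L)
    expect_identical(e$design$n_B, 3L)
  }
  # toy design, enumerated by hand from the cyclic shift: 4 experiments,
  # |truth| = (4-1)*2 = 6, |excluded| = 2
  ex_toy <- rearrange_latin_square(toy_design())
  expect_length(ex_toy, 4L)
  expect_true(all(vapply(ex_toy, function(e) length(e$truth), integer(1)) == 6L))
  expect_true(all(vapply(ex_toy, function(e) length(e$excluded),
                         integer(1)) == 2L))
  # closed form |truth| = genes_per_group * (n_groups - 1) on another design
  des5 <- spikein_design(n_groups = 5, genes_per_group = 3,
                         concentrations = c(0, 1, 2, 4, 8), n_null_genes = 1)
  expect_true(all(vapply(rearrange_latin_square(des5),
                         function(e) length(e$truth), integer(1)) == 12L))
})

test_that("excluded group is exactly the max-concentration wrap transition", {
  des <- toy_design()                       # concentrations 0, 1, 2, 4
  sim <- simulate_latin_square(des, unit_model(), seed = 2)
  for (e in rearrange_latin_square(des)) {
    a_rep <- e$condition_A_samples[1]
    b_rep <- e$condition_B_samples[1]
    conc_a <- sim$theta[e$excluded, a_rep]
    conc_b <- sim$theta[e$excluded, b_rep]
    expect_true(all(conc_a == max(des$concentrations)))
    expect_true(all(conc_b == 0))
    # truth genes move one doubling step (or 0 -> lowest dose)
    ta <- sim$theta[e$truth, a_rep]
    tb <- sim$theta[e$truth, b_rep]
    expect_true(all(tb[ta > 0] == 2 * ta[ta > 0]))
    expect_true(all(tb[ta == 0] == min(des$concentrations[des$concentrations > 0])))
  }
})

test_that("two-condition generator honours truth, fold change and seed", {
  sim <- simulate_two_condition(n_genes = 30, n_deg = 6, fold_change = 3,
                                n_A = 3, n_B = 4, probes_per_gene = 2,
                                seed = 5)
  expect_length(sim$truth, 6L)
  a <- samples_of(sim$design, "A")
  b <- samples_of(sim$design, "B")
  expect_equal(sim$theta[sim$truth, b[1]], 3 * sim$theta[sim$truth, a[1]])
  nulls <- setdiff(rownames(sim$theta), sim$truth)
  expect_equal(sim$theta[nulls, b[1]], sim$theta[nulls, a[1]])
  expect_identical(
    sim$matrix$values,
    simulate_two_condition(n_genes = 30, n_deg = 6, fold_change = 3,
                           n_A = 3, n_B = 4, probes_per_gene = 2,
                           seed = 5)$matrix$values)
  expect_error(simulate_two_condition(n_genes = 5, n_deg = 9, seed = 1),
               class = "pt_validation_error")
  expect_error(simulate_two_condition(fold_change = 0, seed = 1),
               class = "pt_validation_error")

  # n_deg = 0: empty truth, p-values roughly uniform (input to calibration)
  null_sim <- simulate_two_condition(n_genes = 400, n_deg = 0, n_A = 5,
                                     n_B = 5, probes_per_gene = 3, seed = 6)
  expect_length(null_sim$truth, 0L)
  res <- probe_level_test(null_sim$matrix, null_sim$design)
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
})

test_that("noiseless separation: all truth genes rank above all null genes", {
  sim <- simulate_two_condition(n_genes = 40, n_deg = 8, fold_change = 2,
                                n_A = 3, n_B = 3, probes_per_gene = 3,
                                model = unit_model(), seed = 9)
  # model-exact data: no normalization step needed (columns differ only by
  # the spiked genes, which quantile normalization would distort here)
  res <- suppressWarnings(probe_level_test(sim$matrix, sim$design,
                                           normalize = FALSE))
  truth_ranks <- res$rank[res$gene_id %in% sim$truth]
  expect_true(max(truth_ranks) <= length(sim$truth))
  expect_true(all(res$p_value[res$gene_id %in% sim$truth] == 0))  # sentinels
})

test_that("background misestimation distorts low-expression genes most", {
  sim <- simulate_two_condition(n_genes = 200, n_deg = 0, n_A = 4, n_B = 4,
                                probes_per_gene = 5,
                                model = spikein_model(noise_cv = 0),
                                seed = 14)
  # exact recovery when nothing is misestimated and there is no noise
  unit_sim <- simulate_two_condition(n_genes = 50, n_deg = 0, n_A = 3,
                                     n_B = 3, probes_per_gene = 4,
                                     model = unit_model(), seed = 15)
  expr0 <- summarize_with_background_error(unit_sim$matrix, unit_sim$model,
                                           misestimation_sd = 0, seed = 1)
  ok <- rownames(unit_sim$theta)[unit_sim$theta[, 1] >= 1]  # above the floor
  expect_equal(expr0[ok, ], unit_sim$theta[ok, ], tolerance = 1e-9)

  # misestimation: relative error decreases with expression level
  expr <- summarize_with_background_error(sim$matrix, sim$model,
                                          misestimation_sd = 50, seed = 2)
  theta <- sim$theta[rownames(expr), ]
  rel_err <- rowMeans(abs(expr - theta)) / rowMeans(theta)
  tert <- cut(rowMeans(theta), quantile(rowMeans(theta), c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = c("low", "mid", "high"))
  expect_gt(mean(rel_err[tert == "low"]), mean(rel_err[tert == "high"]))

  # clamping floor contract
  expect_true(all(expr >= 1))
  expect_error(summarize_with_background_error(sim$matrix, sim$model,
                                               misestimation_sd = -1),
               class = "pt_validation_error")
})
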