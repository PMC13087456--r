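# Generators: construction guarantees, determinism, validation errors, and
# agreement between emitted data and the ground-truth record.

test_that("planted variant genotypes honor the configured mode", {
  sv <- simulate_variant_cohort(variant_sim_config(n_cases = 3, seed = 1))
  for (s in sv$truth$cases) {
    planted <- sv$variants[sv$variants$sample_id == s &
                             sv$variants$gene == "RNU6ATAC", ]
    expect_identical(nrow(planted), 1L)
    expect_identical(planted$genotype, "hom_alt")
    expect_lt(planted$population_af, 1e-5)
  }
  pos <- vapply(sv$truth$cases, function(s) sv$truth$planted[[s]]$positions, 0)
  expect_identical(anyDuplicated(pos), 0L)

  ch <- simulate_variant_cohort(variant_sim_config(
    case_genotype_mode = "compound_het", seed = 2))
  for (s in ch$truth$cases) {
    planted <- ch$variants[ch$variants$sample_id == s &
                             ch$variants$gene == "RNU6ATAC", ]
    expect_identical(nrow(planted), 2L)
    expect_setequal(planted$genotype, "het")
    expect_setequal(planted$parental_origin, c("maternal", "paternal"))
    expect_true(all(planted$population_af < 1e-5))
  }
  # controls never carry target-gene variants
  expect_false(any(ch$variants$gene == "RNU6ATAC" &
                     ch$variants$sample_id %in% ch$truth$controls))
})

test_that("generators are deterministic in the seed and sensitive to it", {
  cfgs <- list(variant_sim_config(seed = 5),
               ir_sim_config(seed = 5, n_genes = 20),
               expr_sim_config(seed = 5, module_sizes = c(10L, 10L),
                               n_cases = 5, n_controls = 5),
               meth_sim_config(seed = 5, n_cpgs = 50, n_cases = 3, n_controls = 3))
  sims <- list(simulate_variant_cohort, simulate_intron_counts,
               simulate_expression, simulate_methylation)
  for (i in seq_along(cfgs)) {
    a <- sims[[i]](cfgs[[i]])
    b <- sims[[i]](cfgs[[i]])
    expect_identical(serialize(a, NULL), serialize(b, NULL))
    cfg2 <- cfgs[[i]]
    cfg2$seed <- 6L
    expect_false(identical(sims[[i]](cfg2), a))
  }
  # named sub-streams: generators draw independently of each other
  before <- simulate_expression(cfgs[[3]])
  invisible(simulate_variant_cohort(cfgs[[1]]))
  expect_identical(simulate_expression(cfgs[[3]]), before)
})

test_that("config validation errors name the offending field", {
  expect_error(variant_sim_config(n_cases = -1), "n_cases")
  expect_error(variant_sim_config(af_spectrum = c(0.5, 1e-6)), "af_spectrum")
  expect_error(ir_sim_config(baseline_psi = c(10, 1), delta_psi = 0.5), "delta_psi")
  expect_error(expr_sim_config(n_cases = 0), "n_cases")
  expect_error(expr_sim_config(n_controls = 0), "n_controls")
  expect_error(expr_sim_config(n_trait_modules = 10, module_sizes = c(20L, 20L)),
               "n_trait_modules")
  expect_error(meth_sim_config(depletion_factor = 0), "depletion_factor")
  expect_error(meth_sim_config(depletion_factor = 1.5), "depletion_factor")
  expect_error(meth_sim_config(depleted_cell_type = "nonexistent"),
               "depleted_cell_type")
})

test_that("intron simulator truth matches its construction rules", {
  # null configuration: no retention shift anywhere
  null <- simulate_intron_counts(ir_sim_config(delta_psi = 0, seed = 3, n_genes = 30))
  expect_identical(null$truth$intron$psi_case, null$truth$intron$psi_control)

  # deterministic hidden-gene count: floor(frac * n + 0.5)
  sim <- simulate_intron_counts(ir_sim_config(n_genes = 100, frac_u12_genes = 0.15,
                                              frac_hidden_u12 = 0.2, seed = 7))
  expect_identical(length(sim$truth$u12_genes), 15L)
  expect_identical(length(sim$truth$hidden_genes), 3L)
  expect_identical(sum(sim$annotation$class == "unknown"), 3L)
  expect_identical(sum(sim$truth$intron$hidden), 3L)
  # hidden minor introns are exactly the "unknown"-labelled ones
  expect_setequal(sim$annotation$intron_id[sim$annotation$class == "unknown"],
                  sim$truth$intron$intron_id[sim$truth$intron$hidden])
  # the U12 label never leaks for hidden genes
  expect_false(any(sim$annotation$gene %in% sim$truth$hidden_genes &
                     sim$annotation$class == "U12"))

  # empirical case-control PSI gap ~ delta_psi within 3 Monte-Carlo SEs
  big <- simulate_intron_counts(ir_sim_config(n_cases = 20, n_controls = 20,
                                              depth_mean = 200, delta_psi = 0.3,
                                              seed = 11))
  tr <- big$truth$intron
  planted <- tr$intron_id[tr$true_class == "U12"]
  cov <- big$counts$retained + big$counts$spliced
  psi <- big$counts$retained / cov
  gcase <- names(big$counts$groups)[big$counts$groups == "case_RNU6ATAC"]
  gctl <- names(big$counts$groups)[big$counts$groups == "control"]
  diffs <- rowMeans(psi[planted, gcase]) - rowMeans(psi[planted, gctl])
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.3), 3 * mc_se)
})

test_that("expression simulator hits the target within-module correlation", {
  sim <- simulate_expression(expr_sim_config(within_module_correlation = 0.99,
                                             noise_sd = 0.01,
                                             module_sizes = c(20L, 20L),
                                             n_trait_modules = 0, seed = 4))
  for (m in c("M1", "M2")) {
    genes <- names(sim$truth$labels)[sim$truth$labels == m]
    cc <- stats::cor(t(sim$expr[genes, ]))
    expect_gte(mean(abs(cc[upper.tri(cc)])), 0.9)
  }
})

test_that("without trait modules no eigengene tracks disease status", {
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_expression(expr_sim_config(n_trait_modules = 0, seed = 300 + s,
                                               module_sizes = rep(30L, 4L),
                                               n_background_genes = 0))
    asg <- sim$truth$labels
    eg <- module_eigengenes(sim$expr, asg)
    r <- abs(stats::cor(eg, sim$traits$status))
    if (max(r) > 0.5) hits <- hits + 1L
  }
  expect_lte(hits, 1L) # >= 95% of seeds stay below |r| = 0.5
})

test_that("methylation mixtures sit on the simplex and respect the null", {
  sim <- simulate_methylation(meth_sim_config(seed = 8, n_cpgs = 60))
  w <- sim$truth$weights
  expect_true(all(w >= 0))
  expect_true(all(abs(colSums(w) - 1) < 1e-12))
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))

  # noiseless flag: data is exactly the convex mixture
  nl <- simulate_methylation(meth_sim_config(seed = 8, n_cpgs = 60, noiseless = TRUE))
  expect_equal(nl$beta, nl$reference %*% nl$truth$weights, tolerance = 1e-12)

  # depletion_factor = 1 is a no-op: controls match across factors and cases
  # match the renormalized scaling of the undepleted weights
  base <- simulate_methylation(meth_sim_config(seed = 9, depletion_factor = 1))
  depl <- simulate_methylation(meth_sim_config(seed = 9, depletion_factor = 0.5))
  ctl <- grep("^control", colnames(base$truth$weights))
  expect_identical(base$truth$weights[, ctl], depl$truth$weights[, ctl])
  w0 <- base$truth$weights[, "case_01"]
  w0["naive B"] <- w0["naive B"] * 0.5
  expect_equal(depl$truth$weights[, "case_01"], w0 / sum(w0), tolerance = 1e-12)
})
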