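# Network construction, module detection, eigengenes, module-trait
# correlation, and gene-set enrichment.

test_that("soft-threshold selection honors its contract", {
  sim <- simulate_expression(expr_sim_config(seed = 41, n_trait_modules = 0,
                                             module_sizes = c(60L, 40L, 25L),
                                             n_background_genes = 75))
  st <- pick_soft_threshold(sim$expr, powers = 1:12)
  # the returned power's R^2 must be reproducible from the adjacency alone
  a <- adjacency_matrix(sim$expr, st$power, signed = TRUE)
  k <- rowSums(a)
  k <- k[k > 0]
  breaks <- seq(min(k), max(k), length.out = 11)
  b <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(tapply(k, b, length))
  km <- as.numeric(tapply(k, b, mean))
  ok <- !is.na(freq) & freq > 0 & km > 0
  fit <- stats::lm(log10(freq[ok]) ~ log10(km[ok]))
  r2_ind <- if (stats::coef(fit)[2] >= 0) 0 else summary(fit)$r.squared
  expect_equal(st$fit$r_squared[st$fit$power == st$power], r2_ind,
               tolerance = 1e-8)
  # flag semantics: with a target no scanned power reaches, the max-R^2
  # power is returned flagged
  st_hi <- pick_soft_threshold(sim$expr, powers = 1:12, target_r2 = 0.999)
  expect_true(st_hi$warning_flag)
  expect_identical(st_hi$power,
                   st_hi$fit$power[which.max(st_hi$fit$r_squared)])
  # single candidate: returned regardless
  expect_identical(pick_soft_threshold(sim$expr, powers = 6)$power, 6)
  expect_error(pick_soft_threshold(sim$expr, powers = integer()), "non-empty")
  const <- matrix(1, 20, 10)
  expect_error(pick_soft_threshold(const), "positive variance")
})

test_that("TOM matches its formula limits and a hand-computed instance", {
  # three perfectly correlated genes with identical neighborhoods: TOM = 1
  x <- matrix(stats::rnorm(10), 1)[rep(1, 3), ]
  x <- x + 0 # three identical profiles
  rownames(x) <- paste0("g", 1:3)
  tom <- compute_tom(x, power = 6)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)

  # hand calculation on a 3-gene adjacency with a single off-diagonal pair:
  # a_12 = 0.6, rest 0 -> TOM_12 = (0 + 0.6) / (min(.6,.6) + 1 - .6) = 0.6
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.6
  expect_equal(tom_from_adjacency(a)[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(tom_from_adjacency(a)[1, 3], 0, tolerance = 1e-12)
})

test_that("TOM equals the brute-force double-loop oracle on random instances", {
  set.seed(5)
  for (rep in 1:5) {
    expr <- matrix(stats::rnorm(20 * 12), 20, 12,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:12)))
    a <- adjacency_matrix(expr, power = 6, signed = rep %% 2 == 0)
    tom <- tom_from_adjacency(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(diag(tom) == 1))
  }
})

test_that("module detection recovers well-separated planted blocks", {
  sim <- simulate_expression(expr_sim_config(seed = 43, n_trait_modules = 0,
                                             module_sizes = c(40L, 40L),
                                             n_background_genes = 20))
  tom <- compute_tom(sim$expr, power = 12) # signed-network conventional power
  asg <- detect_modules(tom, cut_height = 0.95, min_module_size = 15)
  modules <- setdiff(unique(asg), "unassigned")
  expect_identical(length(modules), 2L)
  expect_gte(adjusted_rand_index(asg, sim$truth$labels[names(asg)]), 0.9)

  # oversize threshold: everything unassigned
  all_un <- detect_modules(tom, min_module_size = nrow(tom) + 1)
  expect_true(all(all_un == "unassigned"))

  # gene-order invariance up to labels
  perm <- sample(nrow(tom))
  asg_p <- detect_modules(tom[perm, perm], cut_height = 0.95, min_module_size = 15)
  expect_equal(adjusted_rand_index(asg_p[names(asg)], asg), 1, tolerance = 1e-12)
  expect_error(detect_modules(tom, cut_height = 0), "cut_height")
})

test_that("eigengenes summarize modules with the documented conventions", {
  # module of identical genes: eigengene is the standardized shared profile
  profile <- stats::rnorm(12)
  x <- matrix(profile, 5, 12, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  asg <- stats::setNames(rep("m1", 5), rownames(x))
  eg <- module_eigengenes(x, asg)
  expect_equal(abs(stats::cor(eg[, "m1"], profile)), 1, tolerance = 1e-10)
  expect_gt(stats::cor(eg[, "m1"], profile), 0) # sign-aligned

  # negating every module gene changes nothing observable after alignment
  eg_neg <- module_eigengenes(-x, asg)
  expect_equal(abs(stats::cor(eg_neg[, "m1"], eg[, "m1"])), 1, tolerance = 1e-10)

  # single-gene module: the standardized gene itself
  solo <- module_eigengenes(x[1, , drop = FALSE],
                            stats::setNames("m1", "g1"))
  expect_equal(solo[, "m1"], as.numeric(scale(profile)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # planted one-factor module: eigengene tracks the latent factor
  sim <- simulate_expression(expr_sim_config(seed = 47, module_sizes = 50L,
                                             n_trait_modules = 0, noise_sd = 0.3,
                                             within_module_correlation = 0.8))
  asg2 <- sim$truth$labels[sim$truth$labels == "M1"]
  eg2 <- module_eigengenes(sim$expr, asg2)
  expect_gte(abs(stats::cor(eg2[, "M1"], sim$truth$factors["M1", ])), 0.95)
})

test_that("module-trait correlation applies Bonferroni over the grid", {
  set.seed(3)
  trait <- stats::rnorm(20)
  eg <- cbind(m1 = trait, m2 = stats::rnorm(20))
  rownames(eg) <- paste0("s", 1:20)
  res <- module_trait_correlation(eg, data.frame(status = trait))
  expect_equal(res$r[res$module == "m1"], 1, tolerance = 1e-12)
  expect_equal(res$p_value[res$module == "m1"], 0, tolerance = 1e-12)
  # bonferroni multiplies by the full grid size
  expect_equal(res$bonferroni_adjusted_p, pmin(1, res$p_value * 2),
               tolerance = 1e-12)
  # p = 0.01 with 10 pairs -> adjusted 0.1, not significant
  expect_identical(min(1, 0.01 * 10) < 0.05, FALSE)
  eg10 <- matrix(stats::rnorm(200), 20, 10,
                 dimnames = list(paste0("s", 1:20), paste0("m", 1:10)))
  res10 <- module_trait_correlation(eg10, data.frame(status = trait))
  expect_equal(res10$bonferroni_adjusted_p, pmin(1, res10$p_value * 10),
               tolerance = 1e-12)
  # constant trait: undefined and flagged, not an error
  resc <- module_trait_correlation(eg, data.frame(flat = rep(1, 20)))
  expect_true(all(resc$undefined))
  expect_false(any(resc$significant))
})

test_that("no trait-linked modules means no Bonferroni hits (null property)", {
  clean <- 0L
  for (s in 1:20) {
    sim <- simulate_expression(expr_sim_config(seed = 600 + s, n_trait_modules = 0,
                                               module_sizes = rep(30L, 4L),
                                               n_background_genes = 0))
    eg <- module_eigengenes(sim$expr, sim$truth$labels)
    mt <- module_trait_correlation(eg, data.frame(status = sim$traits$status))
    if (!any(mt$significant)) clean <- clean + 1L
  }
  expect_gte(clean, 19L)
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  genes <- sprintf("g%02d", 1:20)
  asg <- stats::setNames(c(rep("m1", 5), rep("unassigned", 15)), genes)
  sets <- list(hit = genes[1:5], other = genes[6:10])
  res <- enrich_modules(asg, sets)
  # module == set, N = 20, K = 5, n = 5, k = 5 -> p = 1 / C(20, 5)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # disjoint set: overlap 0, one-sided tail P(X >= 0) = 1
  expect_identical(res$overlap[res$set == "other"], 0L)
  expect_equal(res$p_value[res$set == "other"], 1, tolerance = 1e-12)

  set.seed(13)
  for (rep in 1:25) {
    N <- sample(10:30, 1)
    bg <- sprintf("x%03d", 1:N)
    mod <- sample(bg, sample(2:6, 1))
    setg <- sample(bg, sample(2:8, 1))
    asg2 <- stats::setNames(ifelse(bg %in% mod, "m", "unassigned"), bg)
    r <- enrich_modules(asg2, list(s = setg))
    k <- length(intersect(mod, setg))
    expect_equal(r$p_value, hyper_tail_oracle(k, length(setg), N, length(mod)),
                 tolerance = 1e-10)
  }

  expect_warning(enrich_modules(asg, list(hit = genes[1:5], ghost = "nope")),
                 "ghost")
})
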