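# Synthetic-data generators. Each generator emulates the statistical structure
# one downstream analysis assumes -- planted ultra-rare bi-allelic genotypes,
# incomplete U12-restricted intron retention, block-correlated expression
# modules tracking disease status, and methylation profiles as noisy convex
# mixtures with a depleted naive-B compartment -- and emits a ground-truth
# record alongside the data (never embedded in it). All randomness flows
# through the config seed via named sub-streams (see substream_seed), so
# adding a generator never perturbs the draws of existing ones.

#' Configuration for the variant-cohort simulator
#'
#' @param n_cases,n_controls Sample counts per group.
#' @param target_gene Gene carrying the planted bi-allelic genotypes
#'   (non-coding, mirroring an snRNA gene).
#' @param case_genotype_mode `"homozygous"`, `"compound_het"`, or `"mixed"`
#'   (alternating).
#' @param panel Candidate gene panel (character vector).
#' @param n_background_genes Number of background genes.
#' @param background_variants_per_sample Poisson mean of common background
#'   variants per sample.
#' @param af_spectrum Length-2 range of the log-uniform background allele
#'   frequency distribution.
#' @param ultra_rare_background_rate Poisson mean per sample of non-target
#'   variants with AF < 1e-5 (or absent from the reference).
#' @param seed Integer seed fixing all randomness.
#' @return A validated `variant_sim_config` list.
#' @export
variant_sim_config <- function(n_cases = 3, n_controls = 9,
                               target_gene = "RNU6ATAC",
                               case_genotype_mode = c("homozygous", "compound_het", "mixed"),
                               panel = c("RNU6ATAC", "RNU4ATAC"),
                               n_background_genes = 200,
                               background_variants_per_sample = 10,
                               af_spectrum = c(1e-6, 0.5),
                               ultra_rare_background_rate = 2,
                               seed = 1) {
  cfg <- list(
    n_cases = check_count(n_cases, "n_cases"),
    n_controls = check_count(n_controls, "n_controls"),
    target_gene = target_gene,
    case_genotype_mode = match.arg(case_genotype_mode),
    panel = panel,
    n_background_genes = check_count(n_background_genes, "n_background_genes", min = 1L),
    background_variants_per_sample = check_positive(background_variants_per_sample,
                                                    "background_variants_per_sample"),
    af_spectrum = af_spectrum,
    ultra_rare_background_rate = ultra_rare_background_rate,
    seed = check_count(seed, "seed"))
  if (!is.character(target_gene) || length(target_gene) != 1L || !nzchar(target_gene))
    stop_field("target_gene", "must be a non-empty gene identifier")
  if (!is.character(panel) || !length(panel) || anyDuplicated(panel))
    stop_field("panel", "must be a non-empty vector of unique gene identifiers")
  if (length(af_spectrum) != 2L || any(af_spectrum <= 0) || any(af_spectrum > 0.5) ||
      af_spectrum[1L] >= af_spectrum[2L])
    stop_field("af_spectrum", "must be an increasing pair of frequencies in (0, 0.5]")
  if (!is.numeric(ultra_rare_background_rate) || ultra_rare_background_rate < 0)
    stop_field("ultra_rare_background_rate", "must be a non-negative rate")
  structure(cfg, class = "variant_sim_config")
}

#' Simulate an annotated variant cohort with planted bi-allelic genotypes
#'
#' Every case carries a qualifying bi-allelic genotype in `target_gene`
#' (each planted allele's frequency is drawn log-uniform in `[1e-8, 5e-6]`,
#' comfortably below the 1e-5 ultra-rare filter); controls carry none.
#' Background variants are drawn per `af_spectrum`; an extra Poisson stream
#' of ultra-rare background variants (some absent from the reference,
#' i.e. AF missing) exercises the filter's missing-AF path.
#'
#' @param config A [variant_sim_config()].
#' @return List with `variants` (long per-sample call table, see
#'   [write_vcf_minimal()]) and `truth` (planted gene, per-sample planted
#'   genotypes, and the ultra-rare variant keys).
#' @export
simulate_variant_cohort <- function(config) {
  stopifnot(inherits(config, "variant_sim_config"))
  with_seed(substream_seed(config$seed, "variant_cohort"), {
    cases <- sprintf("case_%02d", seq_len(config$n_cases))
    controls <- sprintf("control_%03d", seq_len(config$n_controls))
    samples <- c(cases, controls)
    bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
    bg_coding <- seq_along(bg_genes) %% 2L == 0L # half coding, half non-coding
    genes <- c(config$target_gene, setdiff(config$panel, config$target_gene), bg_genes)
    coding_map <- c(stats::setNames(rep(FALSE, length(genes) - length(bg_genes)),
                                    genes[seq_len(length(genes) - length(bg_genes))]),
                    stats::setNames(bg_coding, bg_genes))
    # deterministic position allocator: each gene owns a 1e5 window on chr1
    # (the target gene on chr9 for flavor); every drawn variant is a new allele
    gene_base <- stats::setNames(seq_along(genes) * 100000L, genes)
    counter <- new.env(parent = emptyenv())
    next_pos <- function(gene) {
      n <- if (is.null(counter[[gene]])) 0L else counter[[gene]]
      counter[[gene]] <- n + 1L
      gene_base[[gene]] + n + 1L
    }
    bases <- c("A", "C", "G", "T")
    rows <- list()
    planted <- list()
    add_row <- function(sample, gene, pos, genotype, af, origin) {
      ref <- sample(bases, 1L)
      alt <- sample(setdiff(bases, ref), 1L)
      data.frame(sample_id = sample,
                 chromosome = if (gene == config$target_gene) "chr9" else "chr1",
                 position = pos, ref = ref, alt = alt, genotype = genotype,
                 gene = gene, coding = unname(coding_map[[gene]]),
                 population_af = af, parental_origin = origin,
                 stringsAsFactors = FALSE)
    }
    rare_af <- function(n) 10^stats::runif(n, log10(1e-8), log10(5e-6))
    mode_of <- function(i) switch(config$case_genotype_mode,
                                  homozygous = "homozygous",
                                  compound_het = "compound_het",
                                  mixed = if (i %% 2L == 1L) "homozygous" else "compound_het")
    for (i in seq_along(cases)) {
      if (mode_of(i) == "homozygous") {
        pos <- next_pos(config$target_gene)
        rows[[length(rows) + 1L]] <- add_row(cases[i], config$target_gene, pos,
                                             "hom_alt", rare_af(1L), "unknown")
        planted[[cases[i]]] <- list(mode = "homozygous", positions = pos)
      } else {
        pos <- c(next_pos(config$target_gene), next_pos(config$target_gene))
        rows[[length(rows) + 1L]] <- add_row(cases[i], config$target_gene, pos[1L],
                                             "het", rare_af(1L), "maternal")
        rows[[length(rows) + 1L]] <- add_row(cases[i], config$target_gene, pos[2L],
                                             "het", rare_af(1L), "paternal")
        planted[[cases[i]]] <- list(mode = "compound_het", positions = pos)
      }
    }
    ultra_keys <- character()
    for (s in samples) {
      n_bg <- stats::rpois(1L, config$background_variants_per_sample)
      if (n_bg > 0L) {
        gs <- sample(bg_genes, n_bg, replace = TRUE)
        afs <- 10^stats::runif(n_bg, log10(config$af_spectrum[1L]),
                               log10(config$af_spectrum[2L]))
        gts <- sample(c("het", "hom_alt"), n_bg, replace = TRUE, prob = c(0.9, 0.1))
        for (j in seq_len(n_bg)) {
          rows[[length(rows) + 1L]] <- add_row(s, gs[j], next_pos(gs[j]), gts[j],
                                               afs[j], "unknown")
        }
      }
      n_ur <- stats::rpois(1L, config$ultra_rare_background_rate)
      if (n_ur > 0L) {
        gs <- sample(bg_genes, n_ur, replace = TRUE)
        afs <- 10^stats::runif(n_ur, log10(1e-8), log10(9.9e-6))
        afs[stats::runif(n_ur) < 0.2] <- NA_real_ # absent from the reference
        gts <- sample(c("het", "hom_alt"), n_ur, replace = TRUE, prob = c(0.7, 0.3))
        for (j in seq_len(n_ur)) {
          pos <- next_pos(gs[j])
          rows[[length(rows) + 1L]] <- add_row(s, gs[j], pos, gts[j], afs[j], "unknown")
          ultra_keys <- c(ultra_keys, paste(s, gs[j], pos, sep = ":"))
        }
      }
    }
    variants <- do.call(rbind, rows)
    variants <- variants[order(variants$sample_id, variants$chromosome,
                               variants$position), , drop = FALSE]
    rownames(variants) <- NULL
    planted_keys <- unlist(lapply(cases, function(s)
      paste(s, config$target_gene, planted[[s]]$positions, sep = ":")))
    # the truth's ultra-rare set is fixed by the drawn frequencies themselves:
    # background-spectrum draws can land below 1e-5 too and belong in it
    all_keys <- paste(variants$sample_id, variants$gene, variants$position, sep = ":")
    truth <- list(target_gene = config$target_gene,
                  cases = cases, controls = controls,
                  planted = planted,
                  planted_keys = planted_keys,
                  variant_keys = all_keys,
                  variant_af = variants$population_af,
                  ultra_rare_keys = all_keys[is.na(variants$population_af) |
                                               variants$population_af < 1e-5])
    list(variants = variants, truth = truth)
  })
}

#' Configuration for the intron-retention count simulator
#'
#' @param n_cases,n_controls Sample counts per group.
#' @param n_genes Number of genes (each with `introns_per_gene` introns; one
#'   intron of each U12 gene is the minor-class intron).
#' @param introns_per_gene Introns per gene.
#' @param frac_u12_genes Fraction of genes that are U12-intron-containing
#'   (count resolved by round-half-up).
#' @param frac_hidden_u12 Fraction of U12 genes omitted from the emitted
#'   annotation (their minor intron labelled `"unknown"`; count resolved by
#'   `floor(frac * n + 0.5)`).
#' @param baseline_psi Length-2 Beta shape parameters of the per-intron
#'   baseline retention fraction.
#' @param delta_psi Mean retention increase of affected U12 introns in cases.
#' @param depth_mean,depth_size Negative-binomial coverage parameters
#'   (mean reads per intron and dispersion size).
#' @param case_group,control_group Group labels attached to the samples.
#' @param seed Integer seed.
#' @return A validated `ir_sim_config` list.
#' @export
ir_sim_config <- function(n_cases = 3, n_controls = 9, n_genes = 100,
                          introns_per_gene = 5, frac_u12_genes = 0.15,
                          frac_hidden_u12 = 0.2,
                          baseline_psi = c(2, 38), delta_psi = 0.3,
                          depth_mean = 200, depth_size = 10,
                          case_group = "case_RNU6ATAC", control_group = "control",
                          seed = 1) {
  cfg <- list(n_cases = check_count(n_cases, "n_cases", 1L),
              n_controls = check_count(n_controls, "n_controls", 1L),
              n_genes = check_count(n_genes, "n_genes", 1L),
              introns_per_gene = check_count(introns_per_gene, "introns_per_gene", 1L),
              frac_u12_genes = check_fraction(frac_u12_genes, "frac_u12_genes"),
              frac_hidden_u12 = check_fraction(frac_hidden_u12, "frac_hidden_u12"),
              baseline_psi = baseline_psi,
              delta_psi = check_fraction(delta_psi, "delta_psi"),
              depth_mean = check_positive(depth_mean, "depth_mean"),
              depth_size = check_positive(depth_size, "depth_size"),
              case_group = case_group, control_group = control_group,
              seed = check_count(seed, "seed"))
  if (length(baseline_psi) != 2L || any(baseline_psi <= 0))
    stop_field("baseline_psi", "must be two positive Beta shape parameters")
  mean_psi <- baseline_psi[1L] / sum(baseline_psi)
  if (mean_psi + cfg$delta_psi > 1 || mean_psi + cfg$delta_psi <= 0)
    stop_field("delta_psi", "baseline mean PSI + delta_psi must lie in (0, 1]")
  structure(cfg, class = "ir_sim_config")
}

#' Simulate retained/spliced intron read counts with planted U12 retention
#'
#' Baseline per-intron PSI is Beta-distributed; in case samples the minor
#' (U12-class) intron of every U12 gene has its PSI raised by `delta_psi`
#' (capped at 1, i.e. retention stays incomplete for typical baselines).
#' Per (intron, sample), coverage is negative-binomial and retained reads are
#' Binomial(coverage, psi). A `floor(frac_hidden_u12 * n_u12 + 0.5)`-sized
#' subset of U12 genes is hidden from the emitted annotation: their minor
#' intron is labelled `"unknown"` while the truth keeps the full labels.
#'
#' @param config An [ir_sim_config()].
#' @return List with `counts` (an `intron_counts` object: `retained` and
#'   `spliced` integer matrices, `groups`), `annotation` (BED-convention data
#'   frame), and `truth` (per-intron true class/PSI and the hidden gene set).
#' @export
simulate_intron_counts <- function(config) {
  stopifnot(inherits(config, "ir_sim_config"))
  with_seed(substream_seed(config$seed, "intron_counts"), {
    genes <- sprintf("gene_%03d", seq_len(config$n_genes))
    n_u12 <- round_half_up(config$frac_u12_genes * config$n_genes)
    u12_genes <- if (n_u12 > 0L) sort(sample(genes, n_u12)) else character()
    n_hidden <- round_half_up(config$frac_hidden_u12 * n_u12)
    hidden_genes <- if (n_hidden > 0L) sort(sample(u12_genes, n_hidden)) else character()
    per_gene <- config$introns_per_gene
    ann <- do.call(rbind, lapply(seq_along(genes), function(gi) {
      g <- genes[gi]
      idx <- seq_len(per_gene)
      minor <- if (g %in% u12_genes) sample(idx, 1L) else 0L
      true_class <- ifelse(idx == minor, "U12", "U2")
      emitted <- true_class
      if (g %in% hidden_genes) emitted[idx == minor] <- "unknown"
      start <- (gi - 1L) * per_gene * 1000L + (idx - 1L) * 1000L
      data.frame(intron_id = paste(g, idx, sep = "|"), gene = g,
                 chromosome = "chr1", start = start, end = start + 500L,
                 class = emitted, true_class = true_class,
                 stringsAsFactors = FALSE)
    }))
    n_introns <- nrow(ann)
    cases <- sprintf("%s_%02d", config$case_group, seq_len(config$n_cases))
    controls <- sprintf("%s_%02d", config$control_group, seq_len(config$n_controls))
    samples <- c(cases, controls)
    groups <- stats::setNames(c(rep(config$case_group, config$n_cases),
                                rep(config$control_group, config$n_controls)), samples)
    psi0 <- stats::rbeta(n_introns, config$baseline_psi[1L], config$baseline_psi[2L])
    affected <- ann$true_class == "U12"
    psi_case <- ifelse(affected, pmin(1, psi0 + config$delta_psi), psi0)
    retained <- matrix(0L, n_introns, length(samples),
                       dimnames = list(ann$intron_id, samples))
    spliced <- retained
    for (j in seq_along(samples)) {
      psi <- if (groups[j] == config$case_group) psi_case else psi0
      total <- stats::rnbinom(n_introns, mu = config$depth_mean, size = config$depth_size)
      ret <- stats::rbinom(n_introns, total, psi)
      retained[, j] <- ret
      spliced[, j] <- total - ret
    }
    counts <- structure(list(retained = retained, spliced = spliced, groups = groups),
                        class = "intron_counts")
    truth <- list(
      intron = data.frame(intron_id = ann$intron_id, gene = ann$gene,
                          true_class = ann$true_class,
                          hidden = ann$gene %in% hidden_genes & ann$true_class == "U12",
                          psi_control = psi0, psi_case = psi_case,
                          stringsAsFactors = FALSE),
      u12_genes = u12_genes, hidden_genes = hidden_genes,
      case_group = config$case_group, control_group = config$control_group)
    ann$true_class <- NULL
    list(counts = counts, annotation = ann, truth = truth)
  })
}

#' Configuration for the modular expression simulator
#'
#' @param n_cases,n_controls Samples per group (both must be >= 1).
#' @param module_sizes Integer vector of module sizes (one entry per module).
#' @param n_trait_modules Number of leading modules whose latent factor
#'   shifts with disease status.
#' @param within_module_correlation Target pairwise correlation of genes
#'   within a module, in (0, 1).
#' @param trait_effect Standardized mean shift of a trait module's factor in
#'   cases.
#' @param noise_sd Residual standard deviation.
#' @param n_background_genes Unstructured background genes.
#' @param seed Integer seed.
#' @return A validated `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_cases = 20, n_controls = 20,
                            module_sizes = rep(50L, 8L), n_trait_modules = 2,
                            within_module_correlation = 0.8, trait_effect = 1.5,
                            noise_sd = 1, n_background_genes = 100, seed = 1) {
  cfg <- list(n_cases = check_count(n_cases, "n_cases", 1L),
              n_controls = check_count(n_controls, "n_controls", 1L),
              module_sizes = vapply(seq_along(module_sizes), function(i)
                check_count(module_sizes[i], "module_sizes", 1L), 0L),
              n_trait_modules = check_count(n_trait_modules, "n_trait_modules"),
              within_module_correlation =
                check_fraction(within_module_correlation, "within_module_correlation",
                               lo_open = TRUE, hi_open = TRUE),
              trait_effect = trait_effect,
              noise_sd = check_positive(noise_sd, "noise_sd"),
              n_background_genes = check_count(n_background_genes, "n_background_genes"),
              seed = check_count(seed, "seed"))
  if (!length(cfg$module_sizes)) stop_field("module_sizes", "must list at least one module")
  if (cfg$n_trait_modules > length(cfg$module_sizes))
    stop_field("n_trait_modules", "cannot exceed the number of modules")
  if (!is.numeric(trait_effect) || length(trait_effect) != 1L || is.na(trait_effect))
    stop_field("trait_effect", "must be a single number")
  structure(cfg, class = "expr_sim_config")
}

#' Simulate block-correlated expression with trait-linked modules
#'
#' Genes in module m follow `x = b * f_m + noise_sd * e` with loading `b`
#' chosen so the within-module pairwise correlation equals
#' `within_module_correlation`. Trait modules add `trait_effect * status` to
#' their factor; background genes are independent noise.
#'
#' @param config An [expr_sim_config()].
#' @return List with `expr` (genes x samples matrix), `traits` (data frame of
#'   `sample_id` and 0/1 `status`), and `truth` (gene module labels, the
#'   trait-linked module names, and the latent factor matrix).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  with_seed(substream_seed(config$seed, "expression"), {
    n <- config$n_cases + config$n_controls
    samples <- c(sprintf("case_%02d", seq_len(config$n_cases)),
                 sprintf("control_%02d", seq_len(config$n_controls)))
    status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
    k <- length(config$module_sizes)
    module_names <- sprintf("M%d", seq_len(k))
    trait_modules <- module_names[seq_len(config$n_trait_modules)]
    r <- config$within_module_correlation
    b <- config$noise_sd * sqrt(r / (1 - r))
    factors <- matrix(stats::rnorm(k * n), k, n,
                      dimnames = list(module_names, samples))
    for (m in trait_modules) factors[m, ] <- factors[m, ] + config$trait_effect * status
    total_genes <- sum(config$module_sizes) + config$n_background_genes
    genes <- sprintf("gene_%04d", seq_len(total_genes))
    labels <- c(rep(module_names, config$module_sizes),
                rep("background", config$n_background_genes))
    expr <- matrix(stats::rnorm(total_genes * n, sd = config$noise_sd),
                   total_genes, n, dimnames = list(genes, samples))
    for (m in seq_len(k)) {
      rows <- which(labels == module_names[m])
      expr[rows, ] <- expr[rows, ] + rep(b * factors[m, ], each = length(rows))
    }
    list(expr = expr,
         traits = data.frame(sample_id = samples, status = status,
                             stringsAsFactors = FALSE),
         truth = list(labels = stats::setNames(labels, genes),
                      trait_modules = trait_modules, factors = factors))
  })
}

# Default whole-blood cell types and Dirichlet concentrations: neutrophil-
# dominant, with small naive/memory/transitional B compartments; total
# concentration ~100 gives realistic between-individual variability
# (naive-B coefficient of variation ~0.5).
BLOOD_CELL_TYPES <- c(
  "naive B" = 4, "memory B" = 2, "transitional B" = 1, "CD4 T" = 14,
  "CD8 T" = 9, "T regulatory" = 2, "NK" = 5, "monocytes" = 8,
  "neutrophils" = 45, "eosinophils" = 3, "basophils" = 1, "dendritic" = 2)

#' Configuration for the methylation-mixture simulator
#'
#' @param n_cell_types Number of cell types (12 by default; must match
#'   `base_proportions` when supplied).
#' @param n_cpgs Number of CpG features.
#' @param n_cases,n_controls Samples per group.
#' @param base_proportions Named Dirichlet concentration vector; defaults to
#'   a whole-blood profile (see `BLOOD_CELL_TYPES` in the source).
#' @param depleted_cell_type Cell type whose mixing weight is multiplied by
#'   `depletion_factor` in cases (then renormalized).
#' @param depletion_factor Fraction in (0, 1]; 1 disables the depletion.
#' @param beta_precision Beta measurement-noise precision; larger is less
#'   noisy.
#' @param noiseless If `TRUE`, emit the exact convex mixture (no Beta noise).
#' @param seed Integer seed.
#' @return A validated `meth_sim_config` list.
#' @export
meth_sim_config <- function(n_cell_types = 12, n_cpgs = 200,
                            n_cases = 10, n_controls = 17,
                            base_proportions = NULL,
                            depleted_cell_type = "naive B",
                            depletion_factor = 0.4, beta_precision = 100,
                            noiseless = FALSE, seed = 1) {
  n_cell_types <- check_count(n_cell_types, "n_cell_types", 2L)
  if (is.null(base_proportions)) {
    base_proportions <- if (n_cell_types == length(BLOOD_CELL_TYPES)) BLOOD_CELL_TYPES
      else stats::setNames(rep(5, n_cell_types), sprintf("celltype_%02d", seq_len(n_cell_types)))
  }
  if (length(base_proportions) != n_cell_types || is.null(names(base_proportions)) ||
      any(base_proportions <= 0))
    stop_field("base_proportions", "must be named positive concentrations, one per cell type")
  if (n_cell_types != length(BLOOD_CELL_TYPES) && identical(depleted_cell_type, "naive B") &&
      !"naive B" %in% names(base_proportions))
    depleted_cell_type <- names(base_proportions)[1L]
  if (!depleted_cell_type %in% names(base_proportions))
    stop_field("depleted_cell_type", "must name one of the cell types")
  if (!is.numeric(depletion_factor) || length(depletion_factor) != 1L ||
      is.na(depletion_factor) || depletion_factor <= 0 || depletion_factor > 1)
    stop_field("depletion_factor", "must lie in (0, 1]")
  structure(list(n_cell_types = n_cell_types,
                 n_cpgs = check_count(n_cpgs, "n_cpgs", 1L),
                 n_cases = check_count(n_cases, "n_cases", 1L),
                 n_controls = check_count(n_controls, "n_controls", 1L),
                 base_proportions = base_proportions,
                 depleted_cell_type = depleted_cell_type,
                 depletion_factor = depletion_factor,
                 beta_precision = check_positive(beta_precision, "beta_precision"),
                 noiseless = isTRUE(noiseless),
                 seed = check_count(seed, "seed")),
            class = "meth_sim_config")
}

#' Simulate methylation beta values as noisy convex cell-type mixtures
#'
#' Cell-type reference profiles are drawn once (U-shaped Beta(0.4, 0.4), so
#' types are mutually distinguishable); per-sample mixing weights are
#' Dirichlet on the simplex, with the depleted type's weight multiplied by
#' `depletion_factor` in cases before renormalization. Observed betas are
#' Beta-distributed around the mixture mean with precision `beta_precision`,
#' or exactly the mixture when `noiseless`.
#'
#' @param config A [meth_sim_config()].
#' @return List with `beta` (CpG x sample matrix), `reference` (CpG x
#'   cell-type matrix), `groups` (named sample group labels), and `truth`
#'   (exact mixing weights, cell types x samples).
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "meth_sim_config"))
  with_seed(substream_seed(config$seed, "methylation"), {
    types <- names(config$base_proportions)
    cpgs <- sprintf("cg%06d", seq_len(config$n_cpgs))
    reference <- matrix(stats::rbeta(config$n_cpgs * length(types), 0.4, 0.4),
                        config$n_cpgs, length(types),
                        dimnames = list(cpgs, types))
    samples <- c(sprintf("case_%02d", seq_len(config$n_cases)),
                 sprintf("control_%02d", seq_len(config$n_controls)))
    groups <- stats::setNames(c(rep("case", config$n_cases),
                                rep("control", config$n_controls)), samples)
    weights <- sapply(samples, function(s) {
      w <- stats::rgamma(length(types), shape = config$base_proportions)
      w <- w / sum(w)
      if (groups[[s]] == "case") {
        w[types == config$depleted_cell_type] <-
          w[types == config$depleted_cell_type] * config$depletion_factor
        w <- w / sum(w)
      }
      w
    })
    rownames(weights) <- types
    mu <- reference %*% weights
    if (config$noiseless) {
      beta <- mu
    } else {
      mu_c <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
      beta <- matrix(stats::rbeta(length(mu_c), mu_c * config$beta_precision,
                                  (1 - mu_c) * config$beta_precision),
                     nrow(mu_c), ncol(mu_c), dimnames = dimnames(mu_c))
    }
    list(beta = beta, reference = reference, groups = groups,
         truth = list(weights = weights))
  })
}
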