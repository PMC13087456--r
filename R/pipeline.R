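# Pipeline orchestration and the `minorsplice` command-line entry point.
# Stages run in the analysis' natural order (simulate -> variant discovery /
# panel screen -> intron retention -> co-expression network -> deconvolution
# -> clinical summary); every stage writes its outputs plus a JSON manifest
# recording parameters, seed, and input/output file hashes, so a rerun with
# an identical config is byte-identical and verifiable.

PIPELINE_STAGES <- c("simulate", "prioritize", "ir", "modules", "deconvolve", "clinical")

#' Default pipeline configuration
#'
#' A small, fast end-to-end configuration over bundled synthetic data; every
#' block is overridable. Stage parameter defaults mirror the individual
#' functions' defaults.
#'
#' @param seed Global seed; sub-stream seeds are derived per generator.
#' @return Nested config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = PIPELINE_STAGES,
    log_level = "info",
    simulate = list(
      variant = list(n_cases = 3, n_controls = 9),
      ir = list(n_cases = 3, n_controls = 9, n_genes = 40, introns_per_gene = 3),
      expr = list(n_cases = 10, n_controls = 10, module_sizes = rep(30L, 4L),
                  n_trait_modules = 1),
      meth = list(n_cases = 6, n_controls = 8, n_cpgs = 120)),
    prioritize = list(maf_threshold = 1e-5, gene_class = "noncoding", panel = NULL),
    ir = list(min_coverage = 10, alpha = 0.05, min_effect = 0.05, gene_rule = "any"),
    modules = list(signed = TRUE, cut_height = 0.95, min_module_size = 15,
                   power = 12),
    deconvolve = list(test = "welch_t", sum_constraint = "equality"),
    clinical = list(tables = NULL))
}

validate_pipeline_config <- function(config) {
  known <- c("seed", "stages", "log_level", "simulate", "prioritize", "ir",
             "modules", "deconvolve", "clinical")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (p in c(config$prioritize$panel, config$clinical$tables)) {
    if (!is.null(p) && !file.exists(p)) stop("configured file does not exist: ", p)
  }
  invisible(config)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

pipeline_log <- function(level, config, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

write_manifest <- function(out_dir, stage, params, seed, inputs, outputs) {
  hash_by_name <- function(paths) {
    h <- tools::md5sum(paths)
    stats::setNames(as.list(unname(h)), basename(paths))
  }
  manifest <- list(stage = stage, seed = seed, parameters = params,
                   inputs = hash_by_name(inputs),
                   outputs = hash_by_name(outputs))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  write_json_report(manifest, path)
  path
}

require_upstream <- function(path, stage, upstream) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' is missing upstream output '%s' from stage '%s'",
                 stage, basename(path), upstream), call. = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order under `out_dir`. Each
#' stage writes versioned plain-text outputs and a JSON manifest (parameters,
#' seed, MD5 of inputs and outputs). All randomness flows through the config
#' seed, so a rerun with an identical config is byte-identical.
#'
#' @param config Nested list as produced by [default_pipeline_config()]
#'   (partial configs are merged over the defaults), or a path to a JSON
#'   file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of manifest paths per executed stage.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- merge_config(default_pipeline_config(), config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% config$stages]
  manifests <- list()
  path <- function(...) file.path(out_dir, ...)

  if ("simulate" %in% stages) {
    pipeline_log("info", config, "simulate: generating synthetic inputs")
    vcfg <- do.call(variant_sim_config,
                    c(config$simulate$variant, list(seed = config$seed)))
    sim_v <- simulate_variant_cohort(vcfg)
    write_vcf_minimal(sim_v$variants, path("variants.vcf"))
    write_json_report(sim_v$truth[c("target_gene", "cases", "controls",
                                    "planted_keys", "ultra_rare_keys")],
                      path("variants_truth.json"))
    icfg <- do.call(ir_sim_config, c(config$simulate$ir, list(seed = config$seed)))
    sim_i <- simulate_intron_counts(icfg)
    write_intron_counts(sim_i$counts, path("intron_counts.tsv"))
    write_bed6(sim_i$annotation, path("intron_annotation.bed"))
    write_tsv_df(data.frame(sample_id = names(sim_i$counts$groups),
                            group = unname(sim_i$counts$groups)),
                 path("ir_samples.tsv"))
    write_json_report(sim_i$truth[c("u12_genes", "hidden_genes")],
                      path("ir_truth.json"))
    ecfg <- do.call(expr_sim_config, c(config$simulate$expr, list(seed = config$seed)))
    sim_e <- simulate_expression(ecfg)
    write_tsv_matrix(sim_e$expr, path("expression.tsv"), id_col = "gene")
    write_tsv_df(sim_e$traits, path("expr_traits.tsv"))
    mcfg <- do.call(meth_sim_config, c(config$simulate$meth, list(seed = config$seed)))
    sim_m <- simulate_methylation(mcfg)
    write_tsv_matrix(sim_m$beta, path("methylation_beta.tsv"), id_col = "cpg")
    write_tsv_matrix(sim_m$reference, path("methylation_reference.tsv"), id_col = "cpg")
    write_tsv_df(data.frame(sample_id = names(sim_m$groups),
                            group = unname(sim_m$groups)),
                 path("meth_samples.tsv"))
    outs <- path(c("variants.vcf", "variants_truth.json", "intron_counts.tsv",
                   "intron_annotation.bed", "ir_samples.tsv", "ir_truth.json",
                   "expression.tsv", "expr_traits.tsv", "methylation_beta.tsv",
                   "methylation_reference.tsv", "meth_samples.tsv"))
    manifests$simulate <- write_manifest(out_dir, "simulate", config$simulate,
                                         config$seed, character(), outs)
  }

  if ("prioritize" %in% stages) {
    vcf <- require_upstream(path("variants.vcf"), "prioritize", "simulate")
    pipeline_log("info", config, "prioritize: ultra-rare bi-allelic screen")
    variants <- read_vcf_minimal(vcf)
    rare <- filter_ultra_rare(variants, config$prioritize$maf_threshold)
    calls <- call_biallelic(rare)
    per_sample <- split(calls, calls$sample_id)
    shared <- intersect_candidate_genes(unname(per_sample),
                                        config$prioritize$gene_class)
    panel_path <- config$prioritize$panel %||%
      system.file("extdata", "minor_spliceosome_panel_synthetic.txt",
                  package = "minorsplice", mustWork = TRUE)
    panel <- read_panel(panel_path)
    screen <- suppressWarnings(screen_panel(variants, panel,
                                            config$prioritize$maf_threshold))
    report <- list(maf_threshold = config$prioritize$maf_threshold,
                   gene_class = config$prioritize$gene_class,
                   shared_genes = as.list(shared),
                   calls = calls_report(calls),
                   panel_hits = calls_report(screen))
    write_json_report(report, path("prioritization.json"))
    manifests$prioritize <- write_manifest(out_dir, "prioritize",
                                           config$prioritize, config$seed,
                                           c(vcf, panel_path),
                                           path("prioritization.json"))
  }

  if ("ir" %in% stages) {
    cts <- require_upstream(path("intron_counts.tsv"), "ir", "simulate")
    bed <- require_upstream(path("intron_annotation.bed"), "ir", "simulate")
    ss <- require_upstream(path("ir_samples.tsv"), "ir", "simulate")
    pipeline_log("info", config, "ir: differential intron retention")
    sheet <- utils::read.delim(ss, stringsAsFactors = FALSE)
    groups <- stats::setNames(sheet$group, sheet$sample_id)
    counts <- read_intron_counts(cts, groups)
    ann <- read_bed6(bed)
    psi <- compute_psi(counts, config$ir$min_coverage)
    case_group <- setdiff(unique(groups), "control")[1L]
    res <- test_differential_ir(psi, case_group, "control",
                                alpha = config$ir$alpha,
                                min_effect = config$ir$min_effect)
    genes <- call_gene_level(res, ann, config$ir$gene_rule)
    write_tsv_df(res, path("ir_results.tsv"))
    write_json_report(list(case_group = case_group,
                           significant_genes = as.list(genes),
                           n_significant_introns = sum(res$significant)),
                      path("ir_genes.json"))
    manifests$ir <- write_manifest(out_dir, "ir", config$ir, config$seed,
                                   c(cts, bed, ss),
                                   path(c("ir_results.tsv", "ir_genes.json")))
  }

  if ("modules" %in% stages) {
    ex <- require_upstream(path("expression.tsv"), "modules", "simulate")
    tr <- require_upstream(path("expr_traits.tsv"), "modules", "simulate")
    pipeline_log("info", config, "modules: co-expression network")
    expr <- read_tsv_matrix(ex)
    traits <- utils::read.delim(tr, stringsAsFactors = FALSE)
    power <- config$modules$power %||%
      pick_soft_threshold(expr, signed = config$modules$signed)$power
    tom <- compute_tom(drop_zero_variance(expr), power, config$modules$signed)
    assignment <- detect_modules(tom, config$modules$cut_height,
                                 config$modules$min_module_size)
    eg <- module_eigengenes(expr, assignment)
    mt <- module_trait_correlation(eg[traits$sample_id, , drop = FALSE],
                                   traits["status"])
    write_tsv_df(data.frame(gene = names(assignment), module = unname(assignment)),
                 path("module_assignment.tsv"))
    write_tsv_df(mt, path("module_trait.tsv"))
    write_json_report(list(power = power,
                           modules = as.list(table(assignment)),
                           significant_modules =
                             as.list(mt$module[mt$significant])),
                      path("modules.json"))
    manifests$modules <- write_manifest(out_dir, "modules", config$modules,
                                        config$seed, c(ex, tr),
                                        path(c("module_assignment.tsv",
                                               "module_trait.tsv", "modules.json")))
  }

  if ("deconvolve" %in% stages) {
    bm <- require_upstream(path("methylation_beta.tsv"), "deconvolve", "simulate")
    rf <- require_upstream(path("methylation_reference.tsv"), "deconvolve", "simulate")
    ss <- require_upstream(path("meth_samples.tsv"), "deconvolve", "simulate")
    pipeline_log("info", config, "deconvolve: cell-composition estimation")
    beta <- read_tsv_matrix(bm)
    reference <- read_tsv_matrix(rf)
    sheet <- utils::read.delim(ss, stringsAsFactors = FALSE)
    groups <- stats::setNames(sheet$group, sheet$sample_id)
    est <- estimate_fractions(beta, reference, config$deconvolve$sum_constraint)
    cmp <- compare_fractions(est, groups, test = config$deconvolve$test)
    wdf <- data.frame(sample_id = rownames(est$weights), est$weights,
                      check.names = FALSE)
    write_tsv_df(wdf, path("cell_fractions.tsv"))
    write_tsv_df(cmp, path("fraction_comparison.tsv"))
    manifests$deconvolve <- write_manifest(out_dir, "deconvolve",
                                           config$deconvolve, config$seed,
                                           c(bm, rf, ss),
                                           path(c("cell_fractions.tsv",
                                                  "fraction_comparison.tsv")))
  }

  if ("clinical" %in% stages) {
    tables <- config$clinical$tables %||% clinical_fixture_path("both")
    pipeline_log("info", config, "clinical: cohort summary")
    cohort <- load_cohort(tables)
    write_json_report(cohort_summary(cohort), path("clinical_summary.json"))
    manifests$clinical <- write_manifest(out_dir, "clinical", config$clinical,
                                         config$seed, tables,
                                         path("clinical_summary.json"))
  }

  invisible(manifests)
}

parse_cli_flags <- function(args) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' `minorsplice <simulate|prioritize|ir-test|modules|deconvolve|clinical|run>`
#' with `--config <json>`, `--seed <int>`, `--out <dir>`, `--log-level
#' <debug|info|warn|quiet>` plus per-stage flags (`--maf-threshold`,
#' `--gene-class`, `--panel`, `--min-coverage`, `--alpha`, `--min-effect`,
#' `--gene-rule`, `--unsigned`, `--cut-height`, `--min-module-size`,
#' `--power`, `--reference`, `--test`, `--sum-constraint`). Subcommands map
#' onto [run_pipeline()] stage subsets.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisible manifest list from [run_pipeline()].
#' @export
minorsplice_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: minorsplice <subcommand> --out <dir> [options]")
  sub <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  if (is.null(opts$out)) stop("--out <dir> is required")
  config <- if (!is.null(opts$config)) {
    merge_config(default_pipeline_config(), jsonlite::read_json(opts$config, simplifyVector = TRUE))
  } else {
    default_pipeline_config()
  }
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$log_level)) config$log_level <- opts$log_level
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  stage_map <- c(simulate = "simulate", prioritize = "prioritize",
                 `ir-test` = "ir", modules = "modules",
                 deconvolve = "deconvolve", clinical = "clinical")
  if (sub == "run") {
    # full pipeline; stages may still be restricted via config
  } else if (sub %in% names(stage_map)) {
    stage <- stage_map[[sub]]
    config$stages <- if (stage %in% c("prioritize", "ir", "modules", "deconvolve"))
      c("simulate", stage) else stage
    if (!is.null(opts$maf_threshold)) config$prioritize$maf_threshold <- num(opts$maf_threshold)
    if (!is.null(opts$gene_class)) config$prioritize$gene_class <- opts$gene_class
    if (!is.null(opts$panel)) config$prioritize$panel <- opts$panel
    if (!is.null(opts$min_coverage)) config$ir$min_coverage <- num(opts$min_coverage)
    if (!is.null(opts$alpha)) config$ir$alpha <- num(opts$alpha)
    if (!is.null(opts$min_effect)) config$ir$min_effect <- num(opts$min_effect)
    if (!is.null(opts$gene_rule)) config$ir$gene_rule <- opts$gene_rule
    if (isTRUE(opts$unsigned)) config$modules$signed <- FALSE
    if (!is.null(opts$cut_height)) config$modules$cut_height <- num(opts$cut_height)
    if (!is.null(opts$min_module_size)) config$modules$min_module_size <- num(opts$min_module_size)
    if (!is.null(opts$power)) config$modules$power <- num(opts$power)
    if (!is.null(opts$test)) config$deconvolve$test <- opts$test
    if (!is.null(opts$sum_constraint)) config$deconvolve$sum_constraint <- opts$sum_constraint
    if (!is.null(opts$tables)) config$clinical$tables <- strsplit(opts$tables, ",")[[1L]]
  } else {
    stop("unknown subcommand: ", sub)
  }
  invisible(run_pipeline(config, opts$out))
}
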