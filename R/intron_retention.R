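# Per-intron retention quantification and case/control differential testing.
#
# PSI here is oriented as a *retention* fraction, retained/(retained+spliced):
# the biological claim under test is intron retention, so larger PSI means
# more retained minor-spliceosome substrate. A `measure = "spliced"` flag
# flips the orientation for users who prefer the splicing convention.

#' Assemble an intron_counts object from matrices
#'
#' @param retained,spliced Non-negative integer matrices (introns x samples,
#'   identical dimnames).
#' @param groups Named character vector mapping sample ids to group labels.
#' @return An `intron_counts` object.
#' @export
intron_counts <- function(retained, spliced, groups) {
  stopifnot(identical(dimnames(retained), dimnames(spliced)),
            all(retained >= 0), all(spliced >= 0),
            all(colnames(retained) %in% names(groups)))
  structure(list(retained = retained, spliced = spliced,
                 groups = groups[colnames(retained)]),
            class = "intron_counts")
}

#' Compute the per-intron PSI (retention fraction) matrix
#'
#' `psi = retained / (retained + spliced)` wherever total coverage reaches
#' `min_coverage`; below that the entry is missing (NA), never imputed.
#'
#' @param counts An `intron_counts` object.
#' @param min_coverage Minimum retained + spliced reads for a defined PSI.
#' @param measure `"retained"` (default) or `"spliced"` (1 - retention).
#' @return A `psi_matrix` object: `psi` and `coverage` matrices plus the
#'   sample `groups`.
#' @export
compute_psi <- function(counts, min_coverage = 10, measure = c("retained", "spliced")) {
  stopifnot(inherits(counts, "intron_counts"))
  measure <- match.arg(measure)
  coverage <- counts$retained + counts$spliced
  psi <- counts$retained / coverage
  if (measure == "spliced") psi <- 1 - psi
  psi[coverage < min_coverage] <- NA_real_
  structure(list(psi = psi, coverage = coverage, retained = counts$retained,
                 groups = counts$groups, min_coverage = min_coverage,
                 measure = measure),
            class = "psi_matrix")
}

# logit of the shrunken retention fraction (retained + 0.5)/(coverage + 1);
# the pseudocount keeps 0 and 1 off the boundary at any coverage
shrunken_logit <- function(retained, coverage) {
  p <- (retained + 0.5) / (coverage + 1)
  log(p / (1 - p))
}

#' Test each intron for differential retention between two groups
#'
#' Two-sided Welch t test on the logit of the pseudocounted PSI, with
#' Benjamini-Hochberg adjustment across all tested introns. An intron is
#' significant when its adjusted p is below `alpha` AND its retention
#' increase (case minus control mean PSI) reaches `min_effect` -- the call is
#' one-directional because the phenomenon under test is retention gain.
#' Introns with fewer than two non-missing PSI values in either group are
#' reported untested (`tested = FALSE`, NA p).
#'
#' @param psi A `psi_matrix` from [compute_psi()].
#' @param case_group,control_group Group labels selecting the two sample sets.
#' @param alpha BH-adjusted significance level.
#' @param min_effect Minimum case-minus-control mean PSI increase.
#' @return Data frame: `intron_id`, `n_case`, `n_control`, `delta_psi`,
#'   `p_value`, `adjusted_p`, `tested`, `significant`.
#' @export
test_differential_ir <- function(psi, case_group, control_group,
                                 alpha = 0.05, min_effect = 0.05) {
  stopifnot(inherits(psi, "psi_matrix"))
  cases <- names(psi$groups)[psi$groups == case_group]
  controls <- names(psi$groups)[psi$groups == control_group]
  if (!length(cases)) stop("test_differential_ir: no samples in case group '", case_group, "'")
  if (!length(controls)) stop("test_differential_ir: no samples in control group '", control_group, "'")
  n_introns <- nrow(psi$psi)
  res <- data.frame(intron_id = rownames(psi$psi),
                    n_case = NA_integer_, n_control = NA_integer_,
                    delta_psi = NA_real_, p_value = NA_real_,
                    adjusted_p = NA_real_, tested = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_introns)) {
    pc <- psi$psi[i, cases]; pk <- psi$psi[i, controls]
    okc <- !is.na(pc); okk <- !is.na(pk)
    res$n_case[i] <- sum(okc); res$n_control[i] <- sum(okk)
    if (sum(okc) < 2L || sum(okk) < 2L) next
    res$delta_psi[i] <- mean(pc[okc]) - mean(pk[okk])
    lc <- shrunken_logit(psi$retained[i, cases][okc], psi$coverage[i, cases][okc])
    lk <- shrunken_logit(psi$retained[i, controls][okk], psi$coverage[i, controls][okk])
    res$p_value[i] <- welch_test(lc, lk)$p_value
    res$tested[i] <- TRUE
  }
  res$adjusted_p[res$tested] <- stats::p.adjust(res$p_value[res$tested], method = "BH")
  res$significant <- res$tested & !is.na(res$adjusted_p) &
    res$adjusted_p < alpha & res$delta_psi >= min_effect
  res
}

#' Aggregate intron-level results to significant genes
#'
#' @param results Data frame from [test_differential_ir()].
#' @param annotation Intron annotation (see [read_bed6()]); every tested
#'   intron must be annotated.
#' @param rule `"any"` (gene significant iff >= 1 significant intron,
#'   default), `"majority"` (more than half of its tested introns), or
#'   `"fisher"` (Fisher combination of intron p values, BH across genes at
#'   0.05).
#' @return Sorted character vector of significant genes.
#' @export
call_gene_level <- function(results, annotation, rule = c("any", "majority", "fisher")) {
  rule <- match.arg(rule)
  unknown <- setdiff(results$intron_id, annotation$intron_id)
  if (length(unknown))
    stop("call_gene_level: introns missing from the annotation: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  gene_of <- stats::setNames(annotation$gene, annotation$intron_id)
  results$gene <- gene_of[results$intron_id]
  if (rule == "any") {
    return(sort(unique(results$gene[results$significant])))
  }
  if (rule == "majority") {
    tested <- tapply(results$tested, results$gene, sum)
    sig <- tapply(results$significant, results$gene, sum)
    genes <- names(sig)[sig > tested[names(sig)] / 2 & tested[names(sig)] > 0]
    return(sort(genes))
  }
  # fisher: combine tested intron p-values per gene, BH across genes
  tested <- results[results$tested, , drop = FALSE]
  if (!nrow(tested)) return(character())
  stats_by_gene <- tapply(tested$p_value, tested$gene, function(p) {
    x2 <- -2 * sum(log(pmax(p, 1e-300)))
    stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
  })
  adj <- stats::p.adjust(stats_by_gene, method = "BH")
  sort(names(adj)[adj < 0.05])
}

#' Cross-tabulate significant genes from two cohorts against the U12 annotation
#'
#' Emits the full 2x2x2 contingency (significant in cohort A x in cohort B x
#' known-U12 per the annotation) over all annotated genes, plus a per-gene
#' table for genes significant in at least one cohort. A gene is "known U12"
#' when the annotation labels at least one of its introns `U12`; a novel
#' candidate is a significant gene that is not known U12 (its minor intron
#' may be annotated `unknown`).
#'
#' @param genes_A,genes_B Significant gene sets of the two cohorts.
#' @param annotation Intron annotation covering all genes.
#' @return List with `genes` (per-gene categories) and `counts` (8-row
#'   contingency data frame with columns `in_A`, `in_B`, `known_u12`, `n`).
#' @export
classify_cohort_overlap <- function(genes_A, genes_B, annotation) {
  universe <- unique(annotation$gene)
  missing <- setdiff(c(genes_A, genes_B), universe)
  if (length(missing))
    stop("classify_cohort_overlap: genes not in the annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  known_u12_genes <- unique(annotation$gene[annotation$class == "U12"])
  in_A <- universe %in% genes_A
  in_B <- universe %in% genes_B
  known <- universe %in% known_u12_genes
  counts <- expand.grid(in_A = c(FALSE, TRUE), in_B = c(FALSE, TRUE),
                        known_u12 = c(FALSE, TRUE))
  counts$n <- vapply(seq_len(nrow(counts)), function(i)
    sum(in_A == counts$in_A[i] & in_B == counts$in_B[i] & known == counts$known_u12[i]),
    0L)
  sig <- in_A | in_B
  genes <- data.frame(gene = universe[sig],
                      significant_in_A = in_A[sig], significant_in_B = in_B[sig],
                      known_u12 = known[sig],
                      novel_candidate = !known[sig],
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, counts = counts)
}

#' Write / read an intron count matrix as TSV with paired columns
#'
#' Columns come in `<sample>.retained` / `<sample>.spliced` pairs.
#'
#' @param counts An `intron_counts` object.
#' @param path TSV path.
#' @export
write_intron_counts <- function(counts, path) {
  stopifnot(inherits(counts, "intron_counts"))
  samples <- colnames(counts$retained)
  m <- matrix(0L, nrow(counts$retained), 2L * length(samples))
  m[, seq(1L, ncol(m), by = 2L)] <- counts$retained
  m[, seq(2L, ncol(m), by = 2L)] <- counts$spliced
  dimnames(m) <- list(rownames(counts$retained),
                      as.vector(rbind(paste0(samples, ".retained"),
                                      paste0(samples, ".spliced"))))
  write_tsv_matrix(m, path, id_col = "intron_id")
  invisible(path)
}

#' @rdname write_intron_counts
#' @param groups Named group labels for the samples in the file.
#' @return An `intron_counts` object.
#' @export
read_intron_counts <- function(path, groups) {
  m <- read_tsv_matrix(path)
  cols <- colnames(m)
  ret_cols <- grep("\\.retained$", cols, value = TRUE)
  samples <- sub("\\.retained$", "", ret_cols)
  spl_cols <- paste0(samples, ".spliced")
  if (!all(spl_cols %in% cols))
    stop("read_intron_counts: unpaired sample columns")
  retained <- m[, ret_cols, drop = FALSE]
  spliced <- m[, spl_cols, drop = FALSE]
  colnames(retained) <- colnames(spliced) <- samples
  intron_counts(retained, spliced, groups)
}

#' Plot a clustered PSI heatmap
#'
#' Plain clustered-matrix display: rows and columns ordered by
#' complete-linkage hierarchical clustering on Euclidean distance
#' (missing PSI entries are mean-imputed for ordering only).
#'
#' @param psi A `psi_matrix` or numeric matrix.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot_psi_heatmap <- function(psi, ...) {
  m <- if (inherits(psi, "psi_matrix")) psi$psi else psi
  for (i in seq_len(nrow(m))) {
    bad <- is.na(m[i, ])
    if (any(bad)) m[i, bad] <- mean(m[i, !bad])
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stats::heatmap(m, hclustfun = function(d) stats::hclust(d, method = "complete"),
                 scale = "none", ...)
}
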