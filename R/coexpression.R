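# Weighted co-expression network analysis: correlation-power adjacency,
# scale-free soft-threshold selection, topological overlap, average-linkage
# module detection with a static tree cut (deterministic; a documented
# simplification of the canonical dynamic cut), module eigengenes,
# Bonferroni-corrected module-trait correlation, and hypergeometric gene-set
# enrichment against user-supplied GMT sets.

MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue")

drop_zero_variance <- function(expr) {
  v <- apply(expr, 1L, stats::var)
  keep <- is.finite(v) & v > 0
  if (!any(keep)) stop("expression matrix has no genes with positive variance")
  expr[keep, , drop = FALSE]
}

#' Correlation-power adjacency matrix
#'
#' Signed: `a_ij = ((1 + cor_ij)/2)^power`; unsigned: `a_ij = |cor_ij|^power`;
#' the diagonal is zero.
#'
#' @param expr Genes x samples matrix.
#' @param power Soft-threshold power (>= 1).
#' @param signed Use the signed transform (default TRUE).
#' @return Adjacency matrix.
#' @export
adjacency_matrix <- function(expr, power, signed = TRUE) {
  if (power < 1) stop("power must be >= 1")
  cc <- stats::cor(t(expr))
  if (any(!is.finite(cc))) {
    bad <- unique(rownames(cc)[which(!is.finite(cc), arr.ind = TRUE)[, 1L]])
    stop("non-finite correlations involving genes: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 0
  a
}

# Scale-free topology fit: regress log10 bin frequency on log10 binned
# connectivity (10 equal-width bins). A power law requires a *decreasing*
# frequency in k, so fits with a non-negative slope score 0 -- the field's
# signed-fit convention, which keeps narrow noise-driven connectivity
# distributions from scoring well by accident.
scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L || max(k) == min(k)) return(0)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(ok) < 3L) return(0)
  x <- log10(as.numeric(kmean[ok]))
  y <- log10(as.numeric(freq[ok]))
  slope <- stats::cov(x, y) / stats::var(x)
  if (slope >= 0) return(0)
  stats::cor(x, y)^2
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each scanned power, the connectivity distribution's scale-free fit
#' R^2 (regression of log10 bin frequency on log10 binned connectivity) is
#' computed; the smallest power reaching `target_r2` is returned. If none
#' reaches it, the power maximizing R^2 is returned with `warning_flag` set.
#'
#' @param expr Genes x samples matrix (zero-variance genes are dropped; >= 10
#'   genes and >= 4 samples required).
#' @param powers Candidate powers (default 1:20).
#' @param signed Signed network (default TRUE).
#' @param target_r2 Scale-free fit target (default 0.8).
#' @return List with `power`, `warning_flag`, and the per-power `fit` table.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, signed = TRUE, target_r2 = 0.8) {
  if (!length(powers)) stop("powers must be non-empty")
  expr <- drop_zero_variance(expr)
  if (nrow(expr) < 10L) stop("need >= 10 genes with positive variance")
  if (ncol(expr) < 4L) stop("need >= 4 samples")
  cc <- stats::cor(t(expr))
  diag(cc) <- NA
  r2 <- vapply(powers, function(p) {
    a <- if (signed) ((1 + cc) / 2)^p else abs(cc)^p
    diag(a) <- 0
    scale_free_r2(rowSums(a))
  }, 0)
  fit <- data.frame(power = powers, r_squared = r2)
  hit <- which(r2 >= target_r2)
  if (length(hit)) {
    list(power = powers[hit[1L]], warning_flag = FALSE, fit = fit)
  } else {
    list(power = powers[which.max(r2)], warning_flag = TRUE, fit = fit)
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k = rowSums(a)` and unit diagonal: the fraction of network neighbors two
#' genes share, a smoother similarity than raw adjacency.
#'
#' @param expr Genes x samples matrix.
#' @param power Soft-threshold power.
#' @param signed Signed adjacency (default TRUE).
#' @return Symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
compute_tom <- function(expr, power, signed = TRUE) {
  a <- adjacency_matrix(expr, power, signed)
  tom_from_adjacency(a)
}

#' @rdname compute_tom
#' @param a Adjacency matrix (zero diagonal).
#' @export
tom_from_adjacency <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2 # enforce exact symmetry against FP noise
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' `1 - TOM`, cut at a fixed height; clusters smaller than
#' `min_module_size` fall into `"unassigned"`. Surviving modules are named
#' by decreasing size with conventional arbitrary color labels
#' (ties broken by first gene index), so labels are deterministic.
#'
#' @param tom Square symmetric TOM.
#' @param cut_height Static cut height on `1 - TOM` in (0, 1].
#' @param min_module_size Minimum module size (default 30).
#' @return Named character vector of module labels per gene.
#' @export
detect_modules <- function(tom, cut_height = 0.95, min_module_size = 30) {
  stopifnot(nrow(tom) == ncol(tom))
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must lie in (0, 1]")
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = cut_height)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(tom)))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order by decreasing size, ties by first occurrence in gene order
  first_idx <- vapply(keep, function(id) which(cl == id)[1L], 0L)
  keep <- keep[order(-as.integer(sizes[keep]), first_idx)]
  labels <- rep("unassigned", length(cl))
  for (i in seq_along(keep)) {
    lab <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else sprintf("module%02d", i)
    labels[cl == as.integer(keep[i])] <- lab
  }
  stats::setNames(labels, genes)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix (one value per sample), sign-aligned so
#' that its correlation with the module's mean standardized expression is
#' positive. A single-gene module's eigengene is that standardized gene.
#'
#' @param expr Genes x samples matrix.
#' @param assignment Named labels from [detect_modules()] (genes labelled
#'   `"unassigned"` are skipped).
#' @return Samples x modules matrix of eigengenes.
#' @export
module_eigengenes <- function(expr, assignment) {
  modules <- setdiff(unique(assignment), "unassigned")
  if (!length(modules)) stop("no modules to summarize")
  out <- sapply(modules, function(m) {
    genes <- names(assignment)[assignment == m]
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[!is.finite(xs)] <- 0 # zero-variance genes carry no signal
    if (nrow(xs) == 1L) return(as.numeric(xs))
    sv <- svd(xs, nu = 0, nv = 1L)
    eg <- sv$v[, 1L]
    ref <- colMeans(xs)
    if (sum(eg * ref) < 0) eg <- -eg
    eg
  })
  rownames(out) <- colnames(expr)
  out
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation with a two-sided t-approximation p value per
#' (module, trait) pair, Bonferroni-corrected over the whole grid
#' (`n_modules * n_traits`). A constant trait yields an undefined (NA,
#' flagged) result rather than an error.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param traits Samples x traits data frame or matrix (numeric; align rows
#'   with the eigengene matrix).
#' @param alpha Significance level after Bonferroni (default 0.05).
#' @return Data frame: `module`, `trait`, `r`, `p_value`,
#'   `bonferroni_adjusted_p`, `significant`, `undefined`.
#' @export
module_trait_correlation <- function(eigengenes, traits, alpha = 0.05) {
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(eigengenes))
    stop("eigengenes and traits must cover the same samples")
  n <- nrow(eigengenes)
  grid <- expand.grid(module = colnames(eigengenes), trait = names(traits),
                      stringsAsFactors = FALSE)
  m_tests <- nrow(grid)
  res <- lapply(seq_len(m_tests), function(i) {
    e <- eigengenes[, grid$module[i]]
    t_ <- as.numeric(traits[[grid$trait[i]]])
    if (stats::sd(t_) == 0 || stats::sd(e) == 0) {
      return(list(r = NA_real_, p = NA_real_, undefined = TRUE))
    }
    r <- stats::cor(e, t_)
    list(r = r, p = cor_test_p(r, n), undefined = FALSE)
  })
  grid$r <- vapply(res, `[[`, 0, "r")
  grid$p_value <- vapply(res, `[[`, 0, "p")
  grid$bonferroni_adjusted_p <- pmin(1, grid$p_value * m_tests)
  grid$significant <- !is.na(grid$bonferroni_adjusted_p) &
    grid$bonferroni_adjusted_p < alpha
  grid$undefined <- vapply(res, `[[`, NA, "undefined")
  grid
}

#' Hypergeometric gene-set enrichment of modules
#'
#' One-sided hypergeometric tail `P(X >= overlap)` per (module, gene set),
#' with the background fixed to all profiled genes (assigned plus
#' unassigned) and BH adjustment across sets within each module. Gene sets
#' with no gene in the background are skipped with a warning.
#'
#' @param assignment Named module labels from [detect_modules()].
#' @param gene_sets Named list of gene vectors (see [read_gmt()]).
#' @return Data frame: `module`, `set`, `overlap`, `module_size`,
#'   `set_size`, `p_value`, `adjusted_p`.
#' @export
enrich_modules <- function(assignment, gene_sets) {
  background <- names(assignment)
  N <- length(background)
  sizes <- vapply(gene_sets, function(s) length(intersect(s, background)), 0L)
  empty <- names(gene_sets)[sizes == 0L]
  if (length(empty)) {
    warning("enrich_modules: skipping gene sets with no background gene: ",
            paste(empty, collapse = ", "))
    gene_sets <- gene_sets[sizes > 0L]
  }
  if (!length(gene_sets)) stop("no usable gene sets")
  modules <- setdiff(unique(assignment), "unassigned")
  rows <- list()
  for (m in modules) {
    mod_genes <- names(assignment)[assignment == m]
    for (s in names(gene_sets)) {
      set_genes <- intersect(gene_sets[[s]], background)
      k <- length(intersect(mod_genes, set_genes))
      p <- stats::phyper(k - 1L, length(set_genes), N - length(set_genes),
                         length(mod_genes), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, overlap = k, module_size = length(mod_genes),
        set_size = length(set_genes), p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  for (m in modules) {
    sel <- out$module == m
    out$adjusted_p[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}
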