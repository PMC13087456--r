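# Reference-based cell-composition estimation: project each bulk profile
# onto cell-type reference signatures under the simplex constraint
# (w >= 0, sum w = 1), then compare estimated fractions between groups.
#
# The quadratic program is solved by a primal active-set method written here
# (no QP solver ships in the dependency set): solve the equality-constrained
# least-squares system on the current support via its KKT system, drop the
# most negative weight while any weight is negative, and re-admit excluded
# cell types whose KKT multiplier is negative until the multipliers certify
# optimality. For the sum <= 1 variant, the unconstrained-sum non-negative
# solution is accepted when it already satisfies the budget; otherwise, by
# convexity, the optimum lies on the boundary and the equality solve applies.

solve_constrained_ls <- function(R, y, equality = TRUE) {
  k <- ncol(R)
  G <- crossprod(R)
  b <- drop(crossprod(R, y))
  tol <- 1e-10 * max(1, max(diag(G)))
  solve_support <- function(S) {
    m <- sum(S)
    if (equality) {
      A <- rbind(cbind(G[S, S, drop = FALSE], rep(1, m)), c(rep(1, m), 0))
      sol <- solve(A, c(b[S], 1))
      list(w = sol[seq_len(m)], lambda = 2 * sol[m + 1L])
    } else {
      list(w = drop(solve(G[S, S, drop = FALSE], b[S])), lambda = 0)
    }
  }
  S <- rep(TRUE, k)
  for (iter in seq_len(6L * k + 20L)) {
    sol <- solve_support(S)
    if (any(sol$w < -tol)) {
      drop_idx <- which(S)[which.min(sol$w)]
      S[drop_idx] <- FALSE
      if (!any(S)) stop("active set collapsed; reference may be degenerate")
      next
    }
    w <- numeric(k)
    w[S] <- pmax(sol$w, 0)
    mult <- 2 * (drop(G %*% w) - b) + sol$lambda
    viol <- which(!S & mult < -tol * 10)
    if (!length(viol)) return(w)
    S[viol[which.min(mult[viol])]] <- TRUE
  }
  warning("constrained least squares did not certify optimality; returning current iterate")
  w
}

#' Estimate cell-type fractions by simplex-constrained least squares
#'
#' Per sample, finds weights minimizing `||y - R w||^2` subject to `w >= 0`
#' and `sum(w) = 1` (or `sum(w) <= 1` when `sum_constraint = "inequality"`,
#' for panels that may not span the mixture). Works identically for
#' methylation beta references and expression signature matrices -- only the
#' reference differs.
#'
#' @param samples Features x samples matrix (bulk profiles).
#' @param reference Features x cell-types matrix; feature names must
#'   intersect the samples' in at least `ncol(reference)` features, and the
#'   reference must be full column rank.
#' @param sum_constraint `"equality"` (default, complete panel) or
#'   `"inequality"`.
#' @return A `mixture_estimate`: `weights` (samples x cell types),
#'   `residual_norm` per sample, `cell_types`, `n_features`.
#' @export
estimate_fractions <- function(samples, reference,
                               sum_constraint = c("equality", "inequality")) {
  sum_constraint <- match.arg(sum_constraint)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L,
                                               dimnames = list(names(samples), "sample_1"))
  feats <- intersect(rownames(samples), rownames(reference))
  if (length(feats) < ncol(reference))
    stop(sprintf("only %d shared features for %d cell types", length(feats),
                 ncol(reference)))
  R <- as.matrix(reference[feats, , drop = FALSE])
  qr_r <- qr(R)
  if (qr_r$rank < ncol(R)) {
    dep <- colnames(R)[qr_r$pivot[-seq_len(qr_r$rank)]]
    stop("reference matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  Y <- as.matrix(samples[feats, , drop = FALSE])
  weights <- matrix(NA_real_, ncol(Y), ncol(R),
                    dimnames = list(colnames(Y), colnames(R)))
  resid <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    w <- solve_constrained_ls(R, y, equality = TRUE)
    if (sum_constraint == "inequality") {
      w_free <- solve_constrained_ls(R, y, equality = FALSE)
      if (sum(w_free) <= 1) w <- w_free
    }
    weights[j, ] <- w
    resid[j] <- sqrt(sum((y - drop(R %*% w))^2))
  }
  structure(list(weights = weights, residual_norm = resid,
                 cell_types = colnames(R), n_features = length(feats),
                 sum_constraint = sum_constraint),
            class = "mixture_estimate")
}

#' Compare estimated cell-type fractions between two groups
#'
#' Per cell type, a two-sided Welch t test (default) or Mann-Whitney test of
#' case vs control fractions. The full per-cell-type table is always emitted
#' so non-significant types are visible, with significance tiers at the
#' conventional raw thresholds (`*` p < 0.05, `**` p < 0.01). No
#' multiplicity correction is applied by default (per-cell-type asterisks);
#' `adjust = "BH"` is available, in which case the tiers follow the adjusted
#' p values.
#'
#' @param estimates A `mixture_estimate` or a samples x cell-types weight
#'   matrix.
#' @param groups Named group labels covering the samples.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param case_group,control_group Labels selecting the two groups (>= 2
#'   samples each).
#' @param adjust `"none"` (default) or `"BH"` across cell types.
#' @param alpha,alpha_strict Tier thresholds (0.05 / 0.01).
#' @return Data frame: `cell_type`, `mean_case`, `mean_control`,
#'   `statistic`, `p_value`, `adjusted_p`, `tier`, `significant`.
#' @export
compare_fractions <- function(estimates, groups,
                              test = c("welch_t", "mann_whitney"),
                              case_group = "case", control_group = "control",
                              adjust = c("none", "BH"),
                              alpha = 0.05, alpha_strict = 0.01) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  w <- if (inherits(estimates, "mixture_estimate")) estimates$weights else as.matrix(estimates)
  groups <- groups[rownames(w)]
  cases <- rownames(w)[groups == case_group]
  controls <- rownames(w)[groups == control_group]
  if (length(cases) < 2L || length(controls) < 2L)
    stop("compare_fractions: need >= 2 samples per group")
  rows <- lapply(colnames(w), function(ct) {
    x <- w[cases, ct]; y <- w[controls, ct]
    if (test == "welch_t") {
      wt <- welch_test(x, y)
      data.frame(cell_type = ct, mean_case = wt$mean_x, mean_control = wt$mean_y,
                 statistic = wt$statistic, p_value = wt$p_value,
                 stringsAsFactors = FALSE)
    } else {
      mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      data.frame(cell_type = ct, mean_case = mean(x), mean_control = mean(y),
                 statistic = unname(mw$statistic), p_value = mw$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$tier <- ifelse(out$adjusted_p < alpha_strict, "**",
                     ifelse(out$adjusted_p < alpha, "*", ""))
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out
}
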