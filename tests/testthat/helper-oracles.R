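# Independent brute-force oracles. These deliberately re-derive results by
# the most literal method available (enumeration, double loops, sorting) and
# never call the package code paths they are checking.

# Benjamini-Hochberg step-up, literal: sort p, find largest i with
# p_(i) <= i/m * alpha ... here we return adjusted values by the cumulative
# minimum of m * p_(i) / i from the largest p downwards.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in seq(m, 1L)) {
    val <- min(prev, m * p[ord[i]] / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# TOM by explicit double loop over gene pairs.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- sum(a[i, ] * a[, j]) + a[i, j]
      tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# All weight vectors on the k-simplex with the given step.
simplex_grid <- function(k, step = 0.05) {
  n <- round(1 / step)
  combos <- expand.grid(rep(list(0:n), k - 1L))
  keep <- rowSums(combos) <= n
  combos <- combos[keep, , drop = FALSE]
  w <- cbind(combos, n - rowSums(combos)) * step
  as.matrix(unname(w))
}

# Median / type-7 quartiles by literal sorting and interpolation.
median_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}
quartile7_oracle <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1L, length(v))] - v[lo])
}

# Hypergeometric upper tail P(X >= k) by direct enumeration with choose().
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Tiny hand-rolled variant table builder for call tests.
make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r$s, chromosome = "chr1",
               position = r$pos, ref = "A", alt = "T",
               genotype = r$gt, gene = r$g,
               coding = isTRUE(r$coding),
               population_af = if (is.null(r$af)) NA_real_ else r$af,
               parental_origin = if (is.null(r$o)) "unknown" else r$o,
               stringsAsFactors = FALSE)
  }))
}
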