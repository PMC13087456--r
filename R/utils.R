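# Internal helpers shared across modules: validation, seeding, and a Welch t
# test that tolerates the degenerate inputs stats::t.test refuses.

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_field(field, sprintf("must be a number in %s%g, %g%s",
                              if (lo_open) "(" else "[", lo, hi,
                              if (hi_open) ")" else "]"))
  }
  as.numeric(x)
}

check_positive <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  as.numeric(x)
}

#' Derive a reproducible sub-stream seed from a global seed
#'
#' Every generator in the package draws from its own named random stream so
#' that adding a new generator never perturbs the draws of existing ones.
#' The sub-stream seed is a deterministic hash of the global seed and the
#' stream name, kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.numeric(seed), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 69069 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Round-half-up of x (floor(x + 0.5)); used wherever a fraction of a count
# must resolve to a deterministic integer.
round_half_up <- function(x) floor(x + 0.5)

#' Welch two-sample t test with degenerate-variance handling
#'
#' Behaves like the textbook Welch test but returns `p = 1` when both groups
#' are constant and equal (instead of erroring) and `p = 0` when both are
#' constant but different.
#'
#' @param x,y Numeric vectors (length >= 2 each).
#' @return A list with `statistic`, `df`, `p_value`, and the group means.
#' @export
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("welch_test needs >= 2 finite values per group")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 <= 0) {
    same <- isTRUE(all.equal(mx, my, tolerance = 1e-12))
    return(list(statistic = if (same) 0 else sign(mx - my) * Inf,
                df = NA_real_, p_value = if (same) 1 else 0,
                mean_x = mx, mean_y = my))
  }
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = stat, df = df, p_value = 2 * stats::pt(-abs(stat), df),
       mean_x = mx, mean_y = my)
}

# Pearson correlation p-value (two-sided, t approximation), NA-safe for
# degenerate inputs.
cor_test_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}
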