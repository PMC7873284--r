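# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a vector of child seeds (< 2^31) from a master seed, deterministically.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_srp <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop_srp(sprintf("`%s` must be a single finite number >= %s", name, min))
  }
  x
}

# Sort each row of a numeric matrix (ascending). Single vectorized radix
# order keeps this fast for many short rows.
row_sort <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) <= 1L) return(x)
  o <- order(row(x), x, method = "radix")
  matrix(x[o], nrow = nrow(x), byrow = TRUE)
}

# 16-bin equal-width histogram over [min, max] of `v`, L1-normalized.
# Degenerate range puts all mass in bin 1.
hist16 <- function(v, bins = 16L) {
  rng <- range(v)
  if (!is.finite(rng[1L]) || !is.finite(rng[2L])) {
    stop_srp("non-finite values in histogram input")
  }
  if (rng[2L] - rng[1L] <= 0) {
    out <- numeric(bins)
    out[1L] <- 1
    return(out)
  }
  idx <- floor((v - rng[1L]) / (rng[2L] - rng[1L]) * bins) + 1L
  idx[idx > bins] <- bins
  tabulate(idx, nbins = bins) / length(v)
}

# Rank-based AUC of `score` against logical `positive`; ties share ranks.
# Constant scores give 0.5 by construction.
auc_score <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
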