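# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results with naive loops / closed forms so they
# stay independent of the implementation they check.

# Fresh scratch directory under the session tempdir (wiped with the session).
withr_local_tempdir <- function() {
  d <- tempfile("srp3d-")
  dir.create(d)
  d
}

rand_patch <- function(side = 5L, lo = 0, hi = 100) {
  matrix(stats::runif(side^2, lo, hi), side, side)
}

# Counter-clockwise quarter rotation of a matrix.
rot90m <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Brute-force Chebyshev ring enumeration: glob and sqr patterns.
oracle_ring_patterns <- function(patch) {
  side <- nrow(patch)
  n <- (side - 1L) / 2L
  ctr <- n + 1L
  sqr <- patch[ctr, ctr]
  for (r in seq_len(n)) {
    vals <- c()
    for (x in seq_len(side)) {
      for (y in seq_len(side)) {
        if (max(abs(x - ctr), abs(y - ctr)) == r) vals <- c(vals, patch[x, y])
      }
    }
    sqr <- c(sqr, sort(vals))
  }
  list(glob = sort(as.vector(patch)), sqr = sqr)
}

# Naive circular sampling oracle: plain cos/sin positions and textbook
# bilinear interpolation (agrees with the implementation up to fp noise).
oracle_circle_patterns <- function(patch) {
  side <- nrow(patch)
  n <- (side - 1L) / 2L
  ctr <- n # 0-based centre
  bil <- function(px, py) {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    g <- function(x, y) patch[min(x, side - 1L) + 1L, min(y, side - 1L) + 1L]
    (1 - fx) * (1 - fy) * g(x0, y0) + fx * (1 - fy) * g(x0 + 1, y0) +
      (1 - fx) * fy * g(x0, y0 + 1) + fx * fy * g(x0 + 1, y0 + 1)
  }
  circ <- patch[ctr + 1L, ctr + 1L]
  ang <- c(); rad <- c()
  for (r in seq_len(n)) {
    q <- 8L * r
    th <- 2 * pi * (0:(q - 1L)) / q
    s_out <- vapply(th, function(t) bil(ctr + r * cos(t), ctr + r * sin(t)), 0)
    s_in <- vapply(th, function(t) bil(ctr + (r - 1) * cos(t), ctr + (r - 1) * sin(t)), 0)
    circ <- c(circ, sort(s_out))
    ang <- c(ang, sort(s_out - s_out[c(2:q, 1L)]))
    rad <- c(rad, sort(s_out - s_in))
  }
  list(circ = circ, ang = ang, rad = rad)
}

# Loop matrix-vector multiply.
oracle_matvec <- function(m, x) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    acc <- 0
    for (j in seq_len(ncol(m))) acc <- acc + m[i, j] * x[j]
    out[i] <- acc
  }
  out
}

# From-scratch loop implementation of the HC/EC ratio mechanics.
oracle_hcec <- function(raw, use_abs = TRUE) {
  vals <- if (use_abs) abs(raw) else raw
  maxima <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) maxima[i] <- max(vals[i, ])
  nz <- maxima[maxima != 0]
  if (length(nz) == 0L) stop("degenerate")
  thr <- min(nz)
  hc <- 0; total <- 0
  for (v in as.vector(vals)) {
    total <- total + v
    if (v > thr) hc <- hc + v
  }
  if (hc == 0) return(0)
  hc / (total - hc)
}

# Parametric line-rasterization oracle (round of parametric interpolation).
oracle_line <- function(p0, p1) {
  span <- max(abs(p1 - p0))
  if (span == 0) return(matrix(as.integer(p0), 1L))
  t(vapply(0:span, function(k) as.integer(round(p0 + k * (p1 - p0) / span)),
           integer(3)))
}

# Hand Kruskal-Wallis H and fixed-level rejection (no ties assumed).
oracle_kw_reject <- function(samples, alpha = 0.01) {
  vals <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  r <- rank(vals)
  n <- length(vals)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) length(x) * (mean(x) - (n + 1) / 2)^2))
  H > stats::qchisq(1 - alpha, df = length(samples) - 1L)
}

# Fake descriptor-set container for metric tests.
fake_descriptor_set <- function(raw_fG, raw_fRA = raw_fG) {
  structure(list(descriptors = matrix(0, nrow(raw_fG), 240L),
                 origins = matrix(0L, nrow(raw_fG), 3L),
                 raw_fG = raw_fG, raw_fRA = raw_fRA,
                 mode = "3d", bank_seed = 42L, n = 2L,
                 depth = 5L, stride = 5L, volume_dim = c(5L, 5L, 5L)),
            class = "srp_descriptor_set")
}

# Gaussian blob data with k well-separated centres (for codebook tests).
blob_data <- function(centers, per, sd = 0.05) {
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(stats::rnorm(per * ncol(centers), sd = sd), per), 2L,
          centers[i, ], `+`)
  }))
}
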