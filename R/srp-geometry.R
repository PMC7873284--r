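# Sampling geometry for SRP patterns.
#
# Circular samples are placed at 8r equally spaced angles on ring r
# (starting east, counter-clockwise) and read off the pixel grid with
# bilinear interpolation. Offsets and interpolation weights are built for
# a first-octant base set only and propagated to the full circle through
# exact dihedral (D4) index permutations; sample values are then evaluated
# as fixed-order 4-term weighted sums. This makes 90/180/270-degree patch
# rotations act as bitwise-exact permutations of the sample values, so the
# rotation invariance of the sorted patterns holds exactly in floating
# point, not merely in real arithmetic.

# Pixel-index permutations of the eight D4 elements on a side x side grid.
# Element order: Q^0..Q^3 (counter-clockwise quarter turns), then
# Q^0 X..Q^3 X where X is the diagonal swap (u,v) -> (v,u), applied first.
d4_pixel_perms <- function(side) {
  n <- (side - 1L) / 2L
  x <- rep(0:(side - 1L), times = side)
  y <- rep(0:(side - 1L), each = side)
  u <- x - n
  v <- y - n
  rot <- function(uu, vv, q) {
    for (i in seq_len(q)) {
      tmp <- uu
      uu <- -vv
      vv <- tmp
    }
    list(u = uu, v = vv)
  }
  perms <- vector("list", 8L)
  for (q in 0:3) {
    g <- rot(u, v, q)
    perms[[q + 1L]] <- (g$u + n) + side * (g$v + n) + 1L
    gx <- rot(v, u, q) # X first, then Q^q
    perms[[q + 5L]] <- (gx$u + n) + side * (gx$v + n) + 1L
  }
  perms
}

# Bilinear weight row for a sample at centre + (dx, dy). Returns four
# (index, weight) slots in fixed order; snapped coordinates collapse to
# zero-weight duplicate slots.
bilinear_row <- function(dx, dy, side) {
  n <- (side - 1L) / 2L
  snap <- function(p) if (abs(p - round(p)) < 1e-9) round(p) else p
  px <- snap(n + dx)
  py <- snap(n + dy)
  x0 <- floor(px)
  y0 <- floor(py)
  fx <- px - x0
  fy <- py - y0
  x1 <- if (fx == 0) x0 else x0 + 1
  y1 <- if (fy == 0) y0 else y0 + 1
  idx <- c(x0 + side * y0, x1 + side * y0, x0 + side * y1, x1 + side * y1) + 1
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  list(idx = as.integer(idx), w = w)
}

# First-octant base offsets for a ring of 8r samples at radius `rho`:
# angles pi*j/(4r), j = 0..r. Axis and diagonal samples are forced exact.
octant_offsets <- function(r, rho) {
  j <- 0:r
  theta <- pi * j / (4 * r)
  dx <- rho * cos(theta)
  dy <- rho * sin(theta)
  dx[1L] <- rho
  dy[1L] <- 0
  dx[r + 1L] <- dy[r + 1L] <- rho * sqrt(0.5)
  cbind(dx, dy)
}

# Sampling structure of one ring: four index vectors and four weight
# vectors (one slot each per sample) for the outer circle (radius r) and
# the inner circle (radius r-1 at the same 8r angles).
ring_sampling <- function(r, side, perms) {
  q <- 8L * r
  build <- function(rho) {
    base <- octant_offsets(r, rho)
    rows <- lapply(seq_len(r + 1L), function(j) {
      bilinear_row(base[j, 1L], base[j, 2L], side)
    })
    I <- matrix(1L, nrow = 4L, ncol = q)
    W <- matrix(0, nrow = 4L, ncol = q)
    for (k in 0:(q - 1L)) {
      qd <- k %/% (2L * r)
      m <- k %% (2L * r)
      if (m <= r) {
        j <- m
        perm <- perms[[qd + 1L]]
      } else {
        j <- 2L * r - m
        perm <- perms[[qd + 5L]]
      }
      row <- rows[[j + 1L]]
      I[, k + 1L] <- perm[row$idx]
      W[, k + 1L] <- row$w
    }
    list(I = I, W = W)
  }
  list(q = q, outer = build(r), inner = build(r - 1L))
}

# Evaluate ring samples for all plane rows at once: P is (nplanes x side^2),
# result is (nplanes x 8r). The four weighted terms are accumulated in a
# fixed order so permuted inputs give bitwise-identical permuted outputs.
sample_ring <- function(P, s) {
  np <- nrow(P)
  acc <- P[, s$I[1L, ], drop = FALSE] * rep(s$W[1L, ], each = np)
  for (l in 2:4) {
    acc <- acc + P[, s$I[l, ], drop = FALSE] * rep(s$W[l, ], each = np)
  }
  acc
}

# Cached per-n pattern structures: centre index, square (Chebyshev) ring
# index sets and circular sampling rings.
.srp_cache <- new.env(parent = emptyenv())

srp_structures <- function(n) {
  key <- as.character(n)
  if (!is.null(.srp_cache[[key]])) return(.srp_cache[[key]])
  side <- 2L * n + 1L
  x <- rep(0:(side - 1L), times = side)
  y <- rep(0:(side - 1L), each = side)
  cheb <- pmax(abs(x - n), abs(y - n))
  rings_sq <- lapply(seq_len(n), function(i) which(cheb == i))
  perms <- d4_pixel_perms(side)
  rings_circ <- lapply(seq_len(n), function(r) ring_sampling(r, side, perms))
  out <- list(
    n = n, side = side,
    center = n + side * n + 1L,
    rings_sq = rings_sq,
    rings_circ = rings_circ
  )
  .srp_cache[[key]] <- out
  out
}

# Lengths of the five pattern vectors for ring parameter n.
pattern_lengths <- function(n) {
  side <- 2L * n + 1L
  nc <- 4L * n * (n + 1L)
  c(G = side^2, S = side^2, C = 1L + nc, A = nc, R = nc)
}

# Five pattern matrices (one row per plane) from a stack of flattened
# square grids. The core of the SRP descriptor.
pattern_matrices <- function(P, st) {
  np <- nrow(P)
  glob <- row_sort(P)
  sqr_blocks <- vector("list", st$n + 1L)
  sqr_blocks[[1L]] <- P[, st$center, drop = FALSE]
  circ_blocks <- vector("list", st$n + 1L)
  circ_blocks[[1L]] <- P[, st$center, drop = FALSE]
  ang_blocks <- vector("list", st$n)
  rad_blocks <- vector("list", st$n)
  for (r in seq_len(st$n)) {
    sqr_blocks[[r + 1L]] <- row_sort(P[, st$rings_sq[[r]], drop = FALSE])
    rc <- st$rings_circ[[r]]
    s_out <- sample_ring(P, rc$outer)
    s_in <- sample_ring(P, rc$inner)
    circ_blocks[[r + 1L]] <- row_sort(s_out)
    shift <- c(2:rc$q, 1L)
    ang_blocks[[r]] <- row_sort(s_out - s_out[, shift, drop = FALSE])
    rad_blocks[[r]] <- row_sort(s_out - s_in)
  }
  list(
    G = glob,
    S = do.call(cbind, sqr_blocks),
    C = do.call(cbind, circ_blocks),
    A = do.call(cbind, ang_blocks),
    R = do.call(cbind, rad_blocks)
  )
}
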