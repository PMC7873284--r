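# Volumetric 3D SRP description: hyperplanes inside cubic patches.

#' 3D Bresenham voxel line
#'
#' Rasterizes the 26-connected voxel line between two integer voxel
#' coordinates using the parametric-rounding form of Bresenham's
#' algorithm: the k-th voxel is `round(p0 + k * (p1 - p0) / span)` where
#' `span` is the largest absolute coordinate difference. Rounding halves
#' follow IEEE round-half-to-even, which makes the path exactly symmetric
#' under endpoint reversal.
#'
#' @param p0,p1 Integer voxel coordinate triples.
#' @return Integer matrix with `max span + 1` rows and 3 columns, from
#'   `p0` to `p1` inclusive.
#' @examples
#' bresenham3d(c(0, 0, 0), c(4, 4, 4))
#' @export
bresenham3d <- function(p0, p1) {
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L ||
      any(p0 != round(p0)) || any(p1 != round(p1))) {
    stop_srp("endpoints must be integer voxel coordinate triples")
  }
  d <- p1 - p0
  span <- max(abs(d))
  if (span == 0) {
    return(matrix(as.integer(p0), nrow = 1L, ncol = 3L))
  }
  k <- 0:span
  pts <- round(outer(k / span, d) + rep(p0, each = span + 1L))
  storage.mode(pts) <- "integer"
  dimnames(pts) <- NULL
  pts
}

# Line parameters t_k for a hyperplane column track between bottom column i
# and top column j inside a patch of depth z: 5 samples along the Bresenham
# line (subsampled at 5 evenly spaced path indices when the raw path is
# longer, evaluated at 5 evenly spaced fractions when z < 5).
line_fractions <- function(i, j, z) {
  span <- max(abs(i - j), z - 1L)
  if (span > 4L) {
    round(seq(0, span, length.out = 5L)) / span
  } else {
    (0:4) / 4
  }
}

# Flat voxel index matrices for all hyperplanes of a 5 x 5 x z patch, one
# row per plane, 25 columns (plane grid flattened row-fastest: rows are the
# lateral positions, columns the line samples / slice index). Cached per z.
.plane_cache <- new.env(parent = emptyenv())

plane_indices <- function(z, side = 5L) {
  key <- paste(z, side)
  if (!is.null(.plane_cache[[key]])) return(.plane_cache[[key]])
  if (side != 5L) stop_srp("hyperplane construction supports lateral side 5 only")
  if (z < 2L) stop_srp("patch depth must be >= 2")
  lat <- 0:(side - 1L)
  yz <- matrix(0L, nrow = side^2, ncol = side^2)
  xz <- matrix(0L, nrow = side^2, ncol = side^2)
  p <- 0L
  for (i in lat) {
    for (j in lat) {
      p <- p + 1L
      t <- line_fractions(i, j, z)
      u <- as.integer(round(i + t * (j - i))) # lateral track
      w <- as.integer(round(t * (z - 1L)))    # slice track
      for (k in 0:(side - 1L)) {
        # YZ family: track runs along x, rows are y positions.
        yz[p, lat + side * k + 1L] <- u[k + 1L] + side * lat + side^2 * w[k + 1L] + 1L
        # XZ family: track runs along y, rows are x positions.
        xz[p, lat + side * k + 1L] <- lat + side * u[k + 1L] + side^2 * w[k + 1L] + 1L
      }
    }
  }
  zsel <- if (z > side) as.integer(round(seq(1L, z, length.out = side))) else seq_len(z)
  xy <- matrix(0L, nrow = length(zsel), ncol = side^2)
  grid <- lat + side * rep(lat, each = side) # x fastest within slice
  for (s in seq_along(zsel)) {
    xy[s, ] <- grid + side^2 * (zsel[s] - 1L) + 1L
  }
  out <- list(yz = yz, xz = xz, xy = xy,
              counts = c(yz = nrow(yz), xz = nrow(xz), xy = nrow(xy)))
  .plane_cache[[key]] <- out
  out
}

validate_volume_patch <- function(patch) {
  if (!is.array(patch) || length(dim(patch)) != 3L) {
    stop_srp("patch must be a 3D array")
  }
  d <- dim(patch)
  if (d[1L] != d[2L] || d[1L] %% 2L == 0L) {
    stop_srp("patch lateral sides must be odd and equal")
  }
  if (d[1L] != 5L) stop_srp("unsupported patch size: lateral side must be 5")
  if (d[3L] < 2L) stop_srp("patch depth must be >= 2")
  if (any(!is.finite(patch)) || any(patch < 0)) {
    stop_srp("patch intensities must be finite and non-negative")
  }
  invisible(d)
}

#' Build the hyperplanes of a cubic patch
#'
#' For the `yz` family, one 5 x 5 sampling plane is built for every ordered
#' pair (bottom column i, top column j), i, j in 0..4: its rows are the five
#' lateral y positions and its columns the five samples along the 3D
#' Bresenham line from voxel (i, y, 0) to (j, y, z-1), giving 25 planes.
#' The `xz` family swaps the roles of x and y. The `xy` family consists of
#' the axial slices of the patch (all slices when z <= 5, five evenly
#' resampled slices when z > 5).
#'
#' @param patch 3D array of shape 5 x 5 x z (z >= 2), finite non-negative.
#' @param orientation One of `"yz"`, `"xz"`, `"xy"`.
#' @return List of 5 x 5 numeric matrices (one per plane).
#' @export
build_hyperplanes <- function(patch, orientation = c("yz", "xz", "xy")) {
  orientation <- match.arg(tolower(orientation), c("yz", "xz", "xy"))
  d <- validate_volume_patch(patch)
  idx <- plane_indices(d[3L])[[orientation]]
  v <- as.vector(patch)
  lapply(seq_len(nrow(idx)), function(p) matrix(v[idx[p, ]], 5L, 5L))
}

# Shared descriptor core: from a stacked plane matrix (rows grouped by
# patch, plane order yz/xz/xy within a patch) compute the five projected
# function matrices and fold them into per-patch histogram descriptors.
describe_planes <- function(P, counts, npatch, bank, bins = 16L) {
  st <- srp_structures(bank$n)
  pm <- pattern_matrices(P, st)
  fmat <- lapply(names(pm), function(f) pm[[f]] %*% t(bank$rp[[f]]))
  names(fmat) <- names(pm)
  a <- bank$a
  npl <- sum(counts)
  fun_order <- c("G", "C", "S", "A", "R") # per-orientation block order
  desc <- matrix(0, nrow = npatch, ncol = bins * 5L * length(counts))
  raw_fG <- matrix(0, nrow = npatch, ncol = npl * a)
  raw_fRA <- matrix(0, nrow = npatch, ncol = 2L * npl * a)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  for (p in seq_len(npatch)) {
    prow <- (p - 1L) * npl
    col <- 0L
    for (o in seq_along(counts)) {
      rows <- prow + (starts[o]:ends[o])
      for (f in fun_order) {
        desc[p, col + seq_len(bins)] <- hist16(fmat[[f]][rows, ], bins)
        col <- col + bins
      }
    }
    all_rows <- prow + seq_len(npl)
    raw_fG[p, ] <- as.vector(fmat$G[all_rows, ])
    raw_fRA[p, ] <- c(as.vector(fmat$R[all_rows, ]), as.vector(fmat$A[all_rows, ]))
  }
  list(descriptors = desc, raw_fG = raw_fG, raw_fRA = raw_fRA)
}

#' 3D SRP descriptor of one cubic patch
#'
#' Computes, for each plane family (yz, xz, xy), the five SRP function
#' values of every plane, pools them per function across the family,
#' histograms each pooled vector into 16 equal-width bins spanning its own
#' range (L1-normalized; a degenerate range puts all mass in bin 1), and
#' concatenates the five 16-bin blocks (80 values per family) and the
#' three families (240 values total). The raw projected values are
#' retained for the heterochromatin metrics.
#'
#' @param patch 3D array of shape 5 x 5 x z, z >= 2.
#' @param bank An `srp_rp_bank` built for n = 2.
#' @param bins Number of histogram bins per function (default 16).
#' @return Object of class `srp_patch_descriptor`: list with `vector`
#'   (length 240), `raw_fG` (length #planes * a), `raw_fRA` (length
#'   #planes * 2a) and `plane_counts`.
#' @export
describe_patch <- function(patch, bank, bins = 16L) {
  d <- validate_volume_patch(patch)
  if (!inherits(bank, "srp_rp_bank")) stop_srp("`bank` must be an srp_rp_bank")
  if (bank$n != 2L) stop_srp("volumetric description requires a bank built for n = 2")
  pidx <- plane_indices(d[3L])
  v <- as.vector(patch)
  P <- rbind(matrix(v[pidx$yz], nrow(pidx$yz)),
             matrix(v[pidx$xz], nrow(pidx$xz)),
             matrix(v[pidx$xy], nrow(pidx$xy)))
  res <- describe_planes(P, pidx$counts, 1L, bank, bins)
  structure(
    list(vector = as.vector(res$descriptors),
         raw_fG = as.vector(res$raw_fG),
         raw_fRA = as.vector(res$raw_fRA),
         plane_counts = pidx$counts),
    class = "srp_patch_descriptor"
  )
}

#' Tile a volume into cubic patches
#'
#' Non-overlapping tiling by default (stride = patch side); incomplete
#' border tiles are discarded and the patch depth is clamped to the volume
#' depth.
#'
#' @param volume 3D numeric array.
#' @param patch_side Lateral patch side (default 5).
#' @param depth Patch depth (default 5; clamped to the volume z-extent).
#' @param stride Lateral and axial tiling stride (default `patch_side`).
#' @return List of patches, each a list with `values` (3D array) and
#'   `origin` (0-based voxel coordinate of the patch corner).
#' @export
tile_volume <- function(volume, patch_side = 5L, depth = 5L, stride = patch_side) {
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    stop_srp("volume must be a 3D array")
  }
  d <- dim(volume)
  depth <- min(depth, d[3L])
  if (d[1L] < patch_side || d[2L] < patch_side || d[3L] < depth) {
    warning("volume smaller than one patch; returning empty tiling")
    return(list())
  }
  xs <- seq(1L, d[1L] - patch_side + 1L, by = stride)
  ys <- seq(1L, d[2L] - patch_side + 1L, by = stride)
  zs <- seq(1L, d[3L] - depth + 1L, by = depth)
  out <- vector("list", length(xs) * length(ys) * length(zs))
  i <- 0L
  for (z0 in zs) for (y0 in ys) for (x0 in xs) {
    i <- i + 1L
    out[[i]] <- list(
      values = volume[x0:(x0 + patch_side - 1L),
                      y0:(y0 + patch_side - 1L),
                      z0:(z0 + depth - 1L), drop = FALSE],
      origin = c(x0 - 1L, y0 - 1L, z0 - 1L)
    )
  }
  out
}

#' 3D SRP description of a whole volume
#'
#' Tiles the volume into cubic patches and computes the per-patch SRP
#' descriptor. In `"3d"` mode every patch yields a 240-dimensional
#' descriptor built from the yz, xz and xy plane families; in `"pseudo3d"`
#' mode only the axial (xy) slice sequence is used, yielding
#' 80-dimensional descriptors and ignoring interslice correlations.
#'
#' @param volume 3D numeric array (finite, non-negative).
#' @param bank An `srp_rp_bank` for n = 2.
#' @param mode `"3d"` or `"pseudo3d"`.
#' @param patch_side,depth,stride Tiling parameters (see [tile_volume()]).
#' @param bins Histogram bins per function (default 16).
#' @return Object of class `srp_descriptor_set`: list with `descriptors`
#'   (matrix, one row per patch), `origins`, `raw_fG`, `raw_fRA`
#'   (matrices, one row per patch), `mode`, `bank_seed`, `n`, `depth`,
#'   `stride`, `volume_dim`.
#' @export
describe_volume <- function(volume, bank, mode = c("3d", "pseudo3d"),
                            patch_side = 5L, depth = 5L, stride = patch_side,
                            bins = 16L) {
  mode <- match.arg(mode)
  if (!inherits(bank, "srp_rp_bank")) stop_srp("`bank` must be an srp_rp_bank")
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop_srp("volume intensities must be finite and non-negative")
  }
  tiles <- tile_volume(volume, patch_side, depth, stride)
  npatch <- length(tiles)
  if (npatch == 0L) {
    return(structure(list(descriptors = matrix(0, 0L, 0L),
                          origins = matrix(0L, 0L, 3L),
                          raw_fG = matrix(0, 0L, 0L),
                          raw_fRA = matrix(0, 0L, 0L),
                          mode = mode, bank_seed = bank$seed, n = bank$n,
                          depth = depth, stride = stride,
                          volume_dim = dim(volume)),
                     class = "srp_descriptor_set"))
  }
  z <- dim(tiles[[1L]]$values)[3L]
  if (z == 1L) {
    # 2D applicability: a single-slice volume has no hyperplanes; both
    # modes reduce to the axial slice sequence with one plane per patch.
    lat <- 0:(patch_side - 1L)
    idx <- matrix(lat + patch_side * rep(lat, each = patch_side) + 1L, nrow = 1L)
    counts <- c(xy = 1L)
  } else {
    pidx <- plane_indices(z)
    idx <- switch(mode,
                  "3d" = rbind(pidx$yz, pidx$xz, pidx$xy),
                  "pseudo3d" = pidx$xy)
    counts <- switch(mode, "3d" = pidx$counts, "pseudo3d" = c(xy = nrow(pidx$xy)))
  }
  npl <- nrow(idx)
  P <- matrix(0, nrow = npatch * npl, ncol = 25L)
  for (p in seq_len(npatch)) {
    v <- as.vector(tiles[[p]]$values)
    P[(p - 1L) * npl + seq_len(npl), ] <- matrix(v[idx], npl)
  }
  res <- describe_planes(P, counts, npatch, bank, bins)
  structure(
    list(descriptors = res$descriptors,
         origins = do.call(rbind, lapply(tiles, `[[`, "origin")),
         raw_fG = res$raw_fG,
         raw_fRA = res$raw_fRA,
         mode = mode, bank_seed = bank$seed, n = bank$n,
         depth = depth, stride = stride, volume_dim = dim(volume)),
    class = "srp_descriptor_set"
  )
}

#' @export
print.srp_descriptor_set <- function(x, ...) {
  cat(sprintf("SRP descriptor set: %d patches x %d dims (%s mode), volume %s\n",
              nrow(x$descriptors), ncol(x$descriptors), x$mode,
              paste(x$volume_dim, collapse = "x")))
  invisible(x)
}
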