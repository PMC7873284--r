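test_that("bresenham3d rasterizes axis, diagonal and oblique lines", {
  expect_identical(bresenham3d(c(0, 0, 0), c(0, 0, 4)),
                   cbind(0L, 0L, 0:4))
  expect_identical(bresenham3d(c(0, 0, 0), c(4, 4, 4)),
                   cbind(0:4, 0:4, 0:4))
  p <- bresenham3d(c(0, 0, 0), c(4, 1, 2))
  expect_identical(nrow(p), 5L)
  expect_identical(p, oracle_line(c(0, 0, 0), c(4, 1, 2)))
  set.seed(201)
  for (case in 1:50) {
    a <- sample(-6:6, 3, replace = TRUE)
    b <- sample(-6:6, 3, replace = TRUE)
    path <- bresenham3d(a, b)
    expect_identical(path, oracle_line(a, b))
    expect_identical(path, bresenham3d(b, a)[nrow(path):1, , drop = FALSE])
    expect_identical(nrow(path), max(abs(b - a)) + 1L)
    expect_true(all(abs(diff(path)) <= 1L)) # 26-connected
  }
})

test_that("build_hyperplanes enumerates the column pairings", {
  set.seed(202)
  patch <- array(stats::runif(125), c(5, 5, 5))
  yz <- build_hyperplanes(patch, "yz")
  xz <- build_hyperplanes(patch, "xz")
  xy <- build_hyperplanes(patch, "xy")
  expect_length(yz, 25L)
  expect_length(xz, 25L)
  expect_length(xy, 5L)
  expect_true(all(vapply(c(yz, xz, xy), function(m) identical(dim(m), c(5L, 5L)), TRUE)))
  # vertical plane (i = j = 0) of the yz family is the x = 0 wall
  expect_equal(yz[[1L]], patch[1, , ])
  # xy planes are the axial slices
  for (s in 1:5) expect_equal(xy[[s]], patch[, , s])
  const <- build_hyperplanes(array(3, c(5, 5, 5)), "yz")
  expect_true(all(vapply(const, function(m) all(m == 3), TRUE)))
  expect_error(build_hyperplanes(array(1, c(7, 7, 5)), "yz"), "side must be 5")
})

test_that("describe_patch produces the 240-dim descriptor with unit histograms", {
  set.seed(203)
  bank <- make_rp_bank(2, seed = 42)
  patch <- array(stats::runif(125, 0, 300), c(5, 5, 5))
  d <- describe_patch(patch, bank)
  expect_length(d$vector, 240L)
  expect_length(d$raw_fG, 55L * 10L)
  expect_length(d$raw_fRA, 55L * 20L)
  sums <- colSums(matrix(d$vector, nrow = 16L))
  expect_equal(sums, rep(1, 15), tolerance = 1e-9)
  expect_true(all(d$vector >= 0))
  # constant patch: the difference-function (A, R) blocks have zero range
  # and collapse into a single bin; every block still sums to one
  dc <- describe_patch(array(4, c(5, 5, 5)), bank)
  blocks <- matrix(dc$vector, nrow = 16L)
  diff_blocks <- as.vector(outer(4:5, c(0, 5, 10), `+`)) # A, R per family
  expect_true(all(blocks[1L, diff_blocks] == 1))
  expect_true(all(blocks[-1L, diff_blocks] == 0))
  expect_equal(colSums(blocks), rep(1, 15), tolerance = 1e-9)
})

test_that("tile_volume arithmetic matches the non-overlapping contract", {
  vol <- array(stats::runif(64 * 64 * 15), c(64, 64, 15))
  tiles <- tile_volume(vol)
  expect_length(tiles, 12L * 12L * 3L)
  expect_length(tile_volume(array(1, c(5, 5, 5))), 1L)
  shallow <- tile_volume(array(1, c(64, 64, 4)))
  expect_identical(dim(shallow[[1]]$values)[3L], 4L)
  expect_warning(empty <- tile_volume(array(1, c(3, 3, 3))), "smaller")
  expect_length(empty, 0L)
})

test_that("describe_volume dimensions, determinism and pseudo-3D mode", {
  set.seed(204)
  bank <- make_rp_bank(2, seed = 42)
  vol <- array(stats::runif(10 * 10 * 5, 0, 50), c(10, 10, 5))
  d3 <- describe_volume(vol, bank, mode = "3d")
  expect_identical(dim(d3$descriptors), c(4L, 240L))
  dp <- describe_volume(vol, bank, mode = "pseudo3d")
  expect_identical(dim(dp$descriptors), c(4L, 80L))
  expect_identical(dim(dp$raw_fG), c(4L, 50L))
  d3b <- describe_volume(vol, bank, mode = "3d")
  expect_identical(d3, d3b)
  # shallow volume: xy family uses all 4 slices -> 25+25+4 planes
  d4 <- describe_volume(array(stats::runif(5 * 5 * 4), c(5, 5, 4)), bank)
  expect_identical(ncol(d4$raw_fG), 54L * 10L)
  # single-slice volume falls back to the 2D axial sequence
  d1 <- describe_volume(array(stats::runif(25), c(5, 5, 1)), bank)
  expect_identical(dim(d1$descriptors), c(1L, 80L))
})

test_that("axial flip permutes pairings leaving pooled f_G/f_S/f_C/f_R unchanged", {
  set.seed(205)
  bank <- make_rp_bank(2, seed = 42)
  patch <- array(stats::runif(125, 0, 10), c(5, 5, 5))
  flipped <- patch[, , 5:1]
  pooled <- function(p, orientation) {
    planes <- build_hyperplanes(p, orientation)
    fs <- lapply(planes, function(pl) project(extract_patterns(pl), bank))
    lapply(c("f_G", "f_S", "f_C", "f_R"), function(nm) {
      sort(unlist(lapply(fs, `[[`, nm)))
    })
  }
  for (orient in c("yz", "xz", "xy")) {
    a <- pooled(patch, orient)
    b <- pooled(flipped, orient)
    for (i in seq_along(a)) expect_equal(a[[i]], b[[i]], tolerance = 1e-9)
  }
  # and hence the non-angular histogram blocks of the descriptor agree
  da <- describe_patch(patch, bank)$vector
  db <- describe_patch(flipped, bank)$vector
  keep <- rep(rep(c(TRUE, FALSE, TRUE), times = c(48, 16, 16)), 3) # drop A blocks
  expect_equal(da[keep], db[keep], tolerance = 1e-9)
})

test_that("descriptors separate smooth from speckled textures", {
  set.seed(206)
  bank <- make_rp_bank(2, seed = 1)
  smooth <- array(50, c(10, 10, 5)) + array(stats::runif(500), c(10, 10, 5))
  speck <- smooth
  idx <- sample(500, 40)
  speck[idx] <- speck[idx] * 4
  ds <- describe_volume(smooth, bank)
  dk <- describe_volume(speck, bank)
  diff_cols <- as.vector(vapply(0:2, function(o) 80 * o + 49:80, numeric(32)))
  expect_gt(sqrt(sum((ds$descriptors[, diff_cols] - dk$descriptors[, diff_cols])^2)), 0)
})
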