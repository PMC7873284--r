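test_that("elbow selection finds the true cluster count", {
  set.seed(301)
  # 64 well-separated clusters on an 8x8 grid
  centers <- as.matrix(expand.grid(x = 1:8, y = 1:8))
  x64 <- blob_data(centers, per = 10L, sd = 0.01)
  sel <- select_k_elbow(x64, seed = 1)
  expect_identical(sel$k, 64L)
  # 2 clusters at small scale
  x2 <- blob_data(matrix(c(0, 0, 10, 10), 2, byrow = TRUE), per = 20L, sd = 0.1)
  expect_identical(select_k_elbow(x2, candidates = c(2L, 4L, 8L), seed = 1)$k, 2L)
  # degenerate repeated descriptor: SSE = 0 everywhere -> smallest candidate
  xd <- matrix(1, nrow = 50, ncol = 3)
  expect_identical(select_k_elbow(xd, candidates = c(2L, 4L, 8L), seed = 1)$k, 2L)
  # too-large candidates are skipped with a warning
  expect_warning(s2 <- select_k_elbow(x2, candidates = c(2L, 4L, 1000L), seed = 1),
                 "skipping")
  expect_identical(s2$k, 2L)
})

test_that("build_codebook recovers structure and is deterministic", {
  set.seed(302)
  pts <- matrix(stats::runif(5 * 3, 0, 10), 5, 3)
  cb <- build_codebook(pts, k = 5, seed = 2)
  expect_equal(cb$inertia, 0, tolerance = 1e-10)
  expect_equal(cb$centroids[order(cb$centroids[, 1]), ],
               pts[order(pts[, 1]), ], ignore_attr = TRUE)
  expect_identical(build_codebook(pts, k = 5, seed = 2),
                   build_codebook(pts, k = 5, seed = 2))
  expect_error(build_codebook(pts, k = 6, seed = 1), "at least k")
  # 2 Gaussian blobs: centroids within 3 standard errors of the blob means
  mu <- matrix(c(0, 0, 5, 5), 2, byrow = TRUE)
  xb <- blob_data(mu, per = 200L, sd = 1)
  cb2 <- build_codebook(xb, k = 2, seed = 3)
  cen <- cb2$centroids[order(cb2$centroids[, 1]), ]
  expect_true(all(abs(cen - mu) < 3 / sqrt(200)))
})

test_that("BOVW encoding counts hard assignments", {
  set.seed(303)
  cb <- build_codebook(matrix(stats::rnorm(64 * 240), 64), k = 64, seed = 1,
                       nstart = 1L)
  x <- matrix(stats::rnorm(7 * 240), 7)
  enc <- encode_bovw(x, cb)
  expect_length(enc$vector, 64L)
  expect_identical(sum(enc$vector), 7L)
  expect_true(all(enc$vector >= 0))
  # all patches exactly at centroid 3
  x3 <- matrix(rep(cb$centroids[3L, ], 5), 5, byrow = TRUE)
  enc3 <- encode_bovw(x3, cb)
  expect_identical(enc3$vector[3L], 5L)
  expect_identical(sum(enc3$vector), 5L)
  # permutation invariance
  xs <- x[sample(nrow(x)), ]
  expect_identical(encode_bovw(xs, cb)$vector, enc$vector)
  expect_error(encode_bovw(matrix(0, 2, 10), cb), "dimension")
})

test_that("Fisher vectors have dimension 2GD and vanish at component means", {
  gmm_toy <- structure(
    list(weights = c(0.5, 0.5),
         means = matrix(c(0, 0, 0, 5, 5, 5), 2, byrow = TRUE),
         variances = matrix(1, 2, 3), G = 2L, D = 3L),
    class = "srp_gmm")
  set.seed(304)
  x <- matrix(stats::rnorm(20 * 3), 20)
  expect_length(encode_fv(x, gmm_toy)$vector, 12L)
  big <- structure(
    list(weights = rep(1 / 64, 64),
         means = matrix(stats::rnorm(64 * 512), 64),
         variances = matrix(1, 64, 512), G = 64L, D = 512L),
    class = "srp_gmm")
  expect_length(encode_fv(matrix(stats::rnorm(5 * 512), 5), big)$vector, 65536L)
  # all features at a component mean: its mean-gradient block is zero
  at_mean <- matrix(rep(gmm_toy$means[1L, ], 10), 10, byrow = TRUE)
  fv <- encode_fv(at_mean, gmm_toy, normalize = FALSE)$vector
  expect_equal(fv[1:3], rep(0, 3), tolerance = 1e-12)
  expect_error(encode_fv(matrix(0, 2, 5), gmm_toy), "dimension")
})

test_that("fit_gmm recovers well-separated mixture parameters", {
  set.seed(305)
  mu <- matrix(c(0, 0, 8, 8), 2, byrow = TRUE)
  x <- blob_data(mu, per = 300L, sd = 1)
  g <- fit_gmm(x, G = 2, seed = 1)
  expect_equal(sum(g$weights), 1, tolerance = 1e-9)
  expect_true(all(g$variances > 0))
  m <- g$means[order(g$means[, 1]), ]
  expect_true(all(abs(m - mu) < 0.2))
  expect_equal(as.vector(g$weights), c(0.5, 0.5), tolerance = 0.05)
})
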