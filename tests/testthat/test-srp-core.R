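test_that("rp_output_dim follows the 10*(n-1) rule and rejects bad n", {
  expect_identical(rp_output_dim(2), 10L)
  expect_identical(rp_output_dim(3), 20L)
  expect_identical(rp_output_dim(5), 40L)
  expect_error(rp_output_dim(1), "integer >= 2")
  expect_error(rp_output_dim(2.5), "integer >= 2")
})

test_that("extract_patterns validates input and handles constant patches", {
  expect_error(extract_patterns(matrix(1, 4, 4)), "odd")
  expect_error(extract_patterns(matrix(1, 3, 5)), "square")
  expect_error(extract_patterns(matrix(-1, 5, 5)), "non-negative")
  pat <- extract_patterns(matrix(7, 5, 5))
  expect_identical(pat$glob, rep(7, 25))
  expect_true(all(pat$ang == 0))
  expect_true(all(pat$rad == 0))
  expect_equal(length(pat$sqr), 25L)
  expect_equal(length(pat$circ), 25L)
  expect_equal(length(pat$ang), 24L)
})

test_that("patterns match brute-force ring enumeration on random patches", {
  set.seed(101)
  for (case in 1:100) {
    p <- if (case == 1L) matrix(sample(0:24), 5, 5) else rand_patch()
    pat <- extract_patterns(p)
    orc <- oracle_ring_patterns(p)
    expect_identical(pat$glob, orc$glob)
    expect_identical(pat$sqr, orc$sqr)
  }
  # larger patch size exercises the general-n ring bookkeeping
  p7 <- rand_patch(7L)
  pat7 <- extract_patterns(p7)
  orc7 <- oracle_ring_patterns(p7)
  expect_identical(pat7$sqr, orc7$sqr)
  expect_equal(length(pat7$circ), 1L + 4L * 3L * 4L)
})

test_that("circular/angular/radial patterns match a naive sampling oracle", {
  set.seed(102)
  for (case in 1:25) {
    p <- rand_patch()
    pat <- extract_patterns(p)
    orc <- oracle_circle_patterns(p)
    expect_equal(pat$circ, orc$circ, tolerance = 1e-9)
    expect_equal(pat$ang, orc$ang, tolerance = 1e-9)
    expect_equal(pat$rad, orc$rad, tolerance = 1e-9)
  }
})

test_that("make_rp_bank is deterministic, well-shaped and unbiased", {
  b1 <- make_rp_bank(2, seed = 0)
  b2 <- make_rp_bank(2, seed = 0)
  expect_identical(b1, b2)
  expect_identical(dim(b1$rp$S), c(10L, 25L))
  expect_identical(dim(b1$rp$A), c(10L, 24L))
  expect_true(all(vapply(b1$rp, function(m) all(m %in% c(-1, 1)), TRUE)))
  big <- make_rp_bank(5, seed = 1) # a = 40, widths up to 121
  entries <- unlist(big$rp)
  expect_lt(abs(mean(entries)), 3 / sqrt(length(entries)))
})

test_that("project is the literal linear map and checks dimensions", {
  pat <- list(glob = rep(0, 25), sqr = rep(0, 25), circ = rep(0, 25),
              ang = rep(0, 24), rad = rep(0, 24))
  bank <- make_rp_bank(2, seed = 5)
  f0 <- project(pat, bank)
  expect_true(all(unlist(f0) == 0))
  expect_true(all(lengths(f0) == 10L))
  # hand example: 1x2 RP [+1, -1], pattern [3, 1] -> 2
  toy_bank <- bank
  toy_bank$rp <- lapply(toy_bank$rp, function(m) matrix(c(1, -1), 1, 2))
  toy_pat <- lapply(pat, function(x) c(3, 1))
  expect_equal(unname(unlist(project(toy_pat, toy_bank))), rep(2, 5))
  expect_error(project(list(glob = 1:3, sqr = 1:25, circ = 1:25,
                            ang = 1:24, rad = 1:24), bank),
               "dimension mismatch")
  set.seed(103)
  for (case in 1:20) {
    p <- rand_patch()
    pat <- extract_patterns(p)
    f <- project(pat, bank)
    expect_equal(f$f_S, oracle_matvec(bank$rp$S, pat$sqr), tolerance = 1e-12)
    expect_equal(f$f_A, oracle_matvec(bank$rp$A, pat$ang), tolerance = 1e-12)
  }
})

test_that("f_G, f_S, f_C are exactly rotation invariant; f_A/f_R shift-invariant", {
  set.seed(104)
  bank <- make_rp_bank(2, seed = 9)
  for (case in 1:20) {
    p <- rand_patch()
    f <- project(extract_patterns(p), bank)
    q <- p
    for (rot in 1:3) {
      q <- rot90m(q)
      fr <- project(extract_patterns(q), bank)
      expect_identical(fr$f_G, f$f_G)
      expect_identical(fr$f_S, f$f_S)
      expect_identical(fr$f_C, f$f_C)
    }
    fs <- project(extract_patterns(p + 13.7), bank)
    expect_equal(fs$f_A, f$f_A, tolerance = 1e-9)
    expect_equal(fs$f_R, f$f_R, tolerance = 1e-9)
  }
})

test_that("random projection preserves pairwise distance ranking", {
  set.seed(105)
  bank <- make_rp_bank(2, seed = 11)
  m <- 220L
  d_orig <- numeric(m)
  d_proj <- numeric(m)
  for (i in seq_len(m)) {
    scale <- 10^stats::runif(1, -1, 2)
    x <- stats::runif(25) * scale
    y <- stats::runif(25) * 10^stats::runif(1, -1, 2)
    d_orig[i] <- sqrt(sum((x - y)^2))
    px <- as.vector(bank$rp$G %*% x)
    py <- as.vector(bank$rp$G %*% y)
    d_proj[i] <- sqrt(sum((px - py)^2))
  }
  expect_gt(stats::cor(d_orig, d_proj, method = "spearman"), 0.8)
})
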