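test_that("group_kfold_split keeps groups intact and balanced", {
  g20 <- rep(paste0("img", 1:20), each = 3)
  f <- group_kfold_split(g20, k = 10, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  tab <- table(g20, f)
  expect_true(all(rowSums(tab > 0) == 1L)) # no group spans two folds
  expect_true(all(table(f) == 6L))         # 2 groups of 3 cells per fold
  g10 <- rep(letters[1:10], times = c(1:10))
  f10 <- group_kfold_split(g10, k = 10, seed = 2)
  expect_true(all(rowSums(table(g10, f10) > 0) == 1L))
  expect_identical(length(unique(f10)), 10L)
  expect_error(group_kfold_split(rep("a", 30), k = 10), "distinct groups")
})

test_that("tune_gamma implements the median pairwise-distance heuristic", {
  two <- rbind(c(0, 0), c(2, 0))
  expect_equal(tune_gamma(two, seed = 1), 0.25)
  set.seed(501)
  x <- matrix(stats::rnorm(60 * 5), 60)
  g1 <- tune_gamma(x, seed = 3)
  gd <- tune_gamma(rbind(x, x), n_samples = 120L, seed = 3)
  expect_equal(gd / g1, 1, tolerance = 0.25) # robust to duplication
  # standard-normal cloud, D = 10: gamma ~ 1/(2D) within a factor of 2
  xn <- matrix(stats::rnorm(100 * 10), 100)
  gn <- tune_gamma(xn, seed = 4)
  expect_gt(gn, 1 / (4 * 10))
  expect_lt(gn, 2 / (2 * 10))
  expect_warning(gc0 <- tune_gamma(matrix(1, 5, 4), seed = 1), "identical")
  expect_equal(gc0, 0.25)
})

test_that("svm_rbf separates separable data and its AUC machinery is sane", {
  set.seed(502)
  x <- rbind(matrix(stats::rnorm(40, mean = 0), 20),
             matrix(stats::rnorm(40, mean = 6), 20))
  y <- rep(c("neg", "pos"), each = 20)
  fit <- svm_rbf(x, y, gamma = 0.5)
  dv <- predict(fit, x)
  expect_true(all((dv >= 0) == (y == "pos")))
  expect_identical(as.character(predict(fit, x, type = "class")),
                   y)
  # AUC of a constant scorer is 0.5 by the rank definition
  expect_equal(srp3d:::auc_score(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("run_cv is deterministic, leak-free and calibrated on null data", {
  set.seed(503)
  n_img <- 20L
  x <- rbind(matrix(stats::rnorm(10 * 5), 10) + 4,
             matrix(stats::rnorm(10 * 5), 10))
  labels <- rep(c("pos", "neg"), each = 10)
  groups <- paste0("img", 1:20)
  rep1 <- run_cv(x, labels, groups, seed = 9, k = 10, pos_label = "pos")
  rep2 <- run_cv(x, labels, groups, seed = 9, k = 10, pos_label = "pos")
  expect_identical(rep1, rep2)
  expect_equal(unname(rep1$mean["auc"]), 1)
  expect_equal(unname(rep1$mean["f1"]), 1)
  expect_true(all(rep1$per_fold$auc >= 0 & rep1$per_fold$auc <= 1, na.rm = TRUE))
  # grouped integrity on every run
  expect_true(all(rowSums(table(groups, rep1$folds) > 0) == 1L))
  # permuted labels: mean AUC near chance
  xr <- matrix(stats::rnorm(60 * 8), 60)
  gr <- rep(paste0("i", 1:20), each = 3)
  lab <- rep(rep(c("a", "b"), 10), each = 3)
  perm <- with(list(), {set.seed(7); sample(20)})
  lab_perm <- rep(rep(c("a", "b"), 10)[perm], each = 3)
  repn <- run_cv(xr, lab_perm, gr, seed = 5, k = 10)
  expect_gt(unname(repn$mean["auc"]), 0.35)
  expect_lt(unname(repn$mean["auc"]), 0.65)
})

test_that("per-fold codebook fitting differs from a leaky global codebook", {
  set.seed(504)
  n_img <- 12L
  centers <- matrix(stats::runif(n_img * 4, 0, 20), n_img)
  sets <- lapply(seq_len(n_img), function(i) {
    sweep(matrix(stats::rnorm(10 * 4, sd = 0.5), 10), 2L, centers[i, ], `+`)
  })
  labels <- rep(c("a", "b"), 6)
  groups <- paste0("img", seq_len(n_img))
  proper <- run_cv(sets, labels, groups, seed = 3, k = 6,
                   encode = list(method = "bovw", k = 3, nstart = 1L))
  cb_all <- build_codebook(do.call(rbind, sets), k = 3, seed = 3, nstart = 1L)
  enc_all <- t(vapply(sets, function(s) as.numeric(encode_bovw(s, cb_all)$vector),
                      numeric(3)))
  leaky <- run_cv(enc_all, labels, groups, seed = 3, k = 6)
  expect_false(isTRUE(all.equal(proper$roc$decision, leaky$roc$decision)))
})

test_that("kruskal_wallis_compare matches hand H and handles degenerate input", {
  same <- kruskal_wallis_compare(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                      c = c(1, 2, 3)))
  expect_false(same$reject)
  sep <- kruskal_wallis_compare(list(a = stats::rnorm(10),
                                     b = stats::rnorm(10) + 100))
  expect_true(sep$reject)
  tied <- kruskal_wallis_compare(list(a = rep(1, 5), b = rep(1, 5)))
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis_compare(list(a = 1:3)), "two methods")
  set.seed(505)
  samples <- list(a = stats::rnorm(10), b = stats::rnorm(10) + 0.6,
                  c = stats::rnorm(10))
  ours <- kruskal_wallis_compare(samples)
  expect_equal(ours$reject, oracle_kw_reject(samples))
  expect_length(ours$mean_ranks, 3L)
})

test_that("pseudo_vs_3d_ttest decides the third-plane hypothesis", {
  same <- pseudo_vs_3d_ttest(rep(0.9, 10), rep(0.9, 10))
  expect_equal(same$p_value, 1)
  expect_false(same$reject)
  set.seed(506)
  big <- pseudo_vs_3d_ttest(stats::rnorm(10, 0.99, 0.02),
                            stats::rnorm(10, 0.80, 0.02))
  expect_true(big$reject)
  expect_error(pseudo_vs_3d_ttest(1:5, 1:4), "equal length")
})
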