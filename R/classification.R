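# SVM-RBF phenotype classification under grouped 10-fold cross-validation,
# plus the statistical model comparisons.

#' Grouped k-fold split at the image level
#'
#' Assigns whole groups (3D images) to folds so that no group spans two
#' folds. Groups are shuffled (seeded) and then assigned greedily, largest
#' first, to the currently smallest fold, approximately balancing cell
#' counts.
#'
#' @param groups Vector of group ids, one per cell/row.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold assignments (1..k), one per row.
#' @export
group_kfold_split <- function(groups, k = 10L, seed = 42L) {
  ids <- unique(groups)
  if (length(ids) < k) {
    stop_srp(sprintf("need at least k = %d distinct groups, got %d", k, length(ids)))
  }
  sizes <- as.vector(table(factor(groups, levels = ids)))
  ord <- with_seed(seed, sample.int(length(ids)))
  ids <- ids[ord]
  sizes <- sizes[ord]
  ord2 <- order(-sizes)
  ids <- ids[ord2]
  sizes <- sizes[ord2]
  fold_of <- integer(length(ids))
  load <- numeric(k)
  for (i in seq_along(ids)) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  fold_of[match(groups, ids)]
}

#' RBF-kernel gamma by the median pairwise-distance heuristic
#'
#' Samples up to `n_samples` rows (seeded, without replacement) and sets
#' `gamma = 1 / median(pairwise squared Euclidean distances)`. If all
#' sampled points coincide, falls back to `1 / D` with a warning.
#'
#' @param train_features Numeric matrix, one row per sample.
#' @param n_samples Number of rows used by the heuristic (default 100).
#' @param seed RNG seed.
#' @return Positive scalar gamma.
#' @export
tune_gamma <- function(train_features, n_samples = 100L, seed = 42L) {
  x <- as.matrix(train_features)
  if (nrow(x) == 0L) stop_srp("training set is empty")
  m <- min(n_samples, nrow(x))
  idx <- with_seed(seed, sample.int(nrow(x), m))
  xs <- x[idx, , drop = FALSE]
  if (m < 2L) {
    warning("fewer than two samples; falling back to gamma = 1/D")
    return(1 / ncol(x))
  }
  d2 <- as.vector(stats::dist(xs))^2
  med <- stats::median(d2)
  if (!is.finite(med) || med <= 0) {
    warning("sampled points are identical; falling back to gamma = 1/D")
    return(1 / ncol(x))
  }
  1 / med
}

rbf_kernel <- function(x, y, gamma) {
  # ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * x %*% t(y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a C-SVM with RBF kernel
#'
#' Solves the C-SVM dual by coordinate descent on the bias-augmented
#' kernel (K + 1), the standard regularized-bias formulation; default
#' regularization constant C = 1. Exposed so the classifier can be used
#' outside the cross-validation driver.
#'
#' @param x Numeric feature matrix.
#' @param y Labels coercible to two classes; the positive class is
#'   `pos_label` (default: last level).
#' @param gamma RBF kernel width (default: median heuristic on `x`).
#' @param C Regularization constant (default 1).
#' @param pos_label Positive class label.
#' @param max_passes,tol Optimizer controls.
#' @return Object of class `srp_svm` with `alpha`, `sv_x`, `sv_y`,
#'   `gamma`, `C`, `levels`, `pos_label`.
#' @export
svm_rbf <- function(x, y, gamma = NULL, C = 1, pos_label = NULL,
                    max_passes = 200L, tol = 1e-6) {
  x <- as.matrix(x)
  yf <- factor(y)
  if (nlevels(yf) != 2L) stop_srp("svm_rbf requires exactly two classes")
  if (is.null(pos_label)) pos_label <- levels(yf)[2L]
  ys <- ifelse(yf == pos_label, 1, -1)
  if (is.null(gamma)) gamma <- tune_gamma(x, seed = 0L)
  K <- rbf_kernel(x, x, gamma) + 1 # +1 absorbs the bias
  n <- nrow(x)
  alpha <- numeric(n)
  f <- numeric(n) # f_i = sum_j alpha_j y_j K_ij
  diagK <- diag(K)
  for (pass in seq_len(max_passes)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      g <- 1 - ys[i] * f[i]
      step <- g / diagK[i]
      new_a <- min(max(alpha[i] + step, 0), C)
      d <- new_a - alpha[i]
      if (d != 0) {
        alpha[i] <- new_a
        f <- f + d * ys[i] * K[, i]
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  keep <- alpha > 0
  structure(list(alpha = alpha[keep], sv_x = x[keep, , drop = FALSE],
                 sv_y = ys[keep], gamma = gamma, C = C,
                 levels = levels(yf), pos_label = pos_label),
            class = "srp_svm")
}

#' @export
predict.srp_svm <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(object$sv_x) == 0L) {
    dv <- rep(0, nrow(newdata))
  } else {
    K <- rbf_kernel(newdata, object$sv_x, object$gamma) + 1
    dv <- as.vector(K %*% (object$alpha * object$sv_y))
  }
  if (type == "decision") return(dv)
  neg <- setdiff(object$levels, object$pos_label)
  factor(ifelse(dv >= 0, object$pos_label, neg), levels = object$levels)
}

# Standardize columns with train statistics; zero-sd columns pass through.
fold_scaler <- function(train) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  function(x) sweep(sweep(x, 2L, mu), 2L, sd, `/`)
}

classification_metrics <- function(dv, truth_pos) {
  pred_pos <- dv >= 0
  tp <- sum(pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(auc = auc_score(dv, truth_pos), f1 = f1, precision = precision, recall = recall)
}

#' Grouped 10-fold cross-validation of the SVM-RBF classifier
#'
#' Splits at the image (group) level, and within every fold fits all
#' data-dependent artifacts strictly on the outer training set: the BOVW
#' codebook (when encoding from per-image descriptor sets), the feature
#' standardizer and the RBF gamma (median heuristic on 100 sampled training
#' rows). Reports per-fold and mean +/- sd AUC, F1, precision and recall,
#' with the SVM decision values feeding the ROC/AUC.
#'
#' @param x Either a numeric feature matrix (one encoded row per cell) or
#'   a list of per-image descriptor matrices / `srp_descriptor_set`s to be
#'   encoded per fold.
#' @param labels Two-class labels, one per row of `x` (or per list element).
#' @param groups Group (source image) ids, same length.
#' @param seed Master seed (folds, codebooks, gamma sampling).
#' @param k Number of folds (default 10).
#' @param encode `NULL` for precomputed features, or a list
#'   `list(method = "bovw", k = 32, subsample = 5000)` describing the
#'   per-fold encoding.
#' @param C SVM regularization constant (default 1).
#' @param pos_label Positive class (default: last factor level).
#' @param standardize Standardize features per fold (default TRUE).
#' @return Object of class `srp_cv_report`: list with `per_fold` (data
#'   frame), `mean`, `sd`, `folds` (assignments), `roc` (per-fold decision
#'   values and truth), `config`.
#' @export
run_cv <- function(x, labels, groups, seed = 42L, k = 10L, encode = NULL,
                   C = 1, pos_label = NULL, standardize = TRUE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop_srp("exactly two classes are required")
  if (is.null(pos_label)) pos_label <- levels(labels)[2L]
  from_descriptors <- is.list(x) && !is.data.frame(x) && !is.matrix(x)
  n_obj <- if (from_descriptors) length(x) else nrow(x)
  if (length(labels) != n_obj || length(groups) != n_obj) {
    stop_srp("labels and groups must match the number of rows/images")
  }
  folds <- group_kfold_split(groups, k = k, seed = seed)
  seeds <- derive_seeds(seed, 2L * k)
  metric_names <- c("auc", "f1", "precision", "recall")
  per_fold <- matrix(NA_real_, nrow = k, ncol = length(metric_names),
                     dimnames = list(NULL, metric_names))
  roc <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (length(unique(labels[tr])) < 2L) {
      warning(sprintf("fold %d: training data single-class; fold skipped", f))
      next
    }
    if (from_descriptors) {
      feats <- encode_fold(x, tr, encode, seeds[f])
    } else {
      feats <- as.matrix(x)
    }
    xtr <- feats[tr, , drop = FALSE]
    xte <- feats[te, , drop = FALSE]
    if (standardize) {
      scaler <- fold_scaler(xtr)
      xtr <- scaler(xtr)
      xte <- scaler(xte)
    }
    gamma <- tune_gamma(xtr, n_samples = 100L, seed = seeds[k + f])
    fit <- svm_rbf(xtr, labels[tr], gamma = gamma, C = C, pos_label = pos_label)
    dv <- predict(fit, xte)
    truth_pos <- labels[te] == pos_label
    if (length(unique(truth_pos)) < 2L) {
      warning(sprintf("fold %d: held-out data single-class; fold skipped", f))
      next
    }
    per_fold[f, ] <- classification_metrics(dv, truth_pos)
    roc[[f]] <- data.frame(fold = f, decision = dv, positive = truth_pos)
  }
  ok <- stats::complete.cases(per_fold)
  structure(
    list(per_fold = data.frame(fold = seq_len(k), per_fold),
         mean = colMeans(per_fold[ok, , drop = FALSE]),
         sd = apply(per_fold[ok, , drop = FALSE], 2L, stats::sd),
         folds = folds,
         roc = do.call(rbind, roc[ok]),
         config = list(seed = seed, k = k, C = C, encode = encode,
                       pos_label = pos_label, standardize = standardize)),
    class = "srp_cv_report"
  )
}

# Fit the encoding artifacts on the training images only, then encode all.
encode_fold <- function(sets, train_mask, encode, seed) {
  if (is.null(encode)) encode <- list(method = "bovw", k = 32L)
  method <- match.arg(encode$method, c("bovw", "fv"))
  rows <- lapply(sets, descriptor_rows)
  train_desc <- do.call(rbind, rows[train_mask])
  sub <- encode$subsample %||% 5000L
  if (nrow(train_desc) > sub) {
    keep <- with_seed(seed, sample.int(nrow(train_desc), sub))
    train_desc <- train_desc[keep, , drop = FALSE]
  }
  if (method == "bovw") {
    cb <- build_codebook(train_desc, k = encode$k %||% 32L, seed = seed,
                         nstart = encode$nstart %||% 3L)
    t(vapply(rows, function(r) as.numeric(encode_bovw(r, cb)$vector),
             numeric(cb$k)))
  } else {
    gmm <- fit_gmm(train_desc, G = encode$G %||% 16L, seed = seed)
    t(vapply(rows, function(r) encode_fv(r, gmm)$vector,
             numeric(2L * gmm$G * gmm$D)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.srp_cv_report <- function(x, ...) {
  cat("Grouped cross-validation report\n")
  cat(sprintf("  mean AUC %.3f +/- %.3f, F1 %.3f +/- %.3f\n",
              x$mean["auc"], x$sd["auc"], x$mean["f1"], x$sd["f1"]))
  print(x$per_fold, digits = 3)
  invisible(x)
}

#' Kruskal-Wallis comparison of classification models
#'
#' One-way ANOVA on ranks across per-fold metric samples of several
#' methods, with per-method mean ranks and comparison intervals for a
#' mean-rank plot. All-tied input reports p = 1.
#'
#' @param metric_samples Named list of numeric vectors (one per method).
#' @param alpha Significance level (default 0.01).
#' @return Object of class `srp_kruskal`: list with `H`, `p_value`,
#'   `mean_ranks`, `intervals` (half-widths), `alpha`, `reject`.
#' @export
kruskal_wallis_compare <- function(metric_samples, alpha = 0.01) {
  if (!is.list(metric_samples) || length(metric_samples) < 2L) {
    stop_srp("need at least two methods")
  }
  if (any(vapply(metric_samples, length, 0L) < 2L)) {
    stop_srp("need at least two samples per method")
  }
  vals <- unlist(metric_samples, use.names = FALSE)
  grp <- factor(rep(names(metric_samples) %||% seq_along(metric_samples),
                    vapply(metric_samples, length, 0L)))
  if (length(unique(vals)) == 1L) {
    kk <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0), p.value = 1)
  } else {
    kk <- stats::kruskal.test(vals, grp)
  }
  r <- rank(vals)
  mean_ranks <- tapply(r, grp, mean)
  n <- length(vals)
  ns <- tapply(r, grp, length)
  # Tukey-style comparison interval half-widths on ranks.
  se <- sqrt(n * (n + 1) / 12 / ns)
  crit <- stats::qnorm(1 - alpha / 2) / sqrt(2)
  structure(
    list(H = unname(kk$statistic), p_value = kk$p.value,
         mean_ranks = mean_ranks, intervals = crit * se,
         alpha = alpha, reject = kk$p.value < alpha),
    class = "srp_kruskal"
  )
}

#' @export
print.srp_kruskal <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, p = %.3g -> %s (alpha = %g)\n",
              x$H, x$p_value, if (x$reject) "reject H0" else "do not reject H0",
              x$alpha))
  print(data.frame(mean_rank = as.vector(x$mean_ranks),
                   interval = as.vector(x$intervals),
                   row.names = names(x$mean_ranks)), digits = 3)
  invisible(x)
}

#' One-sided t-test: does the 3D descriptor beat its pseudo-3D form?
#'
#' Two-sample pooled-variance t-test of the null hypothesis that the
#' pseudo-3D per-fold metrics are at least as good as the 3D metrics,
#' against the alternative that the 3D mean is larger; rejection at the 5%
#' level indicates a significant third-plane advantage.
#'
#' @param metric_3d,metric_pseudo Equal-length per-fold metric vectors.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `srp_ttest`: list with `p_value`, `t_statistic`,
#'   `alpha`, `reject`, `mean_3d`, `mean_pseudo`.
#' @export
pseudo_vs_3d_ttest <- function(metric_3d, metric_pseudo, alpha = 0.05) {
  if (length(metric_3d) != length(metric_pseudo)) {
    stop_srp("per-fold metric vectors must have equal length")
  }
  if (stats::sd(metric_3d) == 0 && stats::sd(metric_pseudo) == 0) {
    p <- if (mean(metric_3d) > mean(metric_pseudo)) 0 else 1
    tt <- if (p == 0) Inf else 0
  } else {
    fit <- stats::t.test(metric_3d, metric_pseudo, alternative = "greater",
                         var.equal = TRUE)
    p <- fit$p.value
    tt <- unname(fit$statistic)
  }
  structure(list(p_value = p, t_statistic = tt, alpha = alpha,
                 reject = p < alpha,
                 mean_3d = mean(metric_3d), mean_pseudo = mean(metric_pseudo)),
            class = "srp_ttest")
}

#' @export
print.srp_ttest <- function(x, ...) {
  cat(sprintf(
    "3D vs pseudo-3D one-sided t-test: t = %.3f, p = %.3g -> %s (alpha = %g)\n",
    x$t_statistic, x$p_value,
    if (x$reject) "reject H0 (3D better)" else "accept H0", x$alpha))
  invisible(x)
}
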