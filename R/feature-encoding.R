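# Bag-of-visual-words encoding of per-patch descriptors.

# k-means++ seeding followed by Lloyd iterations, multi-restart, seeded.
kmeans_pp <- function(x, k, seed, nstart = 10L, iter_max = 100L) {
  n <- nrow(x)
  if (n < k) stop_srp(sprintf("need at least k = %d descriptors, got %d", k, n))
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- matrix(0, k, ncol(x))
      centers[1L, ] <- x[sample.int(n, 1L), ]
      d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
      for (j in seq_len(k - 1L)) {
        if (all(d2 <= 0)) {
          pick <- sample.int(n, 1L)
        } else {
          pick <- sample.int(n, 1L, prob = d2)
        }
        centers[j + 1L, ] <- x[pick, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j + 1L, ])^2))
      }
      fit <- if (anyDuplicated(centers)) {
        # degenerate data: fewer distinct points than k; assign directly
        d2c <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
        cl <- max.col(-d2c, ties.method = "first")
        list(centers = centers, cluster = cl,
             tot.withinss = sum(pmax(d2c[cbind(seq_len(n), cl)], 0)))
      } else {
        suppressWarnings(
          stats::kmeans(x, centers = centers, iter.max = iter_max,
                        algorithm = "Lloyd")
        )
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

#' Build a k-means visual vocabulary (codebook)
#'
#' Clusters patch descriptors into `k` visual words with seeded k-means++
#' initialization (10 restarts, Lloyd iterations).
#'
#' @param descriptors Numeric matrix, one descriptor per row, or an
#'   `srp_descriptor_set`.
#' @param k Vocabulary size (integer >= 2).
#' @param seed RNG seed.
#' @param nstart,iter_max k-means restart count and iteration cap.
#' @return Object of class `srp_codebook`: list with `centroids` (k x D),
#'   `k`, `seed`, `inertia` (sum of squared errors at convergence).
#' @export
build_codebook <- function(descriptors, k, seed = 42L, nstart = 10L,
                           iter_max = 100L) {
  x <- descriptor_rows(descriptors)
  if (!is.numeric(k) || length(k) != 1L || k < 2) stop_srp("`k` must be >= 2")
  k <- as.integer(k)
  fit <- kmeans_pp(x, k, seed, nstart, iter_max)
  structure(list(centroids = unname(fit$centers), k = k, seed = seed,
                 inertia = fit$tot.withinss),
            class = "srp_codebook")
}

descriptor_rows <- function(x) {
  if (inherits(x, "srp_descriptor_set")) x <- x$descriptors
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 1L) stop_srp("descriptors must be a non-empty numeric matrix")
  x
}

#' Select the BOVW vocabulary size by the elbow method
#'
#' Runs k-means for each candidate `k`, records the sum of squared errors
#' (SSE), and returns the candidate at the elbow of the SSE curve. The
#' elbow is automated as the candidate maximizing the discrete second
#' difference of log(SSE) along the curve anchored at the k = 1 total sum
#' of squares, i.e. the point where the SSE decay rate collapses. Ties and
#' degenerate (zero-SSE) curves resolve to the smallest candidate.
#'
#' @param descriptors Descriptor matrix or `srp_descriptor_set`.
#' @param candidates Candidate vocabulary sizes (default 32, 64, 96, 128,
#'   160). Candidates exceeding the number of descriptors are skipped with
#'   a warning.
#' @param seed RNG seed.
#' @param nstart k-means restarts per candidate.
#' @return Object of class `srp_elbow`: list with `k` (the selection),
#'   `candidates`, `sse` and `curvature`; `plot()` draws the SSE arm.
#' @export
select_k_elbow <- function(descriptors, candidates = c(32L, 64L, 96L, 128L, 160L),
                           seed = 42L, nstart = 5L) {
  x <- descriptor_rows(descriptors)
  keep <- candidates <= nrow(x)
  if (!all(keep)) {
    warning(sprintf("skipping candidates larger than descriptor count: %s",
                    paste(candidates[!keep], collapse = ", ")))
    candidates <- candidates[keep]
  }
  if (length(candidates) == 0L) stop_srp("no usable candidate k")
  candidates <- sort(as.integer(candidates))
  sse <- vapply(seq_along(candidates), function(i) {
    kmeans_pp(x, candidates[i], seed = seed + i, nstart = nstart)$tot.withinss
  }, 0)
  tss <- sum(sweep(x, 2L, colMeans(x))^2)
  eps <- max(tss, 1) * 1e-12
  lcurve <- log(c(tss, sse) + eps) # anchored at k = 1
  m <- length(candidates)
  curvature <- rep(-Inf, m)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      curvature[i] <- lcurve[i] - 2 * lcurve[i + 1L] + lcurve[i + 2L]
    }
  }
  best <- which(curvature >= max(curvature) - 1e-12)[1L]
  if (!is.finite(max(curvature))) best <- 1L
  structure(list(k = candidates[best], candidates = candidates, sse = sse,
                 curvature = curvature, tss = tss),
            class = "srp_elbow")
}

#' @export
print.srp_elbow <- function(x, ...) {
  cat("BOVW elbow selection: k =", x$k, "\n")
  print(data.frame(k = x$candidates, sse = x$sse, curvature = x$curvature))
  invisible(x)
}

#' @export
plot.srp_elbow <- function(x, ...) {
  graphics::plot(x$candidates, x$sse, type = "b", xlab = "k", ylab = "SSE",
                 main = "BOVW elbow", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Bag-of-visual-words encoding of an image
#'
#' Hard-assigns every patch descriptor to its nearest centroid (Euclidean
#' distance, lowest index wins ties) and sum-pools the assignments into a
#' count histogram of length `k`.
#'
#' @param descriptors Descriptor matrix or `srp_descriptor_set` of one image.
#' @param codebook An `srp_codebook`.
#' @return Object of class `srp_encoded`: list with `vector` (integer
#'   counts, length k, summing to the patch count) and `kind = "bovw"`.
#' @export
encode_bovw <- function(descriptors, codebook) {
  x <- descriptor_rows(descriptors)
  if (!inherits(codebook, "srp_codebook")) stop_srp("`codebook` must be an srp_codebook")
  cen <- codebook$centroids
  if (ncol(x) != ncol(cen)) {
    stop_srp(sprintf("descriptor dimension %d does not match codebook dimension %d",
                     ncol(x), ncol(cen)))
  }
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per row.
  cross <- x %*% t(cen)
  d2 <- sweep(-2 * cross, 2L, rowSums(cen^2), `+`)
  assign <- max.col(-d2, ties.method = "first")
  structure(list(vector = tabulate(assign, nbins = codebook$k), kind = "bovw",
                 k = codebook$k),
            class = "srp_encoded")
}

#' @export
print.srp_encoded <- function(x, ...) {
  cat(sprintf("%s encoding, length %d\n", toupper(x$kind), length(x$vector)))
  invisible(x)
}
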