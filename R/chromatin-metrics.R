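# Heterochromatin / euchromatin ratios from retained SRP function values.

#' Heterochromatin threshold from per-patch maxima
#'
#' The HC threshold of a nucleus is the minimum of the strictly non-zero
#' per-patch maxima of the pooled SRP function values; all-zero patches
#' (background corners of tilted nuclei) are excluded.
#'
#' @param per_patch_maxima Numeric vector of per-patch maxima.
#' @return The minimum non-zero entry.
#' @examples
#' hc_threshold(c(0, 3, 5)) # 3
#' @export
hc_threshold <- function(per_patch_maxima) {
  m <- per_patch_maxima[is.finite(per_patch_maxima) & per_patch_maxima != 0]
  if (length(m) == 0L) {
    stop_srp("degenerate volume: all per-patch maxima are zero")
  }
  min(m)
}

# Shared Eq.-style ratio: pool per-patch value rows, threshold at the
# minimum non-zero per-patch maximum, HC = values strictly above the
# threshold, ratio = sum(HC) / (sum(all) - sum(HC)).
hc_ec_ratio <- function(raw, use_abs = TRUE) {
  if (!is.matrix(raw) || nrow(raw) == 0L) {
    stop_srp("descriptor set has no retained raw function values")
  }
  vals <- if (use_abs) abs(raw) else raw
  maxima <- apply(vals, 1L, max)
  thr <- hc_threshold(maxima)
  pooled <- as.vector(vals)
  hc <- pooled[pooled > thr]
  hc_sum <- sum(hc)
  if (hc_sum == 0) return(structure(0, threshold = thr))
  ec_sum <- sum(pooled) - hc_sum
  if (ec_sum <= 0) {
    if (ec_sum == 0) {
      warning("euchromatin sum is zero; ratio reported as +Inf")
      return(structure(Inf, threshold = thr))
    }
    warning("euchromatin denominator is negative; ratio flagged invalid (NaN). ",
            "Signed projected values do not support the ratio form; ",
            "use `use_abs = TRUE`.")
    return(structure(NaN, threshold = thr))
  }
  structure(hc_sum / ec_sum, threshold = thr)
}

#' HC/EC intensity ratio of a nucleus
#'
#' Pools the retained global-pattern projection values `f_G` over all
#' cubic patches, thresholds them at the minimum non-zero per-patch
#' maximum, and returns the ratio of the heterochromatin sum to the
#' euchromatin remainder, `sum(HC) / (sum(Nucleus) - sum(HC))`. Values
#' strictly above the threshold count as HC; ties count as EC. By default
#' magnitudes (absolute values) of the projected values are used, which
#' keeps the ratio well defined under the sign-symmetric +/-1 projection;
#' `use_abs = FALSE` uses the raw signed values and flags a non-positive
#' denominator as invalid.
#'
#' @param descriptor_set An `srp_descriptor_set` (with retained `raw_fG`).
#' @param use_abs Use absolute projected values (default TRUE).
#' @return The intensity ratio (dimensionless, scale-invariant), with the
#'   threshold attached as attribute `threshold`.
#' @export
hc_ec_intensity <- function(descriptor_set, use_abs = TRUE) {
  hc_ec_ratio(descriptor_set$raw_fG, use_abs)
}

#' HC/EC aggregation ratio of a nucleus
#'
#' Identical mechanics to [hc_ec_intensity()] applied to the pooled radial
#' and angular difference projections `f_R`, `f_A` (the gradient measure of
#' chromatin aggregation). A constant-intensity volume has all-zero
#' difference projections and raises a degenerate-volume error.
#'
#' @inheritParams hc_ec_intensity
#' @return The aggregation ratio with attribute `threshold`.
#' @export
hc_ec_aggregation <- function(descriptor_set, use_abs = TRUE) {
  hc_ec_ratio(descriptor_set$raw_fRA, use_abs)
}

#' Per-nucleus HC/EC summary
#'
#' @param descriptor_set An `srp_descriptor_set`.
#' @param use_abs Use absolute projected values (default TRUE).
#' @return Object of class `srp_hcec`: one-row data frame with
#'   `ratio_intensity`, `ratio_aggregation`, `threshold_G`, `threshold_RA`,
#'   `patch_count`.
#' @export
hc_ec <- function(descriptor_set, use_abs = TRUE) {
  ri <- hc_ec_intensity(descriptor_set, use_abs)
  ra <- hc_ec_aggregation(descriptor_set, use_abs)
  out <- data.frame(
    ratio_intensity = as.numeric(ri),
    ratio_aggregation = as.numeric(ra),
    threshold_G = attr(ri, "threshold"),
    threshold_RA = attr(ra, "threshold"),
    patch_count = nrow(descriptor_set$descriptors)
  )
  class(out) <- c("srp_hcec", class(out))
  out
}

#' Wilcoxon rank-sum comparison of two phenotype groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test using the normal
#' approximation with tie correction, reporting the z-statistic alongside
#' the p-value and the direction of the median shift.
#'
#' @param ratios_a,ratios_b Numeric vectors of per-nucleus ratios.
#' @param alpha Significance level (default 0.01).
#' @return Object of class `srp_group_comparison`: list with `p_value`,
#'   `z_statistic`, `direction` (sign of median(a) - median(b)), `n_a`,
#'   `n_b`, `alpha`, `reject`.
#' @export
compare_groups <- function(ratios_a, ratios_b, alpha = 0.01) {
  a <- ratios_a[is.finite(ratios_a)]
  b <- ratios_b[is.finite(ratios_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop_srp("both groups must be non-empty")
  }
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  mu <- na * (na + nb + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
  sig2 <- na * nb / 12 * ((na + nb + 1) - tie_term)
  z <- if (sig2 <= 0) 0 else (w - mu) / sqrt(sig2)
  p <- if (sig2 <= 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(
    list(p_value = p, z_statistic = z,
         direction = sign(stats::median(a) - stats::median(b)),
         n_a = na, n_b = nb, alpha = alpha, reject = p < alpha),
    class = "srp_group_comparison"
  )
}

#' @export
print.srp_group_comparison <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum: z = %.4f, p = %.3g (alpha = %g) -> %s; shift: %s\n",
    x$z_statistic, x$p_value, x$alpha,
    if (x$reject) "reject H0" else "do not reject H0",
    if (x$direction > 0) "group A > group B"
    else if (x$direction < 0) "group A < group B" else "none"))
  invisible(x)
}
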