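#' Output dimension of the random projection for ring parameter n
#'
#' The SRP compression maps each pattern vector of a (2n+1) x (2n+1) patch
#' to a fixed lower dimension `a`: 10 for n = 2, increasing by 10 with
#' every increment of n.
#'
#' @param n Ring parameter (integer >= 2); the patch side is 2n + 1.
#' @return Integer projection dimension `10 * (n - 1)`.
#' @examples
#' rp_output_dim(2) # 10
#' rp_output_dim(3) # 20
#' @export
rp_output_dim <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n != as.integer(n) || n < 2) {
    stop_srp("`n` must be a single integer >= 2")
  }
  10L * (as.integer(n) - 1L)
}

validate_patch <- function(patch) {
  if (!is.matrix(patch) || !is.numeric(patch)) {
    stop_srp("patch must be a numeric matrix")
  }
  if (nrow(patch) != ncol(patch)) {
    stop_srp("patch must be square")
  }
  side <- nrow(patch)
  if (side %% 2L == 0L || side < 5L) {
    stop_srp("patch side must be odd and >= 5")
  }
  if (any(!is.finite(patch)) || any(patch < 0)) {
    stop_srp("patch intensities must be finite and non-negative")
  }
  invisible(side)
}

#' Extract the five sorted SRP patterns from a square patch
#'
#' Computes the sorted intensity and difference patterns of a
#' (2n+1) x (2n+1) patch: `glob` (all pixels sorted), `sqr` (centre pixel,
#' then each concentric square ring sorted, innermost first), `circ`
#' (centre, then bilinear samples on concentric circles sorted per ring),
#' `ang` (sorted consecutive-sample differences along each circle, with
#' wrap-around) and `rad` (sorted differences between each circle sample
#' and the sample at the same angle one ring further in; ring 1 is
#' differenced against the centre). Ring r carries 8r circular samples.
#'
#' @param patch Square numeric matrix with odd side >= 5, finite
#'   non-negative entries.
#' @return An object of class `srp_patterns`: a list with elements `glob`,
#'   `sqr`, `circ`, `ang`, `rad` (numeric vectors) and `n`.
#' @examples
#' p <- matrix(runif(25), 5, 5)
#' str(extract_patterns(p))
#' @export
extract_patterns <- function(patch) {
  side <- validate_patch(patch)
  n <- (side - 1L) %/% 2L
  st <- srp_structures(n)
  pm <- pattern_matrices(matrix(as.vector(patch), nrow = 1L), st)
  structure(
    list(
      glob = as.vector(pm$G), sqr = as.vector(pm$S), circ = as.vector(pm$C),
      ang = as.vector(pm$A), rad = as.vector(pm$R), n = n
    ),
    class = "srp_patterns"
  )
}

#' Build the bank of five +/-1 random-projection matrices
#'
#' Draws one fixed projection matrix per pattern (G, S, C, A, R), each of
#' size `a x b_f` with i.i.d. entries +1 or -1 with probability 1/2, where
#' `a = rp_output_dim(n)` and `b_f` is the length of the corresponding
#' pattern vector. The bank is deterministic for a fixed `(n, seed)` and is
#' meant to be drawn once per analysis and shared across all patches so
#' descriptors remain mutually comparable.
#'
#' @param n Ring parameter (integer >= 2).
#' @param seed RNG seed used to draw all five matrices (default 42).
#' @return An object of class `srp_rp_bank` with elements `rp` (named list
#'   of matrices `G`, `S`, `C`, `A`, `R`), `n`, `a`, `seed`.
#' @examples
#' bank <- make_rp_bank(2, seed = 1)
#' dim(bank$rp$S) # 10 x 25
#' @export
make_rp_bank <- function(n, seed = 42L) {
  a <- rp_output_dim(n)
  lens <- pattern_lengths(n)
  rp <- with_seed(seed, {
    lapply(lens, function(b) {
      matrix(sample(c(-1, 1), a * b, replace = TRUE), nrow = a, ncol = b)
    })
  })
  names(rp) <- names(lens)
  structure(list(rp = rp, n = as.integer(n), a = a, seed = seed),
            class = "srp_rp_bank")
}

#' @export
print.srp_rp_bank <- function(x, ...) {
  cat(sprintf("SRP random-projection bank: n = %d, a = %d, seed = %s\n",
              x$n, x$a, format(x$seed)))
  cat("pattern vector lengths:",
      paste(sprintf("%s=%d", names(x$rp), vapply(x$rp, ncol, 0L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project SRP patterns to the five compressed function vectors
#'
#' Applies the linear random-projection compression `f_X = RP_X %*% x_X`
#' to each of the five sorted pattern vectors.
#'
#' @param patterns An `srp_patterns` object (or a named list with elements
#'   `glob`, `sqr`, `circ`, `ang`, `rad`).
#' @param bank An `srp_rp_bank` whose matrix widths match the pattern
#'   lengths.
#' @return An object of class `srp_functions`: list of numeric vectors
#'   `f_G`, `f_S`, `f_C`, `f_A`, `f_R`, each of length `bank$a`.
#' @export
project <- function(patterns, bank) {
  if (!inherits(bank, "srp_rp_bank")) stop_srp("`bank` must be an srp_rp_bank")
  key <- c(G = "glob", S = "sqr", C = "circ", A = "ang", R = "rad")
  out <- lapply(names(key), function(f) {
    x <- patterns[[key[[f]]]]
    m <- bank$rp[[f]]
    if (length(x) != ncol(m)) {
      stop_srp(sprintf(
        "pattern `%s` has length %d but bank expects %d (dimension mismatch)",
        key[[f]], length(x), ncol(m)))
    }
    as.vector(m %*% x)
  })
  names(out) <- paste0("f_", names(key))
  structure(out, class = "srp_functions")
}
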