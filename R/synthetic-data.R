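# Synthetic DAPI-like nucleus phantoms with controllable heterochromatin
# condensation.

#' Phantom generator parameters
#'
#' Describes one synthetic DAPI-stained nucleus: an ellipsoidal nucleus on
#' a dark background, a smooth euchromatin base texture (Gaussian-blurred
#' noise field), and bright condensed-chromatin foci (hard spheres with
#' Gaussian-feathered edges) whose count, intensity gain and radius are the
#' condensation dials. Intensities are on a 16-bit-like arbitrary
#' fluorescence scale and volumes are quantized to integers so TIFF output
#' round-trips bit-exactly.
#'
#' @param shape Volume shape in voxels (default 64 x 64 x 15, mimicking
#'   cropped fibroblast cell objects).
#' @param semi_axes Ellipsoid semi-axes in voxels (must fit in the volume).
#' @param background Background level outside the nucleus mask.
#' @param base_level Euchromatin base intensity inside the mask.
#' @param smoothness Gaussian blur sigma (voxels) of the base noise field.
#' @param noise_field_sd Amplitude (sd) of the smoothed base texture.
#' @param focus_count Number of heterochromatin foci.
#' @param focus_radius Focus core radius in voxels.
#' @param focus_gain Multiplicative intensity gain of foci (>= 1).
#' @param feather_sigma Gaussian feather sigma at the focus edge (voxels).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return Object of class `srp_phantom_params` (a validated list).
#' @export
phantom_params <- function(shape = c(64L, 64L, 15L),
                           semi_axes = c(26, 22, 6.5),
                           background = 8,
                           base_level = 100,
                           smoothness = 1.5,
                           noise_field_sd = 15,
                           focus_count = 6L,
                           focus_radius = 2,
                           focus_gain = 1.6,
                           feather_sigma = 1,
                           noise_sd = 5,
                           seed = 42L) {
  if (length(shape) != 3L || any(shape < 1)) stop_srp("shape must be 3 positive integers")
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) stop_srp("semi_axes must be 3 positive numbers")
  if (any(2 * semi_axes > shape)) stop_srp("semi_axes must fit inside the volume")
  check_number(background, "background", min = 0)
  check_number(base_level, "base_level", min = 0)
  check_number(noise_field_sd, "noise_field_sd", min = 0)
  check_number(focus_gain, "focus_gain", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(focus_radius, "focus_radius", min = 0)
  structure(
    list(shape = as.integer(shape), semi_axes = as.numeric(semi_axes),
         background = background, base_level = base_level,
         smoothness = smoothness, noise_field_sd = noise_field_sd,
         focus_count = as.integer(focus_count), focus_radius = focus_radius,
         focus_gain = focus_gain, feather_sigma = feather_sigma,
         noise_sd = noise_sd, seed = seed),
    class = "srp_phantom_params"
  )
}

#' Condensed and open chromatin phantom presets
#'
#' The `condensed` preset carries more and brighter foci (count 18, gain
#' 3.0) emulating a condensed-chromatin phenotype; the `open` preset fewer
#' and dimmer foci (count 6, gain 1.6). All other parameters are shared.
#'
#' @return Named list with elements `condensed` and `open`
#'   (`srp_phantom_params`).
#' @export
phantom_presets <- function() {
  list(condensed = phantom_params(focus_count = 18L, focus_gain = 3.0),
       open = phantom_params(focus_count = 6L, focus_gain = 1.6))
}

# Separable Gaussian blur of a 3D array via per-axis band-matrix products.
gaussian_blur3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur_axis <- function(len) {
    rad <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-rad:rad, sd = sigma)
    B <- matrix(0, len, len)
    for (i in seq_len(len)) {
      j <- (i - rad):(i + rad)
      ok <- j >= 1 & j <= len
      B[i, j[ok]] <- k[ok]
      B[i, ] <- B[i, ] / sum(B[i, ])
    }
    B
  }
  d <- dim(x)
  Bx <- blur_axis(d[1L]); By <- blur_axis(d[2L]); Bz <- blur_axis(d[3L])
  m <- matrix(x, d[1L]) # x fastest
  m <- Bx %*% m
  x <- array(m, d)
  x <- aperm(apply(x, c(1L, 3L), function(v) By %*% v), c(2L, 1L, 3L))
  x <- aperm(apply(x, c(1L, 2L), function(v) Bz %*% v), c(2L, 3L, 1L))
  x
}

#' Generate one synthetic nucleus volume
#'
#' Deterministic for a fixed parameter set (seed included): ellipsoidal
#' nucleus mask, smoothed positive base texture, spherical feathered foci
#' with multiplicative gain, additive Gaussian noise clipped at zero,
#' quantized to integer intensities. Voxels outside the mask are exactly
#' the background level.
#'
#' @param params An `srp_phantom_params` object.
#' @param label Optional class label stored with the volume.
#' @return Object of class `srp_phantom`: list with `volume` (3D array),
#'   `mask` (logical 3D array), `label`, `params`.
#' @export
generate_nucleus <- function(params, label = NA_character_) {
  if (!inherits(params, "srp_phantom_params")) {
    stop_srp("`params` must come from phantom_params()")
  }
  p <- params
  d <- p$shape
  ctr <- (d + 1) / 2
  ax <- p$semi_axes
  xg <- (seq_len(d[1L]) - ctr[1L]) / ax[1L]
  yg <- (seq_len(d[2L]) - ctr[2L]) / ax[2L]
  zg <- (seq_len(d[3L]) - ctr[3L]) / ax[3L]
  r2 <- outer(outer(xg^2, yg^2, `+`), zg^2, `+`)
  mask <- r2 <= 1
  vol <- with_seed(p$seed, {
    field <- array(stats::rnorm(prod(d)), d)
    field <- gaussian_blur3d(field, p$smoothness)
    s <- stats::sd(field)
    if (s > 0) field <- field / s
    base <- p$base_level + p$noise_field_sd * field
    # Focus centres drawn from the eroded interior so spheres stay in-mask.
    interior <- which(r2 <= 0.75^2)
    if (p$focus_count > 0L && length(interior) == 0L) {
      stop_srp("cannot place foci: no interior voxels in the nucleus mask")
    }
    mult <- array(1, d)
    if (p$focus_count > 0L) {
      centers <- interior[sample.int(length(interior), p$focus_count,
                                     replace = p$focus_count > length(interior))]
      cidx <- arrayInd(centers, d)
      rad <- p$focus_radius
      win <- ceiling(rad + 3 * p$feather_sigma)
      for (fc in seq_len(nrow(cidx))) {
        c0 <- cidx[fc, ]
        xs <- max(1L, c0[1L] - win):min(d[1L], c0[1L] + win)
        ys <- max(1L, c0[2L] - win):min(d[2L], c0[2L] + win)
        zs <- max(1L, c0[3L] - win):min(d[3L], c0[3L] + win)
        dist <- sqrt(outer(outer((xs - c0[1L])^2, (ys - c0[2L])^2, `+`),
                           (zs - c0[3L])^2, `+`))
        w <- ifelse(dist <= rad, 1,
                    exp(-((dist - rad)^2) / (2 * p$feather_sigma^2)))
        loc <- 1 + (p$focus_gain - 1) * w
        mult[xs, ys, zs] <- pmax(mult[xs, ys, zs], loc)
      }
    }
    v <- base * mult + stats::rnorm(prod(d), sd = p$noise_sd)
    v <- round(pmin(pmax(v, 0), 65535))
    v[!mask] <- p$background
    v
  })
  structure(list(volume = vol, mask = mask, label = label, params = p),
            class = "srp_phantom")
}

#' Generate labelled condensed/open phantom cohorts
#'
#' Draws `n_per_class` phantoms per preset with per-volume seeds derived
#' from the master seed. When `dir` is given, volumes are written as 16-bit
#' multi-page TIFFs next to a `labels.csv` (filename, class, seed) and a
#' `params.json` provenance file.
#'
#' @param n_per_class Number of volumes per class (>= 1).
#' @param condensed,open Parameter sets for the two classes (defaults:
#'   [phantom_presets()]).
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return Invisibly, a list with `volumes` (list of `srp_phantom`),
#'   `labels` (character vector) and `files` (paths or NULL).
#' @export
make_cohorts <- function(n_per_class, condensed = phantom_presets()$condensed,
                         open = phantom_presets()$open, seed = 7L, dir = NULL) {
  if (n_per_class < 1L) stop_srp("n_per_class must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_per_class)
  classes <- rep(c("condensed", "open"), each = n_per_class)
  presets <- list(condensed = condensed, open = open)
  volumes <- vector("list", 2L * n_per_class)
  for (i in seq_along(classes)) {
    pp <- presets[[classes[i]]]
    pp$seed <- seeds[i]
    volumes[[i]] <- generate_nucleus(pp, label = classes[i])
  }
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(length(volumes))
    for (i in seq_along(volumes)) {
      files[i] <- file.path(dir, sprintf("%s_%03d.tif", classes[i],
                                         ((i - 1L) %% n_per_class) + 1L))
      write_volume(volumes[[i]]$volume, files[i])
    }
    utils::write.csv(
      data.frame(filename = basename(files), class = classes, seed = seeds),
      file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_per_class = n_per_class,
           condensed = unclass(condensed), open = unclass(open)),
      file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(volumes = volumes, labels = classes, files = files))
}
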