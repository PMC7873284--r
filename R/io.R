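# Object cropping and tabular descriptor output.

#' Crop labelled objects from a volume
#'
#' Cuts the tight bounding box (plus `pad` voxels, clipped at the volume
#' border) of every label in an instance mask; voxels inside the crop that
#' do not belong to the object are zeroed so background never dilutes the
#' texture description. Coordinates are 0-based, boxes half-open.
#'
#' @param volume 3D numeric array.
#' @param label_mask Integer array of the same shape; 0 is background.
#' @param pad Padding in voxels (default 0).
#' @return List with one element per label id: `list(volume, id, bbox)`
#'   where `bbox` is a 2 x 3 matrix of (start, end) 0-based half-open
#'   bounds. Empty mask gives an empty list with a warning.
#' @export
crop_objects <- function(volume, label_mask, pad = 0L) {
  if (!identical(dim(volume), dim(label_mask))) {
    stop_srp("mask and volume must have identical shapes")
  }
  ids <- sort(unique(as.vector(label_mask)))
  ids <- ids[ids != 0]
  if (length(ids) == 0L) {
    warning("label mask is empty; no objects to crop")
    return(list())
  }
  d <- dim(volume)
  lapply(ids, function(id) {
    w <- which(label_mask == id, arr.ind = TRUE)
    lo <- pmax(apply(w, 2L, min) - pad, 1L)
    hi <- pmin(apply(w, 2L, max) + pad, d)
    sub <- volume[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    subm <- label_mask[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    sub[subm != id] <- 0
    list(volume = sub, id = id,
         bbox = rbind(start = lo - 1L, end = hi))
  })
}

#' Write a descriptor set as tab-separated text with sidecar metadata
#'
#' One row per patch: origin x, y, z then the descriptor values; a JSON
#' sidecar (`<path>.meta.json`) records the run configuration for
#' provenance.
#'
#' @param dset An `srp_descriptor_set`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_descriptors <- function(dset, path) {
  if (!inherits(dset, "srp_descriptor_set")) {
    stop_srp("`dset` must be an srp_descriptor_set")
  }
  tab <- data.frame(dset$origins, dset$descriptors)
  names(tab) <- c("x", "y", "z",
                  paste0("d", seq_len(ncol(dset$descriptors))))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("srp3d")),
         mode = dset$mode, n = dset$n, bank_seed = dset$bank_seed,
         depth = dset$depth, stride = dset$stride,
         volume_dim = dset$volume_dim, bins = 16L),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
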