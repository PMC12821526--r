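#' Nucleus segmentation parameters
#'
#' Thresholds for DAPI-channel segmentation. Whole nuclei and dense-chromatin
#' (high-intensity DAPI) subregions are segmented by direct thresholding,
#' without maxima detection. The published analysis used 12 a.u. for whole
#' nuclei and 28 a.u. for dense chromatin on the 8-bit scale; comparisons are
#' inclusive, so a voxel equal to the threshold is kept.
#'
#' @param nucleus_threshold intensity (a.u.) for the whole-nucleus mask
#'   (default 12).
#' @param dense_threshold intensity (a.u.) for dense-chromatin subregions
#'   (default 28); must exceed `nucleus_threshold`.
#' @param min_nucleus_volume minimum physical component volume in um^3
#'   (default 50). A nucleus size filter is not part of the published
#'   protocol; this conservative floor only rejects debris far below any
#'   mammalian nucleus.
#' @param crop_margin margin in um added around each nucleus bounding box
#'   when cropping (default 1.0).
#' @param exclude_border flag nuclei whose bounding box touches a stack face
#'   as excluded (default TRUE). Such records are flagged, never dropped.
#' @return list of class `nucleus_params`.
#' @export
nucleus_params <- function(nucleus_threshold = 12, dense_threshold = 28,
                           min_nucleus_volume = 50, crop_margin = 1.0,
                           exclude_border = TRUE) {
  if (!(nucleus_threshold >= 0 && nucleus_threshold < dense_threshold &&
        dense_threshold <= 255))
    stop("need 0 <= nucleus_threshold < dense_threshold <= 255")
  if (min_nucleus_volume <= 0) stop("min_nucleus_volume must be > 0")
  if (crop_margin < 0) stop("crop_margin must be >= 0")
  structure(list(nucleus_threshold = nucleus_threshold,
                 dense_threshold = dense_threshold,
                 min_nucleus_volume = min_nucleus_volume,
                 crop_margin = crop_margin,
                 exclude_border = isTRUE(exclude_border)),
            class = "nucleus_params")
}

#' 3D connected-component labeling
#'
#' Labels connected components of a 3D logical mask. 26-connectivity is the
#' default, matching the ImageJ 3D convention used throughout the package.
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (vertex-sharing) or 6 (face-sharing).
#' @return 3D integer array of component labels (0 = background), in
#'   first-encounter order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6L, 26L))
  array(.cpp_label_components(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

# Fill holes of a 3D mask: complement components (6-connected, the dual of
# 26-connected foreground) not reaching the volume border are holes.
fill_holes_3d <- function(mask) {
  comp <- label_components(!mask, connectivity = 6L)
  d <- dim(mask)
  border_labels <- unique(c(comp[c(1, d[1]), , ], comp[, c(1, d[2]), ],
                            comp[, , c(1, d[3])]))
  holes <- comp > 0L & !(comp %in% border_labels)
  mask | holes
}

# Slice-wise 2D hole fill (per z-plane), then full 3D fill. DAPI-dark
# nucleoli appear as 2D holes in most planes; the 3D pass catches cavities
# fully enclosed in z.
fill_holes_nucleus <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[1])) {
    slice <- array(mask[z, , ], c(1L, d[2], d[3]))
    mask[z, , ] <- fill_holes_3d(slice)[1, , ]
  }
  fill_holes_3d(mask)
}

#' Segment whole nuclei from the DAPI channel
#'
#' Thresholds the DAPI stack at `nucleus_threshold` (inclusive), fills
#' DAPI-dark holes (nucleoli) slice-wise and in 3D, labels 26-connected
#' components, and discards components whose physical volume falls below
#' `min_nucleus_volume`. Surviving labels are dense-ranked by voxel count,
#' largest first.
#'
#' @param dapi a [channel_stack] with role `"dapi"`.
#' @param params [nucleus_params()].
#' @return 3D integer label array (0 = background); attribute `"volumes_um3"`
#'   holds the physical volume per label. An empty result (no labels) is
#'   valid.
#' @export
segment_nuclei <- function(dapi, params = nucleus_params()) {
  stopifnot(inherits(dapi, "channel_stack"))
  if (dapi$channel_role != "dapi")
    stop("segment_nuclei expects the DAPI channel, got '", dapi$channel_role, "'")
  mask <- dapi$voxels >= params$nucleus_threshold
  if (!any(mask)) return(array(0L, dim(dapi$voxels)))
  mask <- fill_holes_nucleus(mask)
  labels <- label_components(mask, 26L)
  counts <- tabulate(labels[labels > 0L])
  vox_vol <- prod(dapi$voxel_size)
  keep <- which(counts * vox_vol >= params$min_nucleus_volume)
  if (!length(keep)) return(array(0L, dim(dapi$voxels)))
  # dense-rank by size descending; ties keep original label order
  keep <- keep[order(-counts[keep], keep)]
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  nz <- labels > 0L
  out[nz] <- remap[labels[nz]]
  attr(out, "volumes_um3") <- counts[keep] * vox_vol
  out
}

#' Segment dense-chromatin regions inside nuclei
#'
#' Returns the voxels at or above `dense_threshold` restricted to the given
#' nucleus mask. Dense regions are by construction a subset of the nucleus.
#'
#' @param dapi a [channel_stack] with role `"dapi"`.
#' @param nucleus_mask 3D logical array (from [segment_nuclei()] labels).
#' @param params [nucleus_params()].
#' @return 3D logical array.
#' @export
segment_dense_regions <- function(dapi, nucleus_mask, params = nucleus_params()) {
  stopifnot(identical(dim(dapi$voxels), dim(nucleus_mask)))
  (dapi$voxels >= params$dense_threshold) & nucleus_mask
}

#' Crop individual nuclei out of a field-of-view stack
#'
#' For each nucleus label, the crop box is the component bounding box dilated
#' by `crop_margin` (converted per axis to voxels, rounded up) and clipped to
#' the stack bounds. A nucleus is `border_touching` when its undilated
#' bounding box touches any stack face; with `exclude_border` such records
#' are flagged excluded (reason `"border"`), never dropped silently.
#'
#' @param protein,dapi the two [channel_stack]s of one acquisition.
#' @param labels nucleus label array from [segment_nuclei()] on `dapi`.
#' @param params [nucleus_params()].
#' @return list of `nucleus_record` objects, each holding the two channel
#'   crops, the local nucleus and dense-chromatin masks, the crop origin
#'   (1-based voxel offset of the crop's first voxel in the parent stack),
#'   and QC flags. `crop_origin + local_index - 1` recovers parent
#'   coordinates.
#' @export
crop_nuclei <- function(protein, dapi, labels, params = nucleus_params()) {
  if (!identical(dim(protein$voxels), dim(labels)) ||
      !identical(dim(dapi$voxels), dim(labels)))
    stop("label map shape does not match the channel stacks")
  n <- max(labels)
  d <- dim(labels)
  records <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(labels == k, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    border <- any(lo == 1L) || any(hi == d)
    margin <- ceiling(params$crop_margin / protein$voxel_size)
    clo <- pmax(lo - margin, 1L); chi <- pmin(hi + margin, d)
    zz <- clo[1]:chi[1]; yy <- clo[2]:chi[2]; xx <- clo[3]:chi[3]
    nmask <- labels[zz, yy, xx, drop = FALSE] == k
    pcrop <- channel_stack(protein$voxels[zz, yy, xx, drop = FALSE],
                           protein$voxel_size, "protein", protein$source_id)
    dcrop <- channel_stack(dapi$voxels[zz, yy, xx, drop = FALSE],
                           dapi$voxel_size, "dapi", dapi$source_id)
    dense <- (dcrop$voxels >= params$dense_threshold) & nmask
    records[[k]] <- structure(
      list(nucleus_id = k, source_id = protein$source_id,
           crop_origin = as.integer(clo),
           nucleus_mask = nmask, dense_mask = dense,
           protein_crop = pcrop, dapi_crop = dcrop,
           border_touching = border,
           excluded = border && params$exclude_border,
           exclusion_reason = if (border && params$exclude_border) "border_auto" else "none"),
      class = "nucleus_record")
  }
  records
}

#' @export
print.nucleus_record <- function(x, ...) {
  d <- dim(x$nucleus_mask)
  cat(sprintf("<nucleus_record> #%d from '%s': crop %d x %d x %d, origin (%s)%s\n",
              x$nucleus_id, x$source_id, d[1], d[2], d[3],
              paste(x$crop_origin, collapse = ","),
              if (x$border_touching) " [border]" else ""))
  invisible(x)
}
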