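#' Measure one segmented body
#'
#' Bounding-box extents use inclusive voxel counts,
#' `(max_index - min_index + 1) * pitch`, the convention under which a
#' single-voxel object has the size of one voxel. The diameter is the mean
#' of the X- and Y-axis bounding-box lengths - a size estimate deliberately
#' insensitive to the poorer axial resolution of confocal stacks (the Z
#' extent never enters it). The intensity metric is the maximum raw gray
#' value over the object's voxels: peak intensity is a robust readout of
#' local protein density in small high-contrast foci.
#'
#' @param voxel_idx integer matrix of (z, y, x) voxel coordinates (1-based),
#'   as from `which(labels == k, arr.ind = TRUE)`.
#' @param raw 3D integer array of raw protein intensities.
#' @param voxel_size (dz, dy, dx) in um.
#' @param body_id,nucleus_id identifiers carried into the record.
#' @return one-row data.frame: body_id, nucleus_id, voxel_count,
#'   x_len_um, y_len_um, z_len_um, diameter_um, max_gray.
#' @export
measure_body <- function(voxel_idx, raw, voxel_size, body_id = 1L, nucleus_id = 1L) {
  if (is.null(dim(voxel_idx)) || nrow(voxel_idx) == 0L)
    stop("empty voxel set: a body must contain at least one voxel")
  zl <- (max(voxel_idx[, 1]) - min(voxel_idx[, 1]) + 1L) * voxel_size[1]
  yl <- (max(voxel_idx[, 2]) - min(voxel_idx[, 2]) + 1L) * voxel_size[2]
  xl <- (max(voxel_idx[, 3]) - min(voxel_idx[, 3]) + 1L) * voxel_size[3]
  lin <- voxel_idx[, 1] + dim(raw)[1] * ((voxel_idx[, 2] - 1L) +
                                         dim(raw)[2] * (voxel_idx[, 3] - 1L))
  data.frame(body_id = as.integer(body_id), nucleus_id = as.integer(nucleus_id),
             voxel_count = nrow(voxel_idx),
             x_len_um = xl, y_len_um = yl, z_len_um = zl,
             diameter_um = (xl + yl) / 2,
             max_gray = max(raw[lin]))
}

#' Measure every body in a label image
#'
#' @param labels 3D integer label array from [segment_bodies()].
#' @param raw matching raw protein array.
#' @param voxel_size (dz, dy, dx) in um.
#' @param nucleus_id identifier carried into the records.
#' @return data.frame of body records (possibly 0 rows).
#' @export
measure_bodies <- function(labels, raw, voxel_size, nucleus_id = 1L) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(body_id = integer(), nucleus_id = integer(),
                      voxel_count = integer(), x_len_um = numeric(),
                      y_len_um = numeric(), z_len_um = numeric(),
                      diameter_um = numeric(), max_gray = numeric()))
  do.call(rbind, lapply(seq_len(n), function(k)
    measure_body(which(labels == k, arr.ind = TRUE), raw, voxel_size,
                 body_id = k, nucleus_id = nucleus_id)))
}

#' Summarize one nucleus from its body records
#'
#' Per-nucleus metrics are the body count and, for nuclei containing at
#' least one body, the arithmetic means of per-body diameter and per-body
#' maximum gray value. For a nucleus without bodies the mean fields are
#' absent (`NA`), not zero.
#'
#' @param bodies data.frame of body records for one nucleus (0 rows allowed).
#' @param group ordered group label (e.g. age group) or `NA`.
#' @param cytoplasmic_flag logical (or `NA`) cytoplasmic-labeling flag.
#' @param nucleus_id,source_id identifiers; `nucleus_id` defaults to the one
#'   carried by `bodies`.
#' @return one-row data.frame of nucleus metrics.
#' @export
summarize_nucleus <- function(bodies, group = NA_character_,
                              cytoplasmic_flag = NA, nucleus_id = NULL,
                              source_id = NA_character_) {
  if (nrow(bodies) > 0L && length(unique(bodies$nucleus_id)) > 1L)
    stop("body records from multiple nuclei passed to summarize_nucleus")
  if (is.null(nucleus_id))
    nucleus_id <- if (nrow(bodies)) bodies$nucleus_id[1] else NA_integer_
  n <- nrow(bodies)
  data.frame(source_id = source_id, nucleus_id = as.integer(nucleus_id),
             group = as.character(group), n_bodies = n,
             mean_diameter_um = if (n) mean(bodies$diameter_um) else NA_real_,
             mean_max_intensity = if (n) mean(bodies$max_gray) else NA_real_,
             cytoplasmic_flag = cytoplasmic_flag,
             stringsAsFactors = FALSE)
}

#' Rayleigh lateral resolution limit
#'
#' `0.61 * lambda / NA`, in micrometres. For the green emission of a common
#' 488-excited fluorophore (~530 nm) and a 40x/1.25 NA objective this gives
#' ~0.26 um - sizes below it are not optically resolved and bounding-box
#' measurements there reflect the point-spread function, not the object.
#'
#' @param emission_wavelength_nm emission wavelength in nm (default 530).
#' @param numerical_aperture objective NA (default 1.25).
#' @return resolution limit in um.
#' @export
rayleigh_limit <- function(emission_wavelength_nm = 530, numerical_aperture = 1.25) {
  if (emission_wavelength_nm <= 300 || emission_wavelength_nm >= 800)
    stop("emission wavelength must lie in (300, 800) nm")
  if (numerical_aperture <= 0) stop("numerical aperture must be > 0")
  0.61 * emission_wavelength_nm / numerical_aperture / 1000
}
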