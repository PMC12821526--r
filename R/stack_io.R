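#' Construct a channel stack
#'
#' A `channel_stack` is the raw unit of analysis: one channel of a 3D confocal
#' acquisition held as an integer voxel grid on the 8-bit \[0, 255\] intensity
#' scale, together with its physical voxel dimensions.
#'
#' Axis order is (z, y, x) throughout the package, matching the slice-major
#' storage of multi-page TIFFs; voxel indices are R-style 1-based.
#'
#' @param voxels 3D integer array, dimensions (nz, ny, nx), values in \[0, 255\].
#' @param voxel_size numeric length-3, physical voxel pitch (dz, dy, dx) in
#'   micrometres. Anisotropy (dz > dx) is the norm for confocal stacks and is
#'   never assumed away.
#' @param channel_role `"protein"` (the immunostained protein of interest,
#'   e.g. coilin) or `"dapi"` (the DNA counterstain defining the nucleus).
#' @param source_id opaque identifier of the originating acquisition.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(voxels, voxel_size, channel_role = c("protein", "dapi"),
                          source_id = "stack") {
  channel_role <- match.arg(channel_role)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, y, x)")
  if (any(dim(voxels) < 1L))
    stop("all grid dimensions must be >= 1")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive values (dz, dy, dx) in um")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("voxel intensities must lie in [0, 255]")
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size),
         channel_role = channel_role, source_id = as.character(source_id)),
    class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<channel_stack> %s channel '%s': %d x %d x %d (z,y,x), voxel %g x %g x %g um\n",
              x$channel_role, x$source_id, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$voxels)

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page TIFF stack into channel stacks
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF holding a 1- or 2-channel
#' Z-stack and returns one [channel_stack] per channel. 16-bit sources are
#' linearly min-max rescaled to the 8-bit \[0, 255\] scale on which all
#' analysis thresholds are defined; 8-bit sources pass through unchanged.
#'
#' Voxel size metadata travels in a JSON sidecar file `<path>.json` (written
#' automatically by [write_stack()]); for TIFFs from other sources provide
#' `voxel_size_override`.
#'
#' @param path TIFF file path.
#' @param voxel_size_override optional (dz, dy, dx) in micrometres; required
#'   when no sidecar metadata is present, and takes precedence when given.
#' @param n_channels number of channels when no sidecar states it (default 1;
#'   more than 2 channels requires an explicit value and role assignment).
#' @param channel_order page ordering for multi-channel files:
#'   `"interleaved"` (channel fastest, the OME default) or `"block"`
#'   (all slices of channel 1, then channel 2).
#' @param channel_roles roles assigned to channels in order; default follows
#'   the acquisition convention C1 = protein, C2 = DAPI.
#' @return list of [channel_stack], one per channel. The attribute
#'   `"rescale"` on each records whether a 16-bit linear rescale was applied
#'   and the source range.
#' @export
read_stack <- function(path, voxel_size_override = NULL, n_channels = NULL,
                       channel_order = c("interleaved", "block"),
                       channel_roles = c("protein", "dapi")) {
  channel_order <- match.arg(channel_order)
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)

  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)

  voxel_size <- voxel_size_override
  if (is.null(voxel_size) && !is.null(meta$voxel_size)) voxel_size <- meta$voxel_size
  if (is.null(voxel_size))
    stop("no voxel size metadata for ", path,
         ": supply `voxel_size_override` = (dz, dy, dx) in um")

  if (is.null(n_channels)) n_channels <- if (!is.null(meta$n_channels)) meta$n_channels else 1L
  n_channels <- as.integer(n_channels)
  if (!is.null(meta$channel_order)) channel_order <- meta$channel_order
  if (n_channels > length(channel_roles))
    stop(">2 channels require an explicit channel-role mapping")
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages), " is not a multiple of n_channels = ", n_channels)
  nz <- length(pages) %/% n_channels
  source_id <- if (!is.null(meta$source_id)) meta$source_id
               else sub("\\.(ome\\.)?tiff?$", "", basename(path), ignore.case = TRUE)

  maxv <- max(vapply(pages, max, numeric(1)))
  is16 <- maxv > 255
  out <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    page_idx <- if (channel_order == "interleaved")
      (seq_len(nz) - 1L) * n_channels + ch
    else
      (ch - 1L) * nz + seq_len(nz)
    arr <- array(0L, c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[page_idx[z]]]
    rescale <- list(applied = FALSE, from_range = range(arr))
    if (is16) {
      rng <- range(arr)
      rescale <- list(applied = TRUE, from_range = rng)
      arr <- if (rng[2] > rng[1])
        array(as.integer(round(255 * (arr - rng[1]) / (rng[2] - rng[1]))), dim(arr))
      else array(0L, dim(arr))
    }
    stk <- channel_stack(arr, voxel_size, channel_roles[ch], source_id)
    attr(stk, "rescale") <- rescale
    out[[ch]] <- stk
  }
  out
}

#' Write channel stacks to a multi-page TIFF with a metadata sidecar
#'
#' Writes one or two channel stacks as an 8-bit multi-page TIFF (channel-
#' interleaved page order) plus a JSON sidecar carrying voxel size, channel
#' count and source id, so that [read_stack()] round-trips losslessly.
#'
#' @param stacks a [channel_stack] or list of them sharing shape and voxel size.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stacks, path) {
  if (inherits(stacks, "channel_stack")) stacks <- list(stacks)
  d <- dim(stacks[[1]]$voxels)
  pages <- vector("list", d[1] * length(stacks))
  for (z in seq_len(d[1]))
    for (ch in seq_along(stacks))
      pages[[(z - 1L) * length(stacks) + ch]] <-
        matrix(stacks[[ch]]$voxels[z, , ] / 255, d[2], d[3])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(
    list(voxel_size = stacks[[1]]$voxel_size, n_channels = length(stacks),
         channel_order = "interleaved", source_id = stacks[[1]]$source_id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a 3D label image as 16-bit TIFF
#'
#' @param labels 3D integer array of object labels (0 = background).
#' @param path output path.
#' @export
write_label_stack <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  d <- dim(labels)
  pages <- lapply(seq_len(d[1]), function(z) matrix(labels[z, , ] / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

cohort_columns <- c("source_id", "nucleus_id", "group", "n_bodies",
                    "mean_diameter_um", "mean_max_intensity",
                    "cytoplasmic_flag", "excluded", "exclusion_reason")

#' Write the per-nucleus cohort table to CSV
#'
#' One row per nucleus with the fixed column set (source_id, nucleus_id,
#' group, n_bodies, mean_diameter_um, mean_max_intensity, cytoplasmic_flag,
#' excluded, exclusion_reason). Nuclei with zero bodies have their mean fields
#' written as empty cells (absence, not zero). [read_cohort_table()]
#' reproduces the table exactly.
#'
#' @param table data.frame with the cohort columns.
#' @param path output CSV path (UTF-8, '.' decimal, comma separator).
#' @export
write_cohort_table <- function(table, path) {
  if (nrow(table) == 0L) stop("refusing to write an empty cohort table")
  missing_cols <- setdiff(cohort_columns, names(table))
  if (length(missing_cols))
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  out <- table[, cohort_columns]
  con <- file(path, open = "wb")  # fixed LF endings => byte-reproducible
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#' @param path CSV path.
#' @return data.frame with typed columns; empty mean fields become `NA`.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(source_id = "character",
                                        nucleus_id = "integer",
                                        group = "character",
                                        n_bodies = "integer",
                                        mean_diameter_um = "numeric",
                                        mean_max_intensity = "numeric",
                                        cytoplasmic_flag = "logical",
                                        excluded = "logical",
                                        exclusion_reason = "character"))
  tab$exclusion_reason[is.na(tab$exclusion_reason)] <- "none"
  tab$exclusion_reason[tab$exclusion_reason == ""] <- "none"
  tab
}

#' Pipeline configuration
#'
#' Bundles every tunable of the three-stage pipeline. All segmentation
#' defaults are the values used for the published analysis; see
#' [nucleus_params()] and [segmentation_params()].
#'
#' @param nucleus [nucleus_params()] for DAPI-channel nucleus segmentation.
#' @param segmentation [segmentation_params()] for body segmentation.
#' @param groups named character vector mapping source_id to its ordered
#'   group label (e.g. age group).
#' @param group_levels group levels in increasing order (young first).
#' @param exclusions data.frame(source_id, nucleus_id, reason) of manual
#'   exclusions, or NULL.
#' @param channel_roles channel-to-role assignment, C1 = protein by default.
#' @param cytoplasmic_ratio threshold for the cytoplasmic-labeling surrogate
#'   flag, see [flag_cytoplasmic()].
#' @param seed integer; fully determines any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(nucleus = nucleus_params(),
                            segmentation = segmentation_params(),
                            groups = character(),
                            group_levels = c("young", "middle", "old"),
                            exclusions = NULL,
                            channel_roles = c("protein", "dapi"),
                            cytoplasmic_ratio = 0.5,
                            seed = 1L) {
  structure(list(nucleus = nucleus, segmentation = segmentation,
                 groups = groups, group_levels = group_levels,
                 exclusions = exclusions, channel_roles = channel_roles,
                 cytoplasmic_ratio = cytoplasmic_ratio, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trip is lossless: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$nucleus <- unclass(x$nucleus)
  x$segmentation <- unclass(x$segmentation)
  x$groups <- as.list(x$groups)
  if (!is.null(x$exclusions)) x$exclusions <- as.list(x$exclusions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  excl <- if (!is.null(x$exclusions) && length(x$exclusions))
    as.data.frame(x$exclusions, stringsAsFactors = FALSE) else NULL
  pipeline_config(
    nucleus = do.call(nucleus_params, x$nucleus),
    segmentation = do.call(segmentation_params, x$segmentation),
    groups = unlist(x$groups) %||% character(),
    group_levels = x$group_levels,
    exclusions = excl,
    channel_roles = x$channel_roles,
    cytoplasmic_ratio = x$cytoplasmic_ratio,
    seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
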