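#' Apply exclusion criteria and assemble the analysis-ready cohort table
#'
#' The published protocol excluded nuclei for (i) biological/methodological
#' artifacts and (ii) overlapping cytoplasmic bodies - both scored manually.
#' Here manual exclusions are an explicit input (id list with reasons), and
#' two automatic flags are supported: border-touching crops and saturation
#' (>1% voxels at 255). Excluded nuclei are retained in the table with
#' `excluded = TRUE` for auditability; downstream statistics consume only
#' `excluded = FALSE` rows. No row is ever silently dropped.
#'
#' @param metrics data.frame of per-nucleus metrics (one row per nucleus,
#'   from [summarize_nucleus()]).
#' @param manual data.frame with columns `nucleus_id` and optionally
#'   `source_id` and `reason` (`"artifact_manual"` or
#'   `"cytoplasmic_overlap_manual"`), or a vector of nucleus ids. Ids must
#'   exist in `metrics`.
#' @param border_flags,saturation_flags logical vectors aligned with
#'   `metrics` rows (default all FALSE).
#' @return list with `table` (the cohort table: metrics + `excluded`,
#'   `exclusion_reason`) and `summary` (total, excluded count, percentage
#'   excluded rounded to one decimal, counts per reason).
#' @export
apply_exclusions <- function(metrics, manual = NULL,
                             border_flags = NULL, saturation_flags = NULL) {
  n <- nrow(metrics)
  if (is.null(border_flags)) border_flags <- rep(FALSE, n)
  if (is.null(saturation_flags)) saturation_flags <- rep(FALSE, n)
  stopifnot(length(border_flags) == n, length(saturation_flags) == n)
  reason <- rep("none", n)
  reason[saturation_flags] <- "saturation_auto"
  reason[border_flags] <- "border_auto"
  if (!is.null(manual)) {
    if (!is.data.frame(manual))
      manual <- data.frame(nucleus_id = manual, reason = "artifact_manual",
                           stringsAsFactors = FALSE)
    if (is.null(manual$reason)) manual$reason <- "artifact_manual"
    key_m <- if (!is.null(manual$source_id))
      paste(manual$source_id, manual$nucleus_id) else as.character(manual$nucleus_id)
    key_t <- if (!is.null(manual$source_id))
      paste(metrics$source_id, metrics$nucleus_id) else as.character(metrics$nucleus_id)
    hit <- match(key_m, key_t)
    if (anyNA(hit))
      stop("manual exclusion list references unknown nucleus id(s): ",
           paste(key_m[is.na(hit)], collapse = ", "))
    reason[hit] <- manual$reason  # manual verdicts override automatic flags
  }
  tab <- metrics
  tab$excluded <- reason != "none"
  tab$exclusion_reason <- reason
  pct <- round(100 * sum(tab$excluded) / n, 1)
  list(table = tab,
       summary = list(n_total = n, n_excluded = sum(tab$excluded),
                      pct_excluded = pct,
                      by_reason = table(reason[reason != "none"])))
}

# binary 26-neighborhood dilation by whole-array shifts
dilate_26 <- function(mask, iterations = 1L) {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zs <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      xs <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
      out <- out | mask[zs, ys, xs, drop = FALSE]
    }
    mask <- out
  }
  mask
}

#' Flag pronounced cytoplasmic labeling (reproducible surrogate)
#'
#' The published analysis scored cytoplasmic labeling visually. As a
#' reproducible surrogate, a nucleus is flagged when the median protein
#' intensity in a 3-voxel shell just outside the nucleus mask reaches
#' `ratio_threshold` times the median intensity inside it. The flag feeds
#' the categorical (contingency) analysis only; it never excludes a nucleus
#' automatically. The flagged set shrinks monotonically as the threshold
#' rises.
#'
#' @param protein_crop [channel_stack] or 3D array of the protein channel
#'   crop.
#' @param nucleus_mask matching 3D logical array.
#' @param ratio_threshold shell/interior median ratio (default 0.5).
#' @return TRUE/FALSE, or `NA` (with a warning) when the nucleus fills the
#'   crop and no shell exists.
#' @export
flag_cytoplasmic <- function(protein_crop, nucleus_mask, ratio_threshold = 0.5) {
  vox <- if (inherits(protein_crop, "channel_stack")) protein_crop$voxels else protein_crop
  stopifnot(identical(dim(vox), dim(nucleus_mask)))
  shell <- dilate_26(nucleus_mask, 3L) & !nucleus_mask
  if (!any(shell)) {
    warning("nucleus fills the crop: no cytoplasmic shell, flag undetermined")
    return(NA)
  }
  stats::median(vox[shell]) >= ratio_threshold * stats::median(vox[nucleus_mask])
}
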