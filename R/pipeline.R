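#' Run the full three-stage pipeline over a set of stacks
#'
#' For every input stack: (1) nuclei are segmented from the DAPI channel and
#' cropped; (2) bodies are segmented in each nucleus crop (3D Gaussian blur,
#' prominence-based 3D maxima detection, seeded geodesic threshold
#' segmentation, size filter); (3) per-body and per-nucleus quantitative
#' parameters are extracted. Manual and automatic exclusions are applied
#' (excluded nuclei stay in the table, flagged), and the cohort table,
#' per-body table, optional label images and a JSON run log are written.
#'
#' The run is deterministic: identical inputs, configuration and seed yield
#' byte-identical tabular outputs.
#'
#' @param config a [pipeline_config()].
#' @param stack_paths character vector of TIFF paths (2-channel stacks).
#' @param output_dir directory for outputs; created if needed.
#' @param write_labels write per-nucleus body label TIFFs (default TRUE).
#' @param write_crops write per-nucleus 2-channel crop TIFFs (default FALSE).
#' @return list with `table` (cohort data.frame), `bodies` (per-body
#'   data.frame), `exclusion_summary`, and `log` (per-stage counts).
#' @export
run_pipeline <- function(config, stack_paths, output_dir,
                         write_labels = TRUE, write_crops = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  metrics <- NULL; all_bodies <- NULL
  border_flags <- logical(); saturation_flags <- logical()
  log <- list(stacks = list(), seed = config$seed)
  next_id <- 0L

  for (path in stack_paths) {
    stacks <- tryCatch(
      read_stack(path, channel_roles = config$channel_roles),
      error = function(e) stop("stage 'read' failed for ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    roles <- vapply(stacks, function(s) s$channel_role, character(1))
    protein <- stacks[[match("protein", roles)]]
    dapi <- stacks[[match("dapi", roles)]]
    src <- protein$source_id
    group <- if (src %in% names(config$groups)) config$groups[[src]] else NA_character_

    labels <- segment_nuclei(dapi, config$nucleus)
    n_nuclei <- max(labels)
    if (n_nuclei == 0L) {
      warning("no nuclei found in ", src)
      log$stacks[[src]] <- list(n_nuclei = 0L, n_bodies = 0L,
                                rescale = attr(protein, "rescale"))
      next
    }
    records <- crop_nuclei(protein, dapi, labels, config$nucleus)
    # blur the whole field once: blurring isolated crops would truncate the
    # smoothing context at the crop faces and distort the field near them
    blurred_full <- gaussian_blur_3d(protein, config$segmentation$sigma_um)
    n_bodies_img <- 0L
    for (rec in records) {
      next_id <- next_id + 1L
      vs <- rec$protein_crop$voxel_size
      cd <- dim(rec$nucleus_mask)
      blurred <- blurred_full[rec$crop_origin[1] + seq_len(cd[1]) - 1L,
                              rec$crop_origin[2] + seq_len(cd[2]) - 1L,
                              rec$crop_origin[3] + seq_len(cd[3]) - 1L,
                              drop = FALSE]
      seeds <- detect_maxima_3d(blurred, config$segmentation, rec$nucleus_mask,
                                vs, raw = rec$protein_crop$voxels)
      body_labels <- segment_bodies(rec$protein_crop$voxels, blurred, seeds,
                                    config$segmentation, rec$nucleus_mask, vs)
      bodies <- measure_bodies(body_labels, rec$protein_crop$voxels, vs,
                               nucleus_id = next_id)
      n_bodies_img <- n_bodies_img + nrow(bodies)
      cyto <- flag_cytoplasmic(rec$protein_crop, rec$nucleus_mask,
                               config$cytoplasmic_ratio)
      row <- summarize_nucleus(bodies, group = group, cytoplasmic_flag = cyto,
                               nucleus_id = next_id, source_id = src)
      row$nucleus_label <- rec$nucleus_id
      metrics <- rbind(metrics, row)
      if (nrow(bodies)) all_bodies <- rbind(all_bodies, bodies)
      border_flags <- c(border_flags, rec$border_touching &&
                          config$nucleus$exclude_border)
      sat <- mean(rec$protein_crop$voxels[rec$nucleus_mask] == 255L)
      saturation_flags <- c(saturation_flags, sat > 0.01)
      if (write_labels)
        write_label_stack(body_labels,
                          file.path(output_dir,
                                    sprintf("%s_n%d_labels.tif", src, rec$nucleus_id)))
      if (write_crops)
        write_stack(list(rec$protein_crop, rec$dapi_crop),
                    file.path(output_dir,
                              sprintf("%s_n%d.ome.tif", src, rec$nucleus_id)))
    }
    log$stacks[[src]] <- list(n_nuclei = n_nuclei, n_bodies = n_bodies_img,
                              rescale = attr(protein, "rescale"))
  }

  csv_path <- file.path(output_dir, "cohort.csv")
  if (is.null(metrics)) {
    warning("pipeline produced an empty cohort")
    writeLines(paste(cohort_columns, collapse = ","), csv_path)
    empty <- utils::read.csv(text = paste(cohort_columns, collapse = ","))
    log$exclusions <- list(n_total = 0L, n_excluded = 0L, pct_excluded = NA)
    jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(list(table = empty, bodies = NULL,
                exclusion_summary = log$exclusions, log = log))
  }
  manual <- config$exclusions
  if (!is.null(manual)) {
    # manual lists address nuclei as (source_id, per-image nucleus label);
    # translate to the cohort-wide nucleus_id
    hit <- match(paste(manual$source_id, manual$nucleus_id),
                 paste(metrics$source_id, metrics$nucleus_label))
    if (anyNA(hit))
      stop("manual exclusion list references unknown nuclei: ",
           paste(paste(manual$source_id, manual$nucleus_id)[is.na(hit)],
                 collapse = ", "))
    manual <- data.frame(nucleus_id = metrics$nucleus_id[hit],
                         reason = manual$reason %||% "artifact_manual",
                         stringsAsFactors = FALSE)
  }
  excl <- apply_exclusions(metrics, manual, border_flags, saturation_flags)
  write_cohort_table(excl$table, csv_path)
  if (!is.null(all_bodies))
    utils::write.csv(all_bodies, file.path(output_dir, "objects.csv"),
                     row.names = FALSE)
  log$exclusions <- excl$summary[c("n_total", "n_excluded", "pct_excluded")]
  jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(table = excl$table, bodies = all_bodies,
       exclusion_summary = excl$summary, log = log)
}
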