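#' Synthetic cohort specification
#'
#' Defines the generative model for two-channel 3D stacks with planted
#' ground truth: ellipsoidal nuclei rendered in the DAPI channel with
#' embedded high-intensity dense-chromatin blobs, and punctate bodies in the
#' protein channel as isotropic (in physical units) 3D Gaussian spots over a
#' diffuse nucleoplasmic background, with additive Gaussian noise, clipped
#' to the 8-bit range.
#'
#' The default cohort mirrors the published study design: three ordered age
#' groups of 54 / 33 / 42 nuclei across 18 images, with Poisson body counts
#' of decreasing mean (8 / 6 / 4.5) and per-group cytoplasmic-labeling
#' probabilities (0.167, 0.152, 0). Geometry and intensity defaults are
#' chosen so that every planted body is recoverable by the default analysis
#' parameters (sigma = 1 um blur, noise tolerance 0.25, threshold 16): under
#' a 1 um smoothing scale, two spots are resolvable as separate maxima only
#' when ~3 um apart, which fixes the minimum body spacing and in turn the
#' nucleus size needed to host the largest body counts. See the methods
#' vignette for this detectability analysis.
#'
#' @param n_images number of field-of-view images in the cohort.
#' @param group_sizes named integer vector of nuclei per ordered group.
#' @param body_count_means Poisson mean body count per group (same order).
#' @param body_count_cap hard cap on sampled counts (packing feasibility).
#' @param nucleus_semiaxes_z,nucleus_semiaxes_xy sampling ranges (um) for
#'   the nucleus ellipsoid semi-axes.
#' @param body_fwhm_um range of spot full-widths at half maximum (um).
#' @param body_peak_intensity range of spot peak amplitudes (a.u. above the
#'   nucleoplasmic background).
#' @param min_body_spacing_um minimum pairwise distance between planted
#'   centers (um); must be at least twice the maximum body radius.
#' @param background_nucleoplasm,background_outside protein-channel levels
#'   (a.u.) inside / outside the nucleus.
#' @param dapi_level,dapi_outside,dense_level DAPI-channel levels (a.u.).
#' @param dense_n_blobs,dense_blob_radius_um dense-chromatin blob count and
#'   radius range (um).
#' @param cytoplasmic_fraction per-group probability of pronounced
#'   cytoplasmic labeling.
#' @param cytoplasmic_haze added intensity (a.u.) in a perinuclear shell for
#'   cytoplasmic-positive cells.
#' @param noise_sigma additive Gaussian noise sd (a.u.), both channels.
#' @param ref_threshold analysis intensity threshold (a.u.) at which the
#'   ground-truth body diameter is defined (the planted diameter is the
#'   spot's super-threshold XY extent, which is what a threshold
#'   segmentation at that level measures).
#' @param voxel_size (dz, dy, dx) in um.
#' @param seed integer; fully determines the cohort.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images = 18L,
                           group_sizes = c(young = 54L, middle = 33L, old = 42L),
                           body_count_means = c(8, 6, 4.5),
                           body_count_cap = 16L,
                           nucleus_semiaxes_z = c(3.9, 4.3),
                           nucleus_semiaxes_xy = c(12.0, 13.0),
                           body_fwhm_um = c(0.85, 1.0),
                           body_peak_intensity = c(150, 200),
                           min_body_spacing_um = 3.5,
                           background_nucleoplasm = 8,
                           background_outside = 2,
                           dapi_level = 120,
                           dapi_outside = 3,
                           dense_level = 160,
                           dense_n_blobs = 3L,
                           dense_blob_radius_um = c(0.8, 1.2),
                           cytoplasmic_fraction = c(0.167, 0.152, 0),
                           cytoplasmic_haze = 10,
                           noise_sigma = 2,
                           ref_threshold = 16,
                           voxel_size = c(0.5, 0.2, 0.2),
                           seed = 1L) {
  stopifnot(length(group_sizes) >= 1L,
            length(body_count_means) == length(group_sizes),
            length(cytoplasmic_fraction) == length(group_sizes))
  lv <- c(dapi_level, dapi_outside, dense_level, background_nucleoplasm,
          background_outside, body_peak_intensity)
  if (any(lv < 0 | lv > 255)) stop("all intensity parameters must lie in [0, 255]")
  if (min_body_spacing_um < max(body_fwhm_um))
    stop("min_body_spacing_um must be at least twice the maximum body radius")
  structure(as.list(environment()), class = "synthetic_spec")
}

# largest planted-body radius at the reference analysis threshold: centers
# must stay this far inside the nucleus so bodies are not clipped
max_body_radius <- function(spec) {
  smax <- max(spec$body_fwhm_um) / (2 * sqrt(2 * log(2)))
  amax <- max(spec$body_peak_intensity)
  smax * sqrt(2 * log(amax / (spec$ref_threshold - spec$background_nucleoplasm)))
}

# dart-throwing placement of k centers inside the ellipsoid eroded by
# `margin`, pairwise >= spacing apart; physical (z,y,x) offsets from center
place_bodies <- function(k, semi, spacing, margin, max_attempts = 2000L * max(k, 1L)) {
  if (k == 0L) return(matrix(numeric(0), 0L, 3L))
  er <- semi - margin
  if (any(er <= 0)) stop("nucleus too small for the requested bodies")
  pts <- matrix(NA_real_, k, 3L)
  got <- 0L
  for (a in seq_len(max_attempts)) {
    p <- stats::runif(3, -er, er)
    if (sum((p / er)^2) > 1) next
    if (got > 0L) {
      d2 <- rowSums((pts[seq_len(got), , drop = FALSE] -
                     matrix(p, got, 3L, byrow = TRUE))^2)
      if (any(d2 < spacing^2)) next
    }
    got <- got + 1L
    pts[got, ] <- p
    if (got == k) return(pts)
  }
  stop("infeasible packing: could not place ", k, " bodies at spacing ",
       spacing, " um in this nucleus")
}

# noise-free rendering of one nucleus into local crop arrays (doubles);
# truth rows carry local voxel center coordinates
render_nucleus_core <- function(spec, n_bodies, cytoplasmic, semi) {
  vs <- spec$voxel_size
  pad <- 1.0
  dims <- as.integer(ceiling(2 * (semi + pad) / vs))
  center <- (dims + 1) / 2
  ax <- lapply(1:3, function(i) ((seq_len(dims[i]) - center[i]) * vs[i]))
  # normalized squared radius field of the ellipsoid
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
              (ax[[3]] / semi[3])^2, "+")
  inside <- r2 <= 1
  dapi <- array(spec$dapi_outside, dims)
  dapi[inside] <- spec$dapi_level
  protein <- array(spec$background_outside, dims)
  protein[inside] <- spec$background_nucleoplasm
  if (cytoplasmic) {
    shell_semi <- semi + 2.0
    r2s <- outer(outer((ax[[1]] / shell_semi[1])^2, (ax[[2]] / shell_semi[2])^2, "+"),
                 (ax[[3]] / shell_semi[3])^2, "+")
    shell <- (r2s <= 1) & !inside
    protein[shell] <- protein[shell] + spec$cytoplasmic_haze
  }
  # dense-chromatin blobs
  for (b in seq_len(spec$dense_n_blobs)) {
    rad <- stats::runif(1, spec$dense_blob_radius_um[1], spec$dense_blob_radius_um[2])
    ctr <- place_bodies(1L, semi, 0, rad + 0.2)
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                (ax[[3]] - ctr[3])^2, "+")
    dapi[d2 <= rad^2 & inside] <- spec$dense_level
  }
  # bodies
  margin <- max_body_radius(spec) + 0.1
  ctrs <- place_bodies(n_bodies, semi, spec$min_body_spacing_um, margin)
  truth <- data.frame(body = integer(0), z = integer(0), y = integer(0),
                      x = integer(0), fwhm_um = numeric(0), sigma_um = numeric(0),
                      peak = numeric(0), diameter_um = numeric(0))
  for (b in seq_len(n_bodies)) {
    fwhm <- stats::runif(1, spec$body_fwhm_um[1], spec$body_fwhm_um[2])
    sig <- fwhm / (2 * sqrt(2 * log(2)))
    amp <- stats::runif(1, spec$body_peak_intensity[1], spec$body_peak_intensity[2])
    # evaluate the spot only inside its 4-sigma support box
    rng <- lapply(1:3, function(i) {
      w <- which(abs(ax[[i]] - ctrs[b, i]) <= 4 * sig)
      w[w >= 1 & w <= dims[i]]
    })
    g1 <- exp(-(ax[[1]][rng[[1]]] - ctrs[b, 1])^2 / (2 * sig^2))
    g2 <- exp(-(ax[[2]][rng[[2]]] - ctrs[b, 2])^2 / (2 * sig^2))
    g3 <- exp(-(ax[[3]][rng[[3]]] - ctrs[b, 3])^2 / (2 * sig^2))
    spot <- amp * outer(outer(g1, g2, "*"), g3, "*")
    protein[rng[[1]], rng[[2]], rng[[3]]] <-
      protein[rng[[1]], rng[[2]], rng[[3]]] + spot
    truth[b, ] <- list(b, which.min(abs(ax[[1]] - ctrs[b, 1])),
                       which.min(abs(ax[[2]] - ctrs[b, 2])),
                       which.min(abs(ax[[3]] - ctrs[b, 3])),
                       fwhm, sig, amp,
                       2 * sig * sqrt(2 * log(amp / (spec$ref_threshold -
                                                     spec$background_nucleoplasm))))
  }
  list(protein = protein, dapi = dapi, truth = truth, inside = inside, dims = dims)
}

add_noise_clip <- function(arr, noise_sigma) {
  if (noise_sigma > 0)
    arr <- arr + stats::rnorm(length(arr), 0, noise_sigma)
  array(as.integer(pmin(pmax(round(arr), 0), 255)), dim(arr))
}

#' Render one synthetic nucleus
#'
#' Draws nucleus geometry and planted bodies from the spec and renders the
#' two channels of a single-nucleus crop. Rendering is deterministic given
#' the R random-number state; seed with `set.seed()` (or use
#' [generate_cohort()], which seeds from the spec).
#'
#' @param spec a [synthetic_spec()].
#' @param group group label carried into the ground truth.
#' @param n_bodies planted body count; by default drawn from the group's
#'   Poisson distribution (capped at `body_count_cap`).
#' @param cytoplasmic logical; by default drawn from the group's
#'   cytoplasmic fraction.
#' @return list with `protein` and `dapi` ([channel_stack]s), `bodies`
#'   (ground-truth table: local voxel center coordinates, fwhm, peak and the
#'   planted diameter at the reference threshold) and `nucleus` (group,
#'   count, flag, semi-axes).
#' @export
render_nucleus <- function(spec, group = names(spec$group_sizes)[1],
                           n_bodies = NULL, cytoplasmic = NULL) {
  gi <- match(group, names(spec$group_sizes))
  if (is.na(gi)) stop("unknown group: ", group)
  if (is.null(n_bodies))
    n_bodies <- min(stats::rpois(1, spec$body_count_means[gi]), spec$body_count_cap)
  if (is.null(cytoplasmic))
    cytoplasmic <- stats::runif(1) < spec$cytoplasmic_fraction[gi]
  semi <- c(stats::runif(1, spec$nucleus_semiaxes_z[1], spec$nucleus_semiaxes_z[2]),
            stats::runif(1, spec$nucleus_semiaxes_xy[1], spec$nucleus_semiaxes_xy[2]),
            stats::runif(1, spec$nucleus_semiaxes_xy[1], spec$nucleus_semiaxes_xy[2]))
  core <- render_nucleus_core(spec, n_bodies, cytoplasmic, semi)
  list(protein = channel_stack(add_noise_clip(core$protein, spec$noise_sigma),
                               spec$voxel_size, "protein", "synthetic"),
       dapi = channel_stack(add_noise_clip(core$dapi, spec$noise_sigma),
                            spec$voxel_size, "dapi", "synthetic"),
       bodies = core$truth,
       nucleus = list(group = group, n_bodies = n_bodies,
                      cytoplasmic = cytoplasmic, semiaxes = semi))
}

# largest-remainder apportionment of n_images across groups
apportion_images <- function(group_sizes, n_images) {
  quota <- n_images * group_sizes / sum(group_sizes)
  base <- pmax(floor(quota), 1)
  left <- n_images - sum(base)
  if (left > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  base
}

#' Generate a full synthetic cohort with ground truth
#'
#' Allocates images to groups (largest-remainder proportional to group
#' size), distributes each group's nuclei evenly over its images, places
#' nuclei on a grid within each field of view, renders both channels, adds
#' noise and writes the stacks (when `dir` is given) as multi-page TIFFs
#' with metadata sidecars. The entire cohort is reproducible byte-for-byte
#' from `(spec, spec$seed)`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory for TIFFs; when `NULL` the voxel data are
#'   returned in memory instead (use only for small cohorts).
#' @return list with `manifest` (source_id, path, group, n_nuclei),
#'   `truth_nuclei` (one row per nucleus: image, paint order, group, planted
#'   count, cytoplasmic flag, global center-voxel coordinates),
#'   `truth_bodies` (one row per body with global voxel coordinates and
#'   planted diameters), `expected_table` (the cohort table a perfect
#'   pipeline would produce, nucleus ids in paint order) and, when
#'   `dir` is `NULL`, `images` (the channel stacks).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  vs <- spec$voxel_size
  gnames <- names(spec$group_sizes)
  imgs_per_group <- apportion_images(spec$group_sizes, spec$n_images)
  # per-image nucleus counts, evenly split within each group
  img_group <- rep(gnames, imgs_per_group)
  img_counts <- unlist(lapply(seq_along(gnames), function(g) {
    n <- spec$group_sizes[g]; m <- imgs_per_group[g]
    cnt <- rep(n %/% m, m)
    if (n %% m) cnt[seq_len(n %% m)] <- cnt[seq_len(n %% m)] + 1L
    cnt
  }))
  cell_um <- 2 * (max(spec$nucleus_semiaxes_xy) + 1.0) + 2.0
  manifest <- data.frame(source_id = character(), path = character(),
                         group = character(), n_nuclei = integer(),
                         stringsAsFactors = FALSE)
  truth_nuclei <- NULL; truth_bodies <- NULL
  images <- if (is.null(dir)) list() else NULL
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  for (im in seq_along(img_counts)) {
    k_nuc <- img_counts[im]
    grp <- img_group[im]
    gi <- match(grp, gnames)
    ncell <- ceiling(sqrt(k_nuc))
    lat_um <- ncell * cell_um
    nz <- as.integer(ceiling(2 * (max(spec$nucleus_semiaxes_z) + 2.0) / vs[1]))
    ny <- as.integer(ceiling(lat_um / vs[2]))
    nx <- as.integer(ceiling(lat_um / vs[3]))
    protein <- array(spec$background_outside * 1.0, c(nz, ny, nx))
    dapi <- array(spec$dapi_outside * 1.0, c(nz, ny, nx))
    src <- sprintf("img%03d", im)
    for (j in seq_len(k_nuc)) {
      row <- (j - 1L) %/% ncell; col <- (j - 1L) %% ncell
      n_b <- min(stats::rpois(1, spec$body_count_means[gi]), spec$body_count_cap)
      cyto <- stats::runif(1) < spec$cytoplasmic_fraction[gi]
      semi <- c(stats::runif(1, spec$nucleus_semiaxes_z[1], spec$nucleus_semiaxes_z[2]),
                stats::runif(1, spec$nucleus_semiaxes_xy[1], spec$nucleus_semiaxes_xy[2]),
                stats::runif(1, spec$nucleus_semiaxes_xy[1], spec$nucleus_semiaxes_xy[2]))
      core <- render_nucleus_core(spec, n_b, cyto, semi)
      cz <- as.integer(round((nz - core$dims[1]) / 2))
      cy <- as.integer(round(row * cell_um / vs[2] +
                             (cell_um / vs[2] - core$dims[2]) / 2))
      cx <- as.integer(round(col * cell_um / vs[3] +
                             (cell_um / vs[3] - core$dims[3]) / 2))
      zz <- cz + seq_len(core$dims[1]); yy <- cy + seq_len(core$dims[2])
      xx <- cx + seq_len(core$dims[3])
      # paste: nucleus interior and haze replace the field background
      sub_p <- protein[zz, yy, xx]; sub_d <- dapi[zz, yy, xx]
      repl <- core$protein != spec$background_outside
      sub_p[repl] <- core$protein[repl]
      repl_d <- core$dapi != spec$dapi_outside
      sub_d[repl_d] <- core$dapi[repl_d]
      protein[zz, yy, xx] <- sub_p; dapi[zz, yy, xx] <- sub_d
      truth_nuclei <- rbind(truth_nuclei, data.frame(
        source_id = src, paint_order = j, group = grp, n_bodies = n_b,
        cytoplasmic = cyto,
        center_z = cz + (core$dims[1] + 1) / 2,
        center_y = cy + (core$dims[2] + 1) / 2,
        center_x = cx + (core$dims[3] + 1) / 2,
        stringsAsFactors = FALSE))
      if (nrow(core$truth)) {
        tb <- core$truth
        tb$z <- tb$z + cz; tb$y <- tb$y + cy; tb$x <- tb$x + cx
        tb <- cbind(data.frame(source_id = src, paint_order = j,
                               stringsAsFactors = FALSE), tb)
        truth_bodies <- rbind(truth_bodies, tb)
      }
    }
    pstk <- channel_stack(add_noise_clip(protein, spec$noise_sigma), vs, "protein", src)
    dstk <- channel_stack(add_noise_clip(dapi, spec$noise_sigma), vs, "dapi", src)
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(src, ".tif"))
      write_stack(list(pstk, dstk), path)
    } else {
      images[[src]] <- list(protein = pstk, dapi = dstk)
    }
    manifest <- rbind(manifest, data.frame(source_id = src, path = path,
                                           group = grp,
                                           n_nuclei = as.integer(k_nuc),
                                           stringsAsFactors = FALSE))
  }
  expected <- data.frame(
    source_id = truth_nuclei$source_id,
    nucleus_id = truth_nuclei$paint_order,
    group = truth_nuclei$group,
    n_bodies = truth_nuclei$n_bodies,
    cytoplasmic_flag = truth_nuclei$cytoplasmic,
    stringsAsFactors = FALSE)
  out <- list(manifest = manifest, truth_nuclei = truth_nuclei,
              truth_bodies = truth_bodies, expected_table = expected)
  if (is.null(dir)) out$images <- images
  out
}
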