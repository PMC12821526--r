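# Fixture builders and independent oracles shared across test files.

# ellipsoid stack: intensity `value` inside an ellipsoid of the given
# physical semi-axes (um) centered at `center` (voxels), background `bg`
make_ellipsoid <- function(dims, voxel_size, semi, value = 120, bg = 0,
                           center = (dims + 1) / 2) {
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - center[i]) * voxel_size[i])
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
              (ax[[3]] / semi[3])^2, "+")
  arr <- array(bg, dims)
  arr[r2 <= 1] <- value
  arr
}

dapi_stack <- function(voxels, voxel_size = c(0.5, 0.2, 0.2), id = "fix") {
  channel_stack(voxels, voxel_size, "dapi", id)
}
protein_stack <- function(voxels, voxel_size = c(0.5, 0.2, 0.2), id = "fix") {
  channel_stack(voxels, voxel_size, "protein", id)
}

# Independent brute-force seed oracle for small grids (<= 16^3): local
# maxima by direct neighborhood scan; prominence from pairwise saddle
# heights found by level-set connectivity (BFS at each candidate level);
# greedy distance suppression re-derived from the rule's statement.
oracle_seeds <- function(values, mask, tol, threshold, voxel_size, gate = values) {
  d <- dim(values)
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  inb <- function(p) all(p >= 1) && all(p <= d)
  neighbors <- function(p) {
    out <- list()
    for (r in seq_len(nrow(nb))) {
      q <- p + nb[r, ]
      if (inb(q) && mask[q[1], q[2], q[3]]) out[[length(out) + 1L]] <- q
    }
    out
  }
  vox <- which(mask, arr.ind = TRUE)
  is_max <- logical(nrow(vox))
  for (i in seq_len(nrow(vox))) {
    p <- vox[i, ]
    vals <- vapply(neighbors(p), function(q) values[q[1], q[2], q[3]], numeric(1))
    is_max[i] <- all(values[p[1], p[2], p[3]] >= vals)
  }
  cand <- vox[is_max, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(z = integer(), y = integer(), x = integer()))
  lex <- (cand[, 1] * d[2] + cand[, 2]) * d[3] + cand[, 3]
  v <- values[cand]
  # plateau dedup: equal-value candidates in one connected plateau count
  # once, represented by the lexicographically first voxel
  keep <- rep(TRUE, nrow(cand))
  for (val in unique(v)) {
    comp <- label_components(mask & (values == val), 26L)
    ids <- which(v == val)
    for (cc in unique(comp[cand[ids, , drop = FALSE]])) {
      members <- ids[comp[cand[ids, , drop = FALSE]] == cc]
      if (length(members) > 1L)
        keep[setdiff(members, members[which.min(lex[members])])] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; v <- v[keep]; lex <- lex[keep]
  # saddle height between candidates i,j = highest level L at which both lie
  # in the same 26-connected component of {values >= L}; one descending sweep
  n <- nrow(cand)
  sad <- matrix(-Inf, n, n)
  resolved <- diag(TRUE, n)
  for (L in sort(unique(values[mask]), decreasing = TRUE)) {
    comp <- label_components(mask & (values >= L), 26L)
    cc <- comp[cand]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!resolved[i, j] && cc[i] > 0L && cc[i] == cc[j]) {
        sad[i, j] <- sad[j, i] <- L
        resolved[i, j] <- resolved[j, i] <- TRUE
      }
    }
    if (all(resolved)) break
  }
  prom <- numeric(n)
  for (i in seq_len(n)) {
    higher <- which(v > v[i] | (v == v[i] & lex < lex[i]))
    prom[i] <- if (!length(higher)) Inf else v[i] - max(sad[i, higher])
  }
  ok <- prom >= tol & gate[cand] >= threshold
  cand <- cand[ok, , drop = FALSE]; v <- v[ok]; lex <- lex[ok]
  ord <- order(-v, lex)
  cand <- cand[ord, , drop = FALSE]
  acc <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (j in which(acc)) {
      dxy <- sqrt(sum(((cand[i, 2:3] - cand[j, 2:3]) * voxel_size[2:3])^2))
      dz <- abs(cand[i, 1] - cand[j, 1]) * voxel_size[1]
      if (dxy < 0.5 && dz < 0.5) { conflict <- TRUE; break }
    }
    acc[i] <- !conflict
  }
  data.frame(z = cand[acc, 1], y = cand[acc, 2], x = cand[acc, 3])
}

# run the spot-segmentation stages on a rendered single-nucleus stack,
# blurring the full rendered field (the pipeline's convention)
segment_rendered <- function(r, np = nucleus_params(), sp = segmentation_params()) {
  labs <- segment_nuclei(r$dapi, np)
  if (max(labs) == 0L) return(NULL)
  recs <- crop_nuclei(r$protein, r$dapi, labs, np)
  rec <- recs[[1]]
  vs <- rec$protein_crop$voxel_size
  blf <- gaussian_blur_3d(r$protein, sp$sigma_um)
  cd <- dim(rec$nucleus_mask)
  bl <- blf[rec$crop_origin[1] + seq_len(cd[1]) - 1L,
            rec$crop_origin[2] + seq_len(cd[2]) - 1L,
            rec$crop_origin[3] + seq_len(cd[3]) - 1L, drop = FALSE]
  seeds <- detect_maxima_3d(bl, sp, rec$nucleus_mask, vs,
                            raw = rec$protein_crop$voxels)
  labels <- segment_bodies(rec$protein_crop$voxels, bl, seeds, sp,
                           rec$nucleus_mask, vs)
  list(record = rec, blurred = bl, seeds = seeds, labels = labels,
       bodies = measure_bodies(labels, rec$protein_crop$voxels, vs))
}

# small shared synthetic cohort (3 images), built once per test run
small_cohort_spec <- function(seed = 303L) {
  synthetic_spec(n_images = 3L,
                 group_sizes = c(young = 4L, middle = 3L, old = 3L),
                 seed = seed)
}

# built once per test session; helpers are re-sourced per file, so the cache
# lives in the session tempdir rather than in this environment
get_small_cohort <- function() {
  dir <- file.path(tempdir(), "nbq_small_cohort")
  cache <- file.path(dir, "cohort_cache.rds")
  if (file.exists(cache)) return(readRDS(cache))
  cohort <- generate_cohort(small_cohort_spec(), dir)
  saveRDS(cohort, cache)
  cohort
}
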