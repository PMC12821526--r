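test_that("blurring a constant image returns it unchanged", {
  vs <- c(0.5, 0.25, 0.25)
  out <- gaussian_blur_3d(array(100, c(10, 12, 14)), 1.0, vs)
  expect_equal(range(out), c(100, 100), tolerance = 1e-12)
})

test_that("an impulse blurs to the closed-form discrete Gaussian", {
  vs <- c(0.25, 0.25, 0.25)          # isotropic: per-axis sigma = 4 voxels
  dims <- c(41, 41, 41)
  img <- array(0, dims); img[21, 21, 21] <- 255
  out <- gaussian_blur_3d(img, 1.0, vs)
  # value at the impulse: 255 * (2*pi*16)^(-3/2)
  expect_equal(out[21, 21, 21], 255 * (2 * pi * 16)^(-3 / 2), tolerance = 0.01)
  # closed form on the whole grid, 1% relative at the center plane
  i <- -20:20
  g <- dnorm(i, sd = 4); g <- g / sum(g)
  expected <- 255 * outer(outer(g, g), g)
  expect_equal(out, array(expected, dims), tolerance = 0.01)
  # total intensity conserved for structures >= 4 sigma from all faces
  expect_equal(sum(out), 255, tolerance = 0.005 * 255)
})

test_that("blur respects voxel anisotropy", {
  vs <- c(0.5, 0.25, 0.25)            # z sigma 2 vox, lateral sigma 4 vox
  dims <- c(31, 41, 41)
  img <- array(0, dims); img[16, 21, 21] <- 255
  out <- gaussian_blur_3d(img, 1.0, vs)
  # equal physical offsets give equal response: 2 z-voxels = 4 xy-voxels = 1 um
  expect_equal(out[18, 21, 21], out[16, 25, 21], tolerance = 1e-9)
  expect_gt(out[17, 21, 21], out[16, 23, 21] - 1e-9)  # 0.5 um z vs 0.5 um y
})

test_that("single and well-separated spots yield the expected seeds", {
  vs <- c(0.5, 0.25, 0.25)
  dims <- c(20, 60, 60)
  mask <- array(TRUE, dims)
  sp <- segmentation_params(sigma_um = 0.5, noise_tolerance = 0.25,
                            intensity_threshold = 2, threshold_on = "blurred")
  one <- array(0, dims); one[10, 30, 30] <- 255
  bl <- gaussian_blur_3d(one, 0.5, vs)
  seeds <- detect_maxima_3d(bl, sp, mask, vs)
  expect_identical(nrow(seeds), 1L)
  expect_true(all(abs(unlist(seeds[1, c("z", "y", "x")]) - c(10, 30, 30)) <= 1))

  # two spots 2 um apart -> 2 seeds
  two <- array(0, dims); two[10, 30, 20] <- 255; two[10, 30, 28] <- 255
  bl <- gaussian_blur_3d(two, 0.5, vs)
  expect_identical(nrow(detect_maxima_3d(bl, sp, mask, vs)), 2L)
})

test_that("seeds closer than the minimum distance collapse to the brighter", {
  vs <- c(0.5, 0.1, 0.1)
  dims <- c(8, 40, 40)
  img <- array(0, dims)
  img[4, 20, 18] <- 200; img[4, 20, 21] <- 200   # 0.3 um apart in x
  # blur small enough that both spots stay distinct local maxima, so the
  # collapse below is the distance rule, not peak merging
  sp <- segmentation_params(sigma_um = 0.05, noise_tolerance = 0.25,
                            intensity_threshold = 5, threshold_on = "blurred")
  bl <- gaussian_blur_3d(img, 0.05, vs)
  seeds <- detect_maxima_3d(bl, sp, mask <- array(TRUE, dims), vs)
  expect_identical(nrow(seeds), 1L)
  # tie in brightness resolves to the lexicographically first position
  expect_identical(unlist(seeds[1, c("z", "y", "x")], use.names = FALSE),
                   c(4L, 20L, 18L))
})

test_that("seed detection matches the brute-force prominence oracle", {
  set.seed(31)
  vs <- c(0.5, 0.5, 0.5)
  for (rep in 1:12) {
    dims <- c(sample(5:9, 1), sample(5:9, 1), sample(5:9, 1))
    vals <- array(sample(0:11, prod(dims), replace = TRUE) +
                    round(runif(prod(dims)), 3), dims)
    mask <- array(TRUE, dims)
    if (rep %% 3 == 0) mask[, , 1:2] <- FALSE  # non-trivial domain
    tol <- sample(c(0.25, 1, 2.5), 1)
    sp <- segmentation_params(sigma_um = 1, noise_tolerance = tol,
                              intensity_threshold = 4, threshold_on = "blurred")
    got <- detect_maxima_3d(vals, sp, mask, vs)
    exp <- oracle_seeds(vals, mask, tol, 4, vs)
    got_key <- sort(paste(got$z, got$y, got$x))
    exp_key <- sort(paste(exp$z, exp$y, exp$x))
    expect_identical(got_key, exp_key)
  }
})

test_that("plateau maxima produce a single lexicographically-first seed", {
  dims <- c(5, 7, 7)
  vals <- array(0, dims)
  vals[3, 3:4, 3:4] <- 9   # 4-voxel plateau
  sp <- segmentation_params(sigma_um = 1, noise_tolerance = 0.25,
                            intensity_threshold = 5, threshold_on = "blurred")
  seeds <- detect_maxima_3d(vals, sp, array(TRUE, dims), c(0.5, 0.5, 0.5))
  expect_identical(nrow(seeds), 1L)
  expect_identical(unlist(seeds[1, c("z", "y", "x")], use.names = FALSE),
                   c(3L, 3L, 3L))
})

test_that("raising noise tolerance or threshold is monotone", {
  set.seed(17)
  vs <- c(0.5, 0.25, 0.25)
  spec <- synthetic_spec()
  r <- render_nucleus(spec, "young", n_bodies = 8)
  seg <- segment_rendered(r)
  rec <- seg$record
  # seed count never grows as noise tolerance rises
  prev <- Inf
  for (tol in c(0.1, 0.25, 1, 3, 8)) {
    sp <- segmentation_params(noise_tolerance = tol)
    seeds <- detect_maxima_3d(seg$blurred, sp, rec$nucleus_mask,
                              rec$protein_crop$voxel_size,
                              raw = rec$protein_crop$voxels)
    expect_lte(nrow(seeds), prev)
    prev <- nrow(seeds)
  }
  # total body volume never grows as the intensity threshold rises
  prev <- Inf
  for (th in c(10, 16, 40, 90, 160)) {
    sp <- segmentation_params(intensity_threshold = th)
    seeds <- detect_maxima_3d(seg$blurred, sp, rec$nucleus_mask,
                              rec$protein_crop$voxel_size,
                              raw = rec$protein_crop$voxels)
    labels <- segment_bodies(rec$protein_crop$voxels, seg$blurred, seeds, sp,
                             rec$nucleus_mask, rec$protein_crop$voxel_size)
    vol <- sum(labels > 0)
    expect_lte(vol, prev)
    prev <- vol
  }
})

test_that("segmentation partitions the domain among seeds", {
  vs <- c(0.5, 0.25, 0.25)
  dims <- c(16, 60, 60)
  mask <- array(TRUE, dims)
  # dumbbell: two lobes joined by a thin bridge, all super-threshold
  img <- array(0, dims)
  img[6:10, 26:34, 15:25] <- 100
  img[6:10, 26:34, 35:45] <- 100
  img[8, 30, 26:34] <- 60
  sp <- segmentation_params(sigma_um = 0.4, noise_tolerance = 0.25,
                            intensity_threshold = 20, threshold_on = "raw",
                            min_object_size_um = 0.1)
  bl <- gaussian_blur_3d(img, 0.4, vs)
  seeds <- data.frame(z = c(8L, 8L), y = c(30L, 30L), x = c(20L, 40L))
  seeds$index <- seeds$z + dims[1] * ((seeds$y - 1) + dims[2] * (seeds$x - 1))
  seeds$blurred_value <- bl[seeds$index]
  labels <- segment_bodies(img, bl, seeds, sp, mask, vs)
  domain <- img >= 20
  expect_identical(max(labels), 2L)
  expect_true(all(labels[domain] > 0L))           # union = reachable domain
  expect_true(all(domain[labels > 0L]))           # bodies inside the domain
  # geodesic midline: bridge voxels split between the two lobes by distance
  expect_true(all(labels[8, 30, 26:29] == 1L))
  expect_true(all(labels[8, 30, 31:34] == 2L))
  # each body is 26-connected and contains its seed
  for (k in 1:2) {
    comp <- label_components(labels == k, 26L)
    expect_identical(max(comp), 1L)
    expect_identical(labels[seeds$index[k]], k)
  }
})

test_that("the minimum-size filter uses mean XY bounding-box extent", {
  vs <- c(0.5, 0.2, 0.2)
  dims <- c(8, 20, 20)
  img <- array(0, dims); img[4, 10, 10] <- 200    # single-voxel speck
  mask <- array(TRUE, dims)
  bl <- gaussian_blur_3d(img, 0.3, vs)
  seeds <- data.frame(z = 4L, y = 10L, x = 10L)
  seeds$index <- 4L + dims[1] * (9L + dims[2] * 9L)
  seeds$blurred_value <- bl[seeds$index]
  keep <- segmentation_params(sigma_um = 0.3, intensity_threshold = 50,
                              threshold_on = "raw", min_object_size_um = 0.1)
  drop <- segmentation_params(sigma_um = 0.3, intensity_threshold = 50,
                              threshold_on = "raw", min_object_size_um = 0.3)
  expect_identical(max(segment_bodies(img, bl, seeds, keep, mask, vs)), 1L)
  expect_identical(max(segment_bodies(img, bl, seeds, drop, mask, vs)), 0L)
})

test_that("seeds outside the segmentation domain are dropped with a warning", {
  vs <- c(0.5, 0.2, 0.2)
  dims <- c(8, 20, 20)
  img <- array(0L, dims); img[4, 10, 10] <- 200L
  bl <- gaussian_blur_3d(img, 0.3, vs)
  seeds <- data.frame(z = c(4L, 2L), y = c(10L, 3L), x = c(10L, 3L))
  seeds$index <- seeds$z + dims[1] * ((seeds$y - 1) + dims[2] * (seeds$x - 1))
  seeds$blurred_value <- bl[seeds$index]
  sp <- segmentation_params(sigma_um = 0.3, intensity_threshold = 50,
                            threshold_on = "raw")
  expect_warning(labels <- segment_bodies(img, bl, seeds, sp,
                                          array(TRUE, dims), vs), "dropped")
  expect_identical(max(labels), 1L)
})

test_that("watershed assignment mode also partitions the domain", {
  vs <- c(0.5, 0.25, 0.25)
  dims <- c(12, 40, 40)
  img <- array(0, dims)
  img[5:7, 18:22, 8:16] <- 100; img[5:7, 18:22, 24:32] <- 100
  img[6, 20, 17:23] <- 60
  bl <- gaussian_blur_3d(img, 0.4, vs)
  sp <- segmentation_params(sigma_um = 0.4, intensity_threshold = 20,
                            threshold_on = "raw", assignment = "watershed")
  seeds <- data.frame(z = c(6L, 6L), y = c(20L, 20L), x = c(12L, 28L))
  seeds$index <- seeds$z + dims[1] * ((seeds$y - 1) + dims[2] * (seeds$x - 1))
  seeds$blurred_value <- bl[seeds$index]
  labels <- segment_bodies(img, bl, seeds, sp, array(TRUE, dims), vs)
  expect_identical(max(labels), 2L)
  expect_identical(sort(unique(as.integer(labels[img >= 20]))), c(1L, 2L))
})
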