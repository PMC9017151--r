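# Primary descriptors: corrections, filters, masks, zero level, height map,
# volume, spot detection, Z-lines.

test_that("vignetting gain is 1 at the centre, radially decreasing, and matches the formula", {
  img <- matrix(1, 64, 64)
  out <- vignetting_correct(img)
  # centre pixel keeps (almost) full value, corners attenuated
  expect_gt(out[33, 33], max(out[1, 1], out[64, 64]))
  expect_equal(out[33, 33], 1) # pixel (32, 32) sits at the centre: gain e^0
  # brute-force per-pixel oracle on a ramp image
  ramp <- matrix(rep(1:64, each = 64), 64) / 64
  got <- vignetting_correct(ramp)
  s <- sqrt(32^2 * 32^2)
  want <- ramp
  for (i in 1:64) for (j in 1:64) {
    d <- sqrt((j - 1 - 32)^2 + (i - 1 - 32)^2)
    want[i, j] <- ramp[i, j] * exp(-d / s)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("contrast stretching maps linearly onto 0..255 and guards constants", {
  expect_equal(as.vector(stretch_contrast(matrix(c(0, 5, 10), 1))),
               c(0, 127.5, 255))
  m <- matrix(c(0, 100, 255, 30), 2)
  expect_equal(stretch_contrast(m), m)
  expect_warning(z <- stretch_contrast(matrix(7, 3, 3)), "constant")
  expect_true(all(z == 0))
})

test_that("local entropy filter equals the naive histogram oracle", {
  expect_equal(local_entropy_filter(matrix(3, 10, 10), 4),
               matrix(0, 10, 10))
  # checkerboard of 2 levels: interior pixels with an even window see 50/50
  cb <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)
  e <- local_entropy_filter(cb, 4)
  expect_equal(e[3:10, 3:10], matrix(1, 8, 8))
  # random 8-level image vs double-loop oracle
  set.seed(42)
  img <- matrix(sample(0:7, 32 * 32, replace = TRUE), 32)
  expect_equal(local_entropy_filter(img, 5), entropy_oracle(img, 5),
               tolerance = 1e-12)
  expect_error(local_entropy_filter(img, 100), class = "fishspat_parameter_error")
})

test_that("cell mask recovers a textured disk and keeps the largest blob", {
  set.seed(11)
  sz <- 128
  truth <- disk_mask_fix(sz, 64, 64, 40)
  img <- matrix(5 + rnorm(sz * sz, 0, 2), sz, sz)
  img[truth] <- 60 + rnorm(sum(truth), 0, 25)
  m <- detect_cell_mask(image_stack(pmax(img, 0), "tubulin"))
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)

  # blank image fails loudly (after warning about the constant projection)
  expect_error(suppressWarnings(detect_cell_mask(image_stack(matrix(0, 64, 64), "tubulin"))),
               class = "fishspat_segmentation_error")

  # two disjoint textured blobs: only the larger is kept
  img2 <- matrix(5 + rnorm(sz * sz, 0, 2), sz, sz)
  big <- disk_mask_fix(sz, 40, 64, 30); small <- disk_mask_fix(sz, 100, 64, 12)
  img2[big] <- 60 + rnorm(sum(big), 0, 25)
  img2[small] <- 60 + rnorm(sum(small), 0, 25)
  m2 <- suppressWarnings(detect_cell_mask(image_stack(pmax(img2, 0), "tubulin")))
  expect_gt(sum(m2 & big) / sum(m2), 0.9)
  expect_lt(sum(m2 & small), 10)
})

test_that("nucleus mask via Otsu recovers a bright disk, clipped at borders", {
  set.seed(12)
  truth <- disk_mask_fix(64, 32, 32, 12)
  img <- matrix(10 + rnorm(64 * 64, 0, 3), 64, 64)
  img[truth] <- 100 + rnorm(sum(truth), 0, 10)
  m <- detect_nucleus_mask(image_stack(pmax(img, 0), "nucleus"))
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)

  # threshold quality: implementation's Otsu reaches the exhaustive maximum
  thr <- otsu_threshold(img)
  expect_gte(between_class_variance_at(img, thr),
             0.999 * otsu_best_variance(img))
  expect_true(all(img[truth] > thr))

  # nucleus touching the border is clipped, not an error
  truth2 <- disk_mask_fix(64, 2, 32, 12)
  img2 <- matrix(10 + rnorm(64 * 64, 0, 3), 64, 64)
  img2[truth2] <- 100 + rnorm(sum(truth2), 0, 10)
  m2 <- detect_nucleus_mask(image_stack(pmax(img2, 0), "nucleus"))
  expect_gte(sum(m2 & truth2) / sum(m2 | truth2), 0.85)
})

test_that("zero level is the argmax slice with lowest-index ties", {
  mk <- function(sums) {
    vox <- array(0, dim = c(2, 2, length(sums)))
    for (z in seq_along(sums)) vox[, , z] <- sums[z] / 4
    image_stack(vox, "tubulin")
  }
  expect_equal(compute_zero_level(mk(c(3, 9, 9, 1))), 1)
  expect_equal(compute_zero_level(mk(5)), 0)
  set.seed(9)
  sums <- runif(12)
  expect_equal(compute_zero_level(mk(sums)), which.max(sums) - 1)
  # permutation covariance
  perm <- sample(12)
  expect_equal(compute_zero_level(mk(sums[perm])), which(perm == which.max(sums)) - 1)
})

test_that("height maps recover cylinders and domes; volumes follow the voxel formula", {
  # cylinder: same bright disk on slices 1..4 above a dim zero slice
  sz <- 64
  disk <- disk_mask_fix(sz, 32, 32, 20)
  vox <- array(0, dim = c(sz, sz, 5))
  vox[, , 1][disk] <- 100
  for (z in 2:5) vox[, , z][disk] <- 100
  vox <- vox + array(abs(rnorm(length(vox), 0, 1)), dim(vox))
  st <- image_stack(vox, "tubulin")
  h <- compute_height_map(st, zero_level = 1)
  expect_equal(sort(unique(h[disk_mask_fix(sz, 32, 32, 15)])), 4)
  expect_true(all(h[!disk_mask_fix(sz, 32, 32, 25)] == 0))

  # dome: shrinking disks; per-pixel top slice equals the generator truth
  radii <- c(20, 16, 12, 6)
  vox2 <- array(0, dim = c(sz, sz, 4))
  for (z in 1:4) vox2[, , z][disk_mask_fix(sz, 32, 32, radii[z])] <- 100
  vox2 <- vox2 + array(abs(rnorm(length(vox2), 0, 1)), dim(vox2))
  h2 <- compute_height_map(image_stack(vox2, "tubulin"), zero_level = 0)
  want <- matrix(0, sz, sz)
  for (z in 1:4) want[disk_mask_fix(sz, 32, 32, radii[z])] <- z
  inner <- disk_mask_fix(sz, 32, 32, 19)
  expect_gte(mean(h2[inner] == want[inner]), 0.95)

  expect_error(compute_height_map(st, zero_level = 7),
               class = "fishspat_parameter_error")

  # volume formula
  hm <- matrix(0L, 4, 4); hm[2, 2] <- 2L
  expect_equal(cell_volume(hm), 2 * (1 / 9.75)^2 * 0.3)
  expect_equal(cell_volume(matrix(0L, 4, 4)), 0)
  expect_equal(cell_volume(hm, pixel_size_xy = 2 / 9.75), 4 * cell_volume(hm))
  # additivity over disjoint height maps
  hm2 <- matrix(0L, 4, 4); hm2[4, 4] <- 3L
  expect_equal(cell_volume(hm + hm2), cell_volume(hm) + cell_volume(hm2))
  expect_error(cell_volume(matrix(-1L, 2, 2)), class = "fishspat_validation_error")
})

test_that("sum intensity projection adds slices", {
  vox <- array(runif(3 * 4 * 4), dim = c(4, 4, 3))
  st <- image_stack(vox, "signal")
  want <- vox[, , 1] + vox[, , 2] + vox[, , 3]
  expect_equal(sum_intensity_projection(st), want)
  expect_equal(sum_intensity_projection(image_stack(vox[, , 1], "signal")), vox[, , 1])
})

test_that("spot detection meets recall/precision targets and is scale invariant", {
  set.seed(21)
  truth <- cbind(runif(20, 10, 118), runif(20, 10, 118), 0)
  st <- render_spot_image(truth, c(128, 128), psf_sigma = 1.5, peak = 10,
                          noise_sd = 1, seed = 77)
  det <- detect_spots(st)
  d <- as.matrix(dist(rbind(truth[, 1:2], det[, 1:2])))
  d <- d[1:20, 20 + seq_len(nrow(det)), drop = FALSE]
  recall <- mean(apply(d, 1, min) <= 2)
  precision <- mean(apply(d, 2, min) <= 2)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # relative threshold: scaling the image leaves the spot set unchanged
  st2 <- st; st2$voxels <- st$voxels * 7.3
  expect_equal(detect_spots(st2), det)

  # blank noise yields nothing
  blank <- image_stack(matrix(abs(rnorm(64 * 64, 0, 1)), 64), "signal")
  expect_equal(nrow(detect_spots(blank)), 0)

  # two spots 1 px apart merge into at least one detection
  pair <- rbind(c(30, 30, 0), c(31, 30, 0))
  stp <- render_spot_image(pair, c(64, 64), psf_sigma = 1.5, peak = 10,
                           noise_sd = 0.01, seed = 5)
  detp <- detect_spots(stp)
  expect_gte(nrow(detp), 1)
  expect_lte(nrow(detp), 2)

  # spots below a zero level are dropped
  tr3 <- cbind(runif(10, 10, 54), runif(10, 10, 54), rep(c(0, 3), 5))
  st3 <- render_spot_image(tr3, c(64, 64), n_slices = 4, noise_sd = 0.5, seed = 9)
  det3 <- detect_spots(st3, zero_level = 2)
  expect_true(all(det3[, 3] >= 2))
})

test_that("Z-line masks recover stripe count and positions", {
  fib <- make_striated_fiber(length = 300, width = 60, period = 15, seed = 4)
  ztrue <- fib$zline_masks[[1]]
  img <- matrix(2, 60, 300); img[unclass(ztrue)] <- 50
  set.seed(8)
  img <- img + matrix(abs(rnorm(60 * 300, 0, 5)), 60, 300) # ~10% noise
  zm <- detect_zline_mask(img)
  # stripe count within 1 of truth
  count_stripes <- function(m) length(fishspat:::.stripe_leading_edges(unclass(m)[30, ]))
  expect_lte(abs(count_stripes(zm) - count_stripes(ztrue)), 1)
  # stripe centres within 1 px of truth (via run centroids on a middle row)
  cent <- function(m) {
    r <- rle(unclass(m)[30, ]); e <- cumsum(r$lengths); s <- e - r$lengths + 1
    (s[r$values] + e[r$values]) / 2
  }
  cd <- cent(zm); ct <- cent(ztrue)
  matched <- vapply(ct, function(x) min(abs(cd - x)), numeric(1))
  expect_lte(median(matched), 1)
  expect_warning(z0 <- detect_zline_mask(matrix(3, 20, 20)), "constant")
  expect_equal(sum(z0), 0)
})
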