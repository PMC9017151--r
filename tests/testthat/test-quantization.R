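# Peripheral distance map, quadrants, fine-grained segments.

test_that("distance map on concentric disks splits the annulus equidistantly", {
  sz <- 221
  cell <- binary_mask(disk_mask_fix(sz, 110, 110, 100), "cell")
  nuc <- binary_mask(disk_mask_fix(sz, 110, 110, 20), "nucleus")
  cyto <- cytoplasm_mask(cell, nuc)
  dm <- peripheral_distance_map(cyto, nuc, c(110, 110))
  # pixel at radius 60 along the x axis sits on isoline 50
  expect_equal(dm$D[111, 171], 50L)
  # cell boundary -> 0; near the nucleus -> high isolines
  expect_equal(dm$D[111, 211], 0L)
  expect_gte(dm$D[111, 133], 96L)
  # D non-increasing along a ray
  ray <- dm$D[111, 131:210]
  ray <- ray[!is.na(ray)]
  expect_true(all(diff(ray) <= 0))
  # peripheral mask monotone in p
  for (p in c(10, 30, 70)) {
    expect_true(all(peripheral_mask(dm, p) <= peripheral_mask(dm, p + 20)))
  }
})

test_that("distance map agrees with the point-in-polygon oracle on a crossbow", {
  skel <- make_crossbow_cell(radius = 25, nucleus_radius = 7, mtoc_angle = 10)
  cyto <- cytoplasm_mask(skel$cell_mask, skel$nucleus_mask)
  dm <- peripheral_distance_map(cyto, skel$nucleus_mask, skel$nucleus_centroid)
  idx <- which(unclass(cyto), arr.ind = TRUE)
  want <- dmap_oracle(dm, idx[, 2] - 1, idx[, 1] - 1)
  got <- dm$D[idx]
  expect_gte(mean(got == want), 0.99)   # boundary-tie pixels may differ
  expect_lte(max(abs(got - want)), 1)
})

test_that("distance map rejects a centroid outside the nucleus", {
  skel <- make_crossbow_cell(radius = 25, nucleus_radius = 7)
  cyto <- cytoplasm_mask(skel$cell_mask, skel$nucleus_mask)
  expect_error(
    peripheral_distance_map(cyto, skel$nucleus_mask, skel$nucleus_centroid + 20),
    class = "fishspat_geometry_error"
  )
})

test_that("cumulative peripheral volumes are increasing and cover the cytoplasm", {
  rec <- crossbow_record(n_spots = 50, seed = 3, n_slices = 6)
  dm <- record_dmap(rec)
  expect_true(all(diff(dm$peripheral_volumes) >= 0))
  cyto <- cytoplasm_mask(rec$cell_mask, rec$nucleus_mask)
  want <- sum(rec$height_map[unclass(cyto)]) * rec$pixel_size_xy^2 * rec$z_step
  expect_equal(dm$peripheral_volumes[100], want, tolerance = 1e-9)
})

test_that("quadrant orientation equals the 360-way brute force and identities hold", {
  for (seed in 1:4) {
    rec <- crossbow_record(n_spots = 120, seed = seed, mtoc_angle = 37 * seed)
    q <- quadrantize(rec)
    oracle <- orientation_oracle(rec)
    expect_equal(q$orientation_deg, oracle$d)
    expect_equal(q$parts$t[1], oracle$t)
    # density normalization identity
    expect_equal(sum(q$parts$c * q$parts$a), q$area, tolerance = 1e-9)
    expect_equal(sum(q$parts$t), q$total)
    # Q1 contains the MTOC pixel
    expect_equal(q$quadrant_labels[round(rec$mtoc[2]) + 1, round(rec$mtoc[1]) + 1], 1L)
  }
})

test_that("a single spot in the MTOC direction lands in Q1 with the others empty", {
  skel <- make_crossbow_cell(radius = 40, nucleus_radius = 10, mtoc_angle = 0)
  sp <- rbind(c(skel$nucleus_centroid[1] + 30, skel$nucleus_centroid[2], 0))
  rec <- synthetic_cell_record(skel, spots = sp)
  q <- quadrantize(rec)
  expect_equal(q$parts$t, c(1, 0, 0, 0))
  expect_equal(q$parts$c[2:4], c(0, 0, 0))
  expect_equal(sum(q$parts$c * q$parts$a), q$area, tolerance = 1e-9)
})

test_that("symmetric patterns break orientation ties towards the lowest degree", {
  skel <- make_crossbow_cell(radius = 40, nucleus_radius = 10, mtoc_angle = 0,
                             stem = FALSE)
  ctr <- skel$nucleus_centroid
  # perfect 4-fold symmetric spots at 20, 110, 200, 290 degrees
  ang <- c(20, 110, 200, 290) * pi / 180
  sp <- cbind(ctr[1] + 25 * cos(ang), ctr[2] + 25 * sin(ang), 0)
  rec <- synthetic_cell_record(skel, spots = sp)
  q <- quadrantize(rec)
  oracle <- orientation_oracle(rec)
  expect_equal(q$orientation_deg, oracle$d)
  expect_equal(q$orientation_deg, 0L) # every orientation ties; lowest wins
})

test_that("rotating the cell by 90 degrees preserves the density multiset", {
  rec <- crossbow_record(n_spots = 140, seed = 6, mtoc_angle = 25)
  rot_mask <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE] # 90 deg cw
  h <- nrow(rec$cell_mask)
  rot_xy <- function(xy) cbind(h - 1 - xy[, 2], xy[, 1])
  cellr <- binary_mask(rot_mask(unclass(rec$cell_mask)), "cell")
  nucr <- binary_mask(rot_mask(unclass(rec$nucleus_mask)), "nucleus")
  spr <- cbind(rot_xy(rec$spots[, 1:2, drop = FALSE]), rec$spots[, 3])
  rec2 <- cell_record("rot", "mRNA", cell_mask = cellr, nucleus_mask = nucr,
                      mtoc = rot_xy(rbind(rec$mtoc))[1, ], spots = spr,
                      nucleus_centroid = rot_xy(rbind(rec$nucleus_centroid))[1, ])
  q1 <- quadrantize(rec)
  q2 <- quadrantize(rec2)
  expect_equal(sort(q1$parts$c), sort(q2$parts$c), tolerance = 1e-9)
})

test_that("3D quadrant densities equal 2D on a constant-height cell and sum to V", {
  skel <- make_crossbow_cell(radius = 40, nucleus_radius = 10, mtoc_angle = 80)
  skel$height_map <- matrix(0L, nrow(skel$cell_mask), ncol(skel$cell_mask))
  skel$height_map[unclass(skel$cell_mask)] <- 5L
  sp <- sample_poisson_spots(skel$cell_mask, 100, seed = 4)
  rec <- synthetic_cell_record(skel, spots = sp)
  q3 <- quadrantize_3d(rec)
  expect_equal(q3$parts$c3d, q3$parts$c, tolerance = 1e-9)
  expect_equal(sum(q3$parts$c3d * q3$parts$v), q3$volume, tolerance = 1e-9)
  # dome-shaped height: voxel-loop oracle over quadrant labels
  rec2 <- crossbow_record(n_spots = 100, seed = 5, n_slices = 7)
  q <- quadrantize_3d(rec2)
  vol_oracle <- vapply(1:4, function(k) {
    sum(rec2$height_map[q$quadrant_labels == k & !is.na(q$quadrant_labels)]) *
      rec2$pixel_size_xy^2 * rec2$z_step
  }, numeric(1))
  expect_equal(q$parts$v, vol_oracle, tolerance = 1e-9)
  # missing height map refuses
  rec3 <- crossbow_record(n_spots = 40, seed = 6)
  expect_error(quadrantize_3d(rec3), class = "fishspat_capability_error")
})

test_that("fine-grained segments partition the cytoplasm with unit mean density", {
  rec <- crossbow_record(n_spots = 4000, seed = 8)
  dm <- record_dmap(rec)
  fg <- fine_grained_segments(rec, dm, p = 3)
  expect_equal(nrow(fg$parts), 24)
  expect_equal(sum(fg$parts$c * fg$parts$a), fg$area, tolerance = 1e-9)
  # uniform spots: densities near 1
  expect_lt(max(abs(fg$parts$c - 1)), 0.35) # MC tolerance at ~170 spots/segment
  # p = 1 reduces to 8 sectors
  fg1 <- fine_grained_segments(rec, dm, p = 1)
  expect_equal(nrow(fg1$parts), 8)
  expect_equal(sum(fg1$parts$c * fg1$parts$a), fg1$area, tolerance = 1e-9)
  expect_error(fine_grained_segments(rec, dm, p = 0),
               class = "fishspat_parameter_error")
})

test_that("one hand-placed spot occupies exactly one fine-grained segment", {
  skel <- make_crossbow_cell(radius = 40, nucleus_radius = 10, mtoc_angle = 0)
  ctr <- skel$nucleus_centroid
  sp <- rbind(c(ctr[1] + 30, ctr[2], 0)) # on the MTOC ray, outer region
  rec <- synthetic_cell_record(skel, spots = sp)
  dm <- record_dmap(rec)
  fg <- fine_grained_segments(rec, dm, p = 3)
  expect_equal(sum(fg$parts$t > 0), 1)
  expect_equal(sum(fg$parts$t), 1)
  hit <- fg$parts[fg$parts$t > 0, ]
  expect_equal(hit$sector, 1) # MTOC sector
})
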