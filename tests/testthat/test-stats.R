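# Peripheral fraction, Nm, spread, MPI, profiles, colocalization, pooled
# deviation.

test_that("peripheral relative densities are 1 for uniform signal and exact at 100", {
  rec <- crossbow_record(n_spots = 3000, seed = 2)
  dm <- record_dmap(rec)
  v <- peripheral_density_vector(rec, dm)
  expect_equal(v[100], 1, tolerance = 1e-9)
  expect_lt(max(abs(v[20:100] - 1)), 0.25) # MC tolerance; inner regions small
  ser <- acquisition_series(list(rec))
  prof <- peripheral_fraction_profile(ser, list(dm))
  expect_s3_class(prof, "peripheral_profile")
  expect_equal(prof$F[100], 1, tolerance = 1e-9)
  expect_s3_class(autoplot(prof), "ggplot")
})

test_that("fully peripheral signal matches the normalization algebra", {
  rec <- crossbow_record(n_spots = 400, seed = 9)
  dm <- record_dmap(rec)
  # keep only spots inside {D <= 10}
  D <- dmap_lookup(dm, rec$spots[, 1], rec$spots[, 2])
  sp <- rec$spots[D <= 10 & D >= 1, , drop = FALSE]
  skip_if(nrow(sp) < 5)
  rec2 <- cell_record("peri", "mRNA", cell_mask = rec$cell_mask,
                      nucleus_mask = rec$nucleus_mask, mtoc = rec$mtoc,
                      spots = sp, nucleus_centroid = rec$nucleus_centroid)
  v <- peripheral_density_vector(rec2, dm)
  expect_equal(v[10], dm$peripheral_volumes[100] / dm$peripheral_volumes[10],
               tolerance = 1e-9)
})

test_that("volume-corrected noise vanishes for exact proportionality and matches the formula", {
  set.seed(4)
  V <- runif(25, 400, 1200)
  expect_equal(volume_corrected_noise(tibble::tibble(
    total_cytoplasmic = 3 * V, volume_um3 = V)), 0, tolerance = 1e-9)
  # direct-formula oracle on random tables
  for (i in 1:20) {
    set.seed(100 + i)
    Vr <- runif(15, 200, 800)
    Nr <- 50 + 0.2 * Vr + rnorm(15, 0, 12)
    got <- volume_corrected_noise(tibble::tibble(total_cytoplasmic = Nr, volume_um3 = Vr))
    b <- sum((Vr - mean(Vr)) * (Nr - mean(Nr))) / sum((Vr - mean(Vr))^2)
    a <- mean(Nr) - b * mean(Vr)
    want <- (sd(Nr) / mean(Nr))^2 -
      (b * mean(Vr) / (a + b * mean(Vr))) * (cov(Nr, Vr) / (mean(Nr) * mean(Vr)))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # N independent of V: Nm approaches the squared coefficient of variation
  set.seed(5)
  Vi <- runif(4000, 300, 900); Ni <- rpois(4000, 200)
  nm <- volume_corrected_noise(tibble::tibble(total_cytoplasmic = Ni, volume_um3 = Vi))
  expect_equal(nm, (sd(Ni) / mean(Ni))^2, tolerance = 0.1)
  # unit invariance: rescaling V leaves Nm unchanged
  nm2 <- volume_corrected_noise(tibble::tibble(total_cytoplasmic = Ni, volume_um3 = 17 * Vi))
  expect_equal(nm, nm2, tolerance = 1e-9)
  expect_error(volume_corrected_noise(tibble::tibble(
    total_cytoplasmic = c(1, 2, 3), volume_um3 = c(5, 5, 5))),
    class = "fishspat_degenerate_error")
})

test_that("centrality is 1 at the edge, 0 at the nucleus, linear in between", {
  rec <- crossbow_record(n_spots = 400, seed = 3)
  dm <- record_dmap(rec)
  cyto <- cytoplasm_mask(rec$cell_mask, rec$nucleus_mask)
  incyt <- fishspat:::.inside_mask(cyto, rec$spots[, 1], rec$spots[, 2])
  sp <- rec$spots[incyt, , drop = FALSE]
  D <- dmap_lookup(dm, sp[, 1], sp[, 2])
  edge_sp <- sp[D == 0, , drop = FALSE]
  nuc_sp <- sp[D >= 95 & D < 100, , drop = FALSE]
  mk <- function(s) cell_record("c", "mRNA", cell_mask = rec$cell_mask,
                                nucleus_mask = rec$nucleus_mask, mtoc = rec$mtoc,
                                spots = s, nucleus_centroid = rec$nucleus_centroid)
  skip_if(nrow(edge_sp) < 2 || nrow(nuc_sp) < 1)
  expect_equal(centrality(mk(edge_sp), dm), 1)
  expect_lte(centrality(mk(nuc_sp), dm), 0.05)
  Dn <- dmap_lookup(dm, nuc_sp[1, 1], nuc_sp[1, 2])
  both <- rbind(edge_sp[1:2, ], nuc_sp[1, ], nuc_sp[1, ])
  expect_equal(centrality(mk(both), dm), mean((100 - c(0, 0, Dn, Dn)) / 100))
})

test_that("KL entropy matches closed forms for uniform squares", {
  set.seed(10)
  pts <- cbind(runif(2000), runif(2000))
  h1 <- spread_entropy(pts)
  expect_lt(abs(h1), 0.06)
  # doubling the square side adds exactly 2 log 2
  h2 <- spread_entropy(pts * 2)
  expect_equal(h2 - h1, 2 * log(2), tolerance = 1e-9)
  # normalization puts the maximum at 1
  hs <- c(h2, h1, h2 / 2)
  expect_equal(max(normalize_entropy(hs)), 1)
  expect_error(spread_entropy(matrix(1, 10, 2)),
               class = "fishspat_degenerate_error")
})

test_that("MPI is exact at the enrichment extreme and invariant to non-MTOC relabeling", {
  skel <- make_crossbow_cell(radius = 50, nucleus_radius = 12)
  mk_series <- function(ratio, seed, n_cells = 12) {
    recs <- lapply(seq_len(n_cells), function(i) {
      ang <- withr::with_seed(seed * 997 + i, runif(1, 0, 360))
      sk <- skel
      sk$mtoc <- skel$nucleus_centroid + 30 * c(cos(ang * pi / 180), sin(ang * pi / 180))
      sp <- if (ratio == 1) {
        sample_poisson_spots(skel$cell_mask, 60, seed = seed * 10000 + i)
      } else {
        make_polarized_spots(skel$cell_mask, skel$nucleus_centroid, sk$mtoc,
                             ratio, 60, seed = seed * 10000 + i)
      }
      synthetic_cell_record(sk, spots = sp, id = paste0("c", i))
    })
    acquisition_series(recs)
  }
  strong <- mpi(mk_series(25, 1), n_boot = 20, seed = 1)
  expect_equal(strong$mpi, 1)
  expect_lt(strong$p_value, 1e-3)
  expect_gte(strong$mpi, -1); expect_lte(strong$mpi, 1)
  expect_s3_class(tidy(strong), "tbl_df")

  # MPI depends only on the MTOC vs non-MTOC split: permuting the non-MTOC
  # quadrant labels cannot change it (per-image median unchanged)
  ser <- mk_series(3, 2)
  m1 <- mpi(ser, n_boot = 10, seed = 3)
  dens <- lapply(ser$records, fishspat:::.quadrant_densities)
  ex <- sapply(dens, function(d) d[1] > median(d[2:4]))
  ex_perm <- sapply(dens, function(d) d[1] > median(d[c(4, 2, 3)]))
  expect_equal(ex, ex_perm)
  expect_equal(m1$mpi, 2 * mean(ex) - 1)
})

test_that("peripheral MPI restricts densities to the outer region", {
  skel <- make_crossbow_cell(radius = 40, nucleus_radius = 10)
  recs <- lapply(1:6, function(i) {
    sk <- skel
    ang <- withr::with_seed(50 + i, runif(1, 0, 360))
    sk$mtoc <- skel$nucleus_centroid + 24 * c(cos(ang * pi / 180), sin(ang * pi / 180))
    synthetic_cell_record(sk, spots = sample_poisson_spots(skel$cell_mask, 80, seed = 60 + i),
                          id = paste0("p", i))
  })
  ser <- acquisition_series(recs)
  dmaps <- lapply(recs, record_dmap)
  m <- mpi(ser, region = "peripheral", p = 30, dmaps = dmaps, n_boot = 10, seed = 4)
  expect_gte(m$mpi, -1); expect_lte(m$mpi, 1)
  expect_equal(m$region, "peripheral")
})

test_that("distribution profiles are elementwise medians with consistent dimensions", {
  recs <- lapply(1:15, function(i) crossbow_record(n_spots = 150, seed = 20 + i))
  quants <- lapply(recs, function(r) fine_grained_segments(r, record_dmap(r), p = 3))
  prof <- distribution_profile(quants)
  M <- do.call(rbind, lapply(quants, function(q) q$parts$c))
  want <- apply(M, 2, function(col) sort(col)[8]) # sort-based median, n = 15
  expect_equal(prof$c_bar, unname(want))
  # single record is its own profile; two records give the midpoint
  expect_equal(distribution_profile(quants[1])$c_bar, quants[[1]]$parts$c)
  expect_equal(distribution_profile(quants[1:2])$c_bar,
               (quants[[1]]$parts$c + quants[[2]]$parts$c) / 2)
  # inconsistent band counts refuse
  q1 <- fine_grained_segments(recs[[1]], record_dmap(recs[[1]]), p = 2)
  expect_error(distribution_profile(list(quants[[1]], q1)),
               class = "fishspat_parameter_error")
})

test_that("density categories follow the mean +/- sd rule", {
  expect_true(all(density_category_map(rep(2, 10)) == "mid"))
  v <- c(rep(1, 9), 50)
  expect_equal(as.character(density_category_map(v))[10], "high")
  set.seed(6)
  x <- rnorm(24)
  got <- density_category_map(x)
  mu <- mean(x); s <- sd(x)
  want <- ifelse(x > mu + s, "high", ifelse(x < mu - s, "low", "mid"))
  expect_equal(as.character(got), want)
})

test_that("A12 equals the exhaustive pairwise oracle, with exact boundary cases", {
  expect_equal(vd_a12(c(5, 6, 7), c(1, 2)), 1)
  expect_equal(vd_a12(rep(3, 4), rep(3, 5)), 0.5)
  set.seed(7)
  for (i in 1:200) {
    x1 <- sample(1:6, sample(2:5, 1), replace = TRUE)
    x2 <- sample(1:6, sample(2:5, 1), replace = TRUE)
    expect_equal(vd_a12(x1, x2), a12_oracle(x1, x2), tolerance = 1e-12)
  }
  # swapping groups reflects the score; monotone transforms leave it fixed
  x1 <- c(0.2, 0.5, 0.9); x2 <- c(0.1, 0.6)
  expect_equal(vd_a12(x1, x2), 1 - vd_a12(x2, x1))
  expect_equal(vd_a12(exp(x1), exp(x2)), vd_a12(x1, x2))
})

test_that("colocalization score reproduces the hand-built 4-pair example", {
  # T1 = {2, 3}, T2 = {3, 5}: S1 = {(2,3),(2,5),(3,5)}, S2 = {(3,3)}
  # build profiles whose Pearson correlations realize chosen similarities
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  mrna <- list(`2` = base, `3` = rev(base))
  prot <- list(`3` = base + rnorm(8, 0, 0.01), `5` = base * 2)
  set.seed(8)
  cs <- colocalization_score(mrna, prot, smoothing = FALSE)
  # gamma: (2,3) ~ 1, (2,5) = 1, (3,5) = -1 in S1; (3,3) ~ -1 in S2
  s1 <- c(cs$similarity["2", "3"], cs$similarity["2", "5"], cs$similarity["3", "5"])
  s2 <- cs$similarity["3", "3"]
  expect_equal(cs$a12, a12_oracle(s1, s2), tolerance = 1e-12)
  td <- tidy(cs)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$forward), 3)

  # identical similarities give exactly 0.5; dominance gives exactly 1
  flatm <- list(`2` = base, `3` = base)
  flatp <- list(`3` = base + 0.001, `5` = base - 0.001)
  expect_equal(colocalization_score(flatm, flatp, smoothing = FALSE)$a12, 0.5)

  # permutation p-value is reproducible under a seed
  cs2 <- colocalization_score(mrna, prot, smoothing = FALSE, n_perm = 200, seed = 9)
  cs3 <- colocalization_score(mrna, prot, smoothing = FALSE, n_perm = 200, seed = 9)
  expect_equal(cs2$permutation_p, cs3$permutation_p)
})

test_that("degenerate profiles are excluded from the similarity matrix", {
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  mrna <- list(`2` = base, `3` = base^2)
  prot <- list(`3` = base, `5` = rep(4, 8)) # constant protein profile at t = 5
  expect_message(cs <- colocalization_score(mrna, prot, smoothing = FALSE),
                 "degenerate")
  expect_true(all(is.na(cs$similarity[, "5"])))
  expect_false(anyNA(cs$similarity[, "3"]))
  # exclusion can empty a side entirely, which is an error
  mrna2 <- list(`2` = base, `3` = rep(1, 8)) # kills the only backward pair
  expect_error(suppressMessages(colocalization_score(mrna2, prot, smoothing = FALSE)),
               "non-empty")
})

test_that("neighborhood smoothing averages the sector/band lattice", {
  v <- rep(0, 16); v[1] <- 8 # sector 1, band 1 on an 8 x 2 lattice
  sm <- fishspat:::smooth_segments(v, 8)
  expect_equal(sm[1], 2)          # self + 2 sector neighbors + 1 band neighbor
  expect_equal(sm[2], 8 / 4)      # sector 2 band 1 sees the spike
  expect_equal(sum(sm > 0), 4)    # spike spreads to its lattice neighbors only
})

test_that("pooled deviation is zero for identical cells and decreases with pool size", {
  vecs <- rep(list(rep(2, 50)), 8)
  dev <- pooled_deviation_profile(vecs, pool_sizes = 1:5, n_draws = 10, seed = 1)
  expect_true(all(dev$deviation == 0))
  # i.i.d. noisy cells: k = 1 matches the mean pairwise L1 / len distance
  set.seed(11)
  vecs2 <- lapply(1:40, function(i) rnorm(30))
  dev2 <- pooled_deviation_profile(vecs2, pool_sizes = c(1, 5, 20), n_draws = 400,
                                   seed = 2)
  pair_l1 <- mean(replicate(2000, {
    ij <- sample(40, 2)
    mean(abs(vecs2[[ij[1]]] - vecs2[[ij[2]]]))
  }))
  expect_equal(dev2$deviation[1], pair_l1, tolerance = 0.05)
  expect_true(all(diff(dev2$deviation) < 0))
  expect_error(pooled_deviation_profile(vecs2, pool_sizes = 40),
               class = "fishspat_parameter_error")
})

test_that("spot rendering into continuous intensity enables the IF code path", {
  rec <- crossbow_record(n_spots = 300, seed = 12)
  cont <- spots_to_intensity(rec, sigma = 2)
  expect_equal(cont$molecule, "protein")
  expect_true(all(cont$intensity >= 0))
  expect_equal(sum(cont$intensity), 300, tolerance = 0.05)
  dm <- record_dmap(rec)
  v <- peripheral_density_vector(cont, dm)
  expect_equal(v[100], 1, tolerance = 1e-9)
})
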