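# Shared fixtures and independent oracles used across the test files.

disk_mask_fix <- function(size, cx, cy, r) {
  x <- matrix(rep(0:(size - 1), each = size), size)
  y <- matrix(rep(0:(size - 1), times = size), size)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# standard small crossbow cell with uniform spots
crossbow_record <- function(n_spots = 150, seed = 1, mtoc_angle = 30,
                            radius = 50, nucleus_radius = 12, n_slices = NULL) {
  skel <- make_crossbow_cell(radius = radius, nucleus_radius = nucleus_radius,
                             mtoc_angle = mtoc_angle, n_slices = n_slices)
  sp <- sample_poisson_spots(skel$cell_mask, n_spots, seed = seed,
                             height_map = skel$height_map)
  synthetic_cell_record(skel, spots = sp)
}

record_dmap <- function(record) {
  cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
  peripheral_distance_map(cyto, record$nucleus_mask, record$nucleus_centroid,
                          height_map = record$height_map)
}

# naive per-pixel windowed histogram entropy (double loop)
entropy_oracle <- function(img, window) {
  h <- nrow(img); w <- ncol(img)
  lo <- ceiling((window - 1) / 2); hi <- floor((window - 1) / 2)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- max(1, i - lo):min(h, i + hi)
    cs <- max(1, j - lo):min(w, j + hi)
    p <- table(img[rs, cs])
    p <- p / sum(p)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# exhaustive-threshold Otsu: maximize between-class variance over a 256-bin
# histogram; returns the best achievable between-class variance
otsu_best_variance <- function(img, levels = 256) {
  rng <- range(img)
  b <- pmin(floor((img - rng[1]) / diff(rng) * levels), levels - 1)
  cnt <- tabulate(b + 1, nbins = levels)
  p <- cnt / sum(cnt)
  best <- 0
  for (t in 1:(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:(t - 1)) * p[1:t]) / w0
    mu1 <- sum((t:(levels - 1)) * p[(t + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) best <- v
  }
  best
}

between_class_variance_at <- function(img, thr, levels = 256) {
  rng <- range(img)
  b <- pmin(floor((img - rng[1]) / diff(rng) * levels), levels - 1)
  tb <- pmin(floor((thr - rng[1]) / diff(rng) * levels), levels - 1)
  p <- tabulate(b + 1, nbins = levels) / length(img)
  w0 <- sum(p[seq_len(tb + 1)]); w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(0)
  mu0 <- sum((0:tb) * p[seq_len(tb + 1)]) / w0
  mu1 <- sum(((tb + 1):(levels - 1)) * p[(tb + 2):levels]) / w1
  w0 * w1 * (mu0 - mu1)^2
}

# even-odd point-in-polygon counting oracle for the distance map
dmap_oracle <- function(dmap, px, py) {
  ang <- (0:359) * pi / 180
  out <- integer(length(px))
  for (i in 1:100) {
    Ri <- dmap$rc - (i / 100) * (dmap$rc - dmap$rn)
    vx <- Ri * cos(ang) + dmap$centroid[1]
    vy <- Ri * sin(ang) + dmap$centroid[2]
    inside <- rep(FALSE, length(px))
    x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
    for (e in seq_along(vx)) {
      crosses <- (vy[e] > py) != (y2[e] > py)
      if (any(crosses)) {
        xint <- (x2[e] - vx[e]) * (py - vy[e]) / (y2[e] - vy[e]) + vx[e]
        inside <- xor(inside, crosses & px < xint)
      }
    }
    out <- out + inside
  }
  out
}

# 360-way brute-force orientation search over the MTOC quadrant spot count
orientation_oracle <- function(record) {
  ctr <- record$nucleus_centroid
  cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
  sp <- record$spots
  keep <- fishspat:::.inside_mask(cyto, sp[, 1], sp[, 2])
  th <- fishspat:::.angle_bin(sp[keep, 1], sp[keep, 2], ctr[1], ctr[2])
  thm <- fishspat:::.angle_bin(record$mtoc[1], record$mtoc[2], ctr[1], ctr[2])
  t1 <- vapply(0:359, function(d) {
    qm <- ((thm - d) %% 360) %/% 90
    sum(((th - d) %% 360) %/% 90 == qm)
  }, numeric(1))
  ties <- (0:359)[t1 == max(t1)]
  list(d = ties[which.min((ties - thm) %% 360)], t = max(t1), ties = ties)
}

# exhaustive pairwise A12 oracle
a12_oracle <- function(x1, x2) {
  gt <- 0; eq <- 0
  for (a in x1) for (b in x2) {
    if (a > b) gt <- gt + 1 else if (a == b) eq <- eq + 1
  }
  (gt + 0.5 * eq) / (length(x1) * length(x2))
}

# minimal striated test fiber with hand-placed spots
hand_fiber <- function(spots, stripe_cols, dimhw = c(40, 60)) {
  zm <- matrix(FALSE, dimhw[1], dimhw[2])
  zm[, stripe_cols + 1] <- TRUE
  fiber_record("hand", matrix(TRUE, dimhw[1], dimhw[2]),
               rbind(c(5, 20), c(55, 20)), spots,
               list(binary_mask(zm, "zline")))
}
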