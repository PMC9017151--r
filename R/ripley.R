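# Generalized degree of clustering: Ripley's K for point patterns and a
# convolution (autocorrelation) estimator for continuous intensities, both
# normalized against permutation envelopes under complete spatial
# randomness (CSR).
#
# No edge correction is applied to K (the estimator is used as printed);
# its boundary bias is shared by the permutation null, which lives in the
# same window, and therefore cancels in the clustering index H*.

#' Observation windows
#'
#' A window carries the measure nu(w) (area in 2D, volume in 3D) and knows
#' how to draw uniform points for the CSR null. `win_rect` is a full
#' rectangle; `win_mask` restricts to a binary mask, with an optional height
#' map for 3D (uniform z within the local height).
#'
#' @param width,height rectangle size.
#' @param mask a [binary_mask()].
#' @param height_map optional height map (3D volume in voxel units).
#' @return An object of class `spatial_window`.
#' @export
win_rect <- function(width, height) {
  structure(list(type = "rect", width = width, height = height,
                 measure = width * height, dim = 2L),
            class = "spatial_window")
}

#' @rdname win_rect
#' @export
win_mask <- function(mask, height_map = NULL) {
  idx <- which(unclass(mask), arr.ind = TRUE)
  if (!nrow(idx)) abort("empty window mask")
  measure <- if (is.null(height_map)) nrow(idx) else sum(height_map[idx])
  structure(list(type = "mask", mask = mask, idx = idx,
                 height_map = height_map,
                 measure = measure, dim = if (is.null(height_map)) 2L else 3L),
            class = "spatial_window")
}

#' Draw uniform (CSR) points in a window
#'
#' @param window a [win_rect()] or [win_mask()].
#' @param n number of points.
#' @return n x 2 (or n x 3) matrix.
#' @export
runif_window <- function(window, n) {
  if (window$type == "rect") {
    cbind(x = runif(n, 0, window$width), y = runif(n, 0, window$height))
  } else {
    if (is.null(window$height_map)) {
      i <- sample.int(nrow(window$idx), n, replace = TRUE)
      cbind(x = window$idx[i, 2] - 1 + runif(n, -0.5, 0.5),
            y = window$idx[i, 1] - 1 + runif(n, -0.5, 0.5))
    } else {
      h <- window$height_map[window$idx]
      i <- sample.int(nrow(window$idx), n, replace = TRUE, prob = h)
      cbind(x = window$idx[i, 2] - 1 + runif(n, -0.5, 0.5),
            y = window$idx[i, 1] - 1 + runif(n, -0.5, 0.5),
            z = runif(n, 0, h[i]))
    }
  }
}

#' Default radii grid
#'
#' 60 radii linearly spaced up to 30% of the equivalent window radius
#' `sqrt(measure / pi)`.
#'
#' @param window a window object.
#' @param n number of radii.
#' @param r_max largest radius; defaults to 0.3 of the equivalent radius.
#' @return Numeric vector of radii.
#' @export
default_radii <- function(window, n = 60, r_max = NULL) {
  r_max <- r_max %||% (0.3 * sqrt(window$measure / pi))
  seq(r_max / n, r_max, length.out = n)
}

#' Ripley's K for a point pattern
#'
#' `K(r) = (1 / (lambda^2 nu(w))) * sum_i N_i(r)` with `lambda = n / nu(w)`
#' and `N_i(r)` the number of other points within distance `r` of point `i`.
#' No edge correction (see the module notes).
#'
#' @param points n x d matrix (columns x, y and optionally z).
#' @param window a window object supplying `nu(w)`.
#' @param radii radii vector.
#' @param dim 2 or 3; defaults to the window's dimension.
#' @return Numeric vector `K(r)` along `radii`.
#' @export
ripley_k_points <- function(points, window, radii, dim = window$dim) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) abort("Ripley's K needs at least 2 points")
  d <- sort(dist(points[, seq_len(dim), drop = FALSE]))
  cnt <- findInterval(radii, d)
  window$measure / n^2 * 2 * cnt
}

#' Convolution-based K for a continuous intensity
#'
#' `Kc(r) = (1 / (lambda^2 V)) * sum_{|lag| <= r} (I * I')(lag) - 1 / lambda`
#' with `I'(x) = I(-x)` (so the convolution is the autocorrelation of the
#' intensity), `lambda = T / V` the mean intensity per unit measure, and `V`
#' the window measure. Computed on the pixel lattice via FFT; a 3D stack is
#' approximated by its 2D sum projection.
#'
#' @param intensity 2D non-negative matrix.
#' @param mask optional [binary_mask()]; intensities outside are zeroed and
#'   the measure is the mask area (otherwise the full frame).
#' @param radii radii vector, in pixels.
#' @return Numeric vector `Kc(r)`.
#' @export
ripley_k_convolution <- function(intensity, mask = NULL, radii) {
  I <- intensity
  if (!is.null(mask)) {
    I <- I * unclass(mask)
    V <- sum(mask)
  } else V <- length(I)
  TT <- sum(I)
  if (TT <= 0) abort("zero total intensity")
  h <- nrow(I); w <- ncol(I)
  P <- matrix(0, 2 * h, 2 * w); P[1:h, 1:w] <- I
  F <- fft(P)
  A <- Re(fft(F * Conj(F), inverse = TRUE)) / length(P)
  dy <- ifelse(seq_len(2 * h) - 1 < h, seq_len(2 * h) - 1, seq_len(2 * h) - 1 - 2 * h)
  dx <- ifelse(seq_len(2 * w) - 1 < w, seq_len(2 * w) - 1, seq_len(2 * w) - 1 - 2 * w)
  lagd <- sqrt(outer(dy^2, dx^2, `+`))
  o <- order(lagd)
  csum <- cumsum(A[o])
  cnt <- findInterval(radii + 1e-9, lagd[o])
  S <- csum[pmax(cnt, 1)]
  S[cnt == 0] <- 0
  V / TT^2 * S - V / TT
}

#' CSR null curves by permutation
#'
#' Point mode: the observed number of points is redrawn uniformly inside the
#' window (literally permuting point coordinates would leave the pattern
#' unchanged). Convolution mode: intensity values are permuted uniformly
#' among within-mask pixels. K is recomputed for each of the
#' `n_permutations` draws.
#'
#' @param x number of points (point mode) or intensity matrix (convolution
#'   mode).
#' @param window a window object (point mode) / [binary_mask()]
#'   (convolution mode; `NULL` permutes the full frame).
#' @param radii radii vector.
#' @param n_permutations number of CSR draws (100 in the reference
#'   protocol).
#' @param seed optional integer seed for reproducible envelopes.
#' @param mode `"point"` or `"convolution"`.
#' @param dim 2 or 3 (point mode).
#' @return Matrix `n_permutations` x `length(radii)` of null K curves.
#' @export
csr_null <- function(x, window = NULL, radii, n_permutations = 100,
                     seed = NULL, mode = c("point", "convolution"),
                     dim = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    if (mode == "point") {
      n <- if (is.matrix(x)) nrow(x) else x
      dim <- dim %||% window$dim
      t(vapply(seq_len(n_permutations), function(i) {
        ripley_k_points(runif_window(window, n), window, radii, dim = dim)
      }, numeric(length(radii))))
    } else {
      mask <- window
      vals_idx <- if (is.null(mask)) seq_along(x) else which(unclass(mask))
      t(vapply(seq_len(n_permutations), function(i) {
        Ip <- x
        Ip[vals_idx] <- x[vals_idx][sample.int(length(vals_idx))]
        ripley_k_convolution(Ip, mask, radii)
      }, numeric(length(radii))))
    }
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Ripley H normalization
#'
#' `H(r) = sqrt(K / pi) - r` in 2D, `(3 K / (4 pi))^(1/3) - r` in 3D; both
#' have expectation 0 under CSR.
#'
#' @param k K curve.
#' @param radii radii vector.
#' @param dim 2 or 3.
#' @return H curve.
#' @export
ripley_h <- function(k, radii, dim = 2) {
  if (dim == 2) sqrt(k / pi) - radii else (3 * k / (4 * pi))^(1 / 3) - radii
}

#' Clustering index H*
#'
#' Normalizes the observed H against the 95th/5th permutation percentiles:
#' `H*(r) = H / H95` when `H >= 0`, `-H / H5` otherwise, so that
#' `|H*| > 1` exactly when H leaves the central 90% permutation band.
#' Radii where the dividing percentile has the wrong sign (degenerate
#' envelope, e.g. no pairs at small r) are masked as `NA`.
#'
#' @param k_hat observed K curve.
#' @param null_curves matrix of null K curves from [csr_null()].
#' @param radii radii vector.
#' @param dim 2 or 3.
#' @return List with `h`, `h_star`, `env_lo`, `env_hi` (H-scale envelopes).
#' @export
clustering_index <- function(k_hat, null_curves, radii, dim = 2) {
  h <- ripley_h(k_hat, radii, dim)
  hn <- t(apply(null_curves, 1, ripley_h, radii = radii, dim = dim))
  # exact Monte-Carlo envelopes: the m-th largest/smallest of the n null
  # curves with m = ceiling(0.05 n), so that under exchangeability the
  # observed curve exceeds an envelope with probability m / (n + 1)
  n <- nrow(hn)
  m <- max(1L, ceiling(0.05 * n))
  h95 <- apply(hn, 2, function(v) sort(v)[n - m + 1L])
  h5 <- apply(hn, 2, function(v) sort(v)[m])
  hs <- ifelse(h >= 0,
               ifelse(h95 > 0, h / h95, NA_real_),
               ifelse(h5 < 0, -h / h5, NA_real_))
  if (anyNA(hs)) {
    message(sprintf("clustering index undefined at %d of %d radii (degenerate envelope)",
                    sum(is.na(hs)), length(hs)))
  }
  list(h = h, h_star = hs, env_lo = h5, env_hi = h95)
}

#' Degree of clustering
#'
#' Trapezoidal integral of `max(H*(r) - 1, 0)` over `(0, r_max]`: the area
#' of the clustering index above 1. Masked radii are dropped.
#'
#' @param h_star clustering index curve.
#' @param radii radii vector.
#' @param r_max upper integration bound (must not exceed the evaluated
#'   radii).
#' @return Scalar degree of clustering (>= 0).
#' @export
degree_of_clustering <- function(h_star, radii, r_max = max(radii)) {
  if (r_max > max(radii) + 1e-9)
    abort("r_max beyond the evaluated radii", class = "fishspat_parameter_error")
  keep <- radii <= r_max + 1e-12 & !is.na(h_star)
  r <- radii[keep]; y <- pmax(h_star[keep] - 1, 0)
  if (length(r) < 2) return(0)
  sum(diff(r) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Full clustering analysis of a pattern or intensity
#'
#' Computes K, the permutation envelopes, the clustering index H* and the
#' scalar degree of clustering in one call.
#'
#' @param points point matrix (point mode), or `NULL`.
#' @param intensity intensity matrix (convolution mode), or `NULL`.
#' @param window a window object (point mode) or a [binary_mask()]
#'   (convolution mode, optional).
#' @param radii radii vector; defaults to [default_radii()] (pixels for
#'   convolution mode).
#' @param n_permutations CSR permutations.
#' @param seed optional seed.
#' @param dim 2 or 3 (point mode).
#' @param r_max integration bound for the degree of clustering.
#' @return An object of class `clustering_result`.
#' @export
ripley_clustering <- function(points = NULL, intensity = NULL, window = NULL,
                              radii = NULL, n_permutations = 100, seed = NULL,
                              dim = NULL, r_max = NULL) {
  if (!is.null(points)) {
    dim <- dim %||% window$dim
    radii <- radii %||% default_radii(window)
    k <- ripley_k_points(points, window, radii, dim = dim)
    null <- csr_null(points, window, radii, n_permutations, seed, mode = "point",
                     dim = dim)
    mode <- "point"
  } else {
    mask <- window
    wmeas <- if (is.null(mask)) length(intensity) else sum(mask)
    radii <- radii %||% seq(1, 0.3 * sqrt(wmeas / pi), length.out = 60)
    k <- ripley_k_convolution(intensity, mask, radii)
    null <- csr_null(intensity, mask, radii, n_permutations, seed,
                     mode = "convolution")
    dim <- 2L
    mode <- "convolution"
  }
  ci <- clustering_index(k, null, radii, dim = dim)
  r_max <- r_max %||% max(radii)
  structure(
    list(radii = radii, k_hat = k, h_hat = ci$h, h_star = ci$h_star,
         envelope_5 = ci$env_lo, envelope_95 = ci$env_hi,
         degree = degree_of_clustering(ci$h_star, radii, r_max),
         n_permutations = n_permutations, mode = mode, dim = dim,
         seed = seed),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s mode (%dD), %d radii <= %.3g, degree = %.4g\n",
              x$mode, x$dim, length(x$radii), max(x$radii), x$degree))
  invisible(x)
}

#' @rdname ripley_clustering
#' @param x a `clustering_result`.
#' @param ... unused.
#' @export
tidy.clustering_result <- function(x, ...) {
  tibble(radius = x$radii, k_hat = x$k_hat, h_hat = x$h_hat,
         h_star = x$h_star, env_lo = x$envelope_5, env_hi = x$envelope_95)
}

#' @rdname ripley_clustering
#' @export
glance.clustering_result <- function(x, ...) {
  tibble(degree = x$degree, n_permutations = x$n_permutations,
         mode = x$mode, dim = x$dim, n_radii = length(x$radii))
}

#' @rdname ripley_clustering
#' @param object a `clustering_result`.
#' @export
autoplot.clustering_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius)) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$h_star), na.rm = TRUE) +
    ggplot2::labs(x = "radius", y = "clustering index H*",
                  title = sprintf("degree of clustering = %.3g", object$degree)) +
    ggplot2::theme_minimal()
}
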