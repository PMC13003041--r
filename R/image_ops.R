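#' Image operators for the swelling and glia quantification workflows
#'
#' These functions reproduce, one by one, the batch-processing steps of the
#' immunostain quantification workflows: 8-bit conversion, contrast
#' inversion, rolling-ball background subtraction, pixel subtraction,
#' median smoothing, linear contrast enhancement, Gaussian smoothing,
#' moment-preserving (Tsai) auto-thresholding and 3-D particle labelling.
#' All 2-D operators act slice-wise on stacks; all radii and sigmas are in
#' pixels.
#'
#' @name image_ops
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Convert a stack to 8-bit
#'
#' Linearly rescales the intensity range `[min, max]` of the stack to
#' `[0, 255]`, rounding half away from zero. A constant stack maps to 0.
#'
#' @param stack an [image_stack()].
#' @return An 8-bit [image_stack()].
#' @export
to_uint8 <- function(stack) {
  assert_stack(stack)
  v <- stack$voxels
  rng <- range(v)
  if (rng[1] == rng[2]) {
    out <- array(0, dim(v))
  } else {
    out <- round_half_up((v - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  with_voxels(stack, out, bit_depth = 8L)
}

#' Invert an 8-bit stack
#'
#' Maps `v -> 255 - v`, turning dark absorbing structures of a brightfield
#' image into bright objects on a dark background. Involutive.
#'
#' @param stack an 8-bit [image_stack()].
#' @return The inverted [image_stack()].
#' @export
invert <- function(stack) {
  assert_stack(stack)
  if (stack$bit_depth != 8L) stop("invert expects an 8-bit stack")
  with_voxels(stack, 255 - stack$voxels)
}

# disc offsets (dy, dx) with dy^2 + dx^2 <= r^2, plus ball height at each
ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- g$dy^2 + g$dx^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  g$h <- sqrt(pmax(radius^2 - g$dy^2 - g$dx^2, 0))
  g
}

# grayscale erosion/dilation of a single slice by a (possibly non-flat)
# structuring element; edges handled by restricting to in-bounds offsets
morph_slice <- function(mat, off, op = c("erode", "dilate")) {
  op <- match.arg(op)
  h <- nrow(mat); w <- ncol(mat)
  acc <- matrix(if (op == "erode") Inf else -Inf, h, w)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]; b <- off$h[i]
    r1 <- max(1, 1 - dy); r2 <- min(h, h - dy)
    c1 <- max(1, 1 - dx); c2 <- min(w, w - dx)
    if (r1 > r2 || c1 > c2) next
    src <- mat[(r1 + dy):(r2 + dy), (c1 + dx):(c2 + dx), drop = FALSE]
    if (op == "erode") {
      acc[r1:r2, c1:c2] <- pmin(acc[r1:r2, c1:c2], src - b)
    } else {
      acc[r1:r2, c1:c2] <- pmax(acc[r1:r2, c1:c2], src + b)
    }
  }
  acc
}

# grayscale opening with a ball-height structuring element
opening_ball <- function(mat, radius) {
  off <- ball_offsets(radius)
  morph_slice(morph_slice(mat, off, "erode"), off, "dilate")
}

#' Rolling-ball background subtraction
#'
#' Estimates, slice by slice, a smooth background as the grayscale
#' morphological opening of the slice with a ball-height structuring
#' element of the given radius (the classical rolling-ball model: the
#' background is the surface traced by a ball of that radius rolling under
#' the intensity landscape), and subtracts it. Structures narrower than
#' the ball are preserved in the corrected image; the background never
#' exceeds the original slice pointwise.
#'
#' @param stack an [image_stack()].
#' @param radius ball radius in pixels (>= 1).
#' @return A list with `background` and `corrected`, both [image_stack()]s.
#' @export
rolling_ball_background <- function(stack, radius) {
  assert_stack(stack)
  if (radius < 1) stop("radius must be >= 1")
  d <- dim(stack$voxels)
  if (radius > min(d[1], d[2]))
    stop("rolling-ball radius larger than the slice extent")
  vmax <- 2^stack$bit_depth - 1
  bg <- array(0, d); corr <- array(0, d)
  for (k in seq_len(d[3])) {
    b <- opening_ball(stack$voxels[, , k], radius)
    b <- pmin(pmax(round_half_up(b), 0), vmax)
    bg[, , k] <- b
    corr[, , k] <- pmin(pmax(stack$voxels[, , k] - b, 0), vmax)
  }
  list(background = with_voxels(stack, bg),
       corrected = with_voxels(stack, corr))
}

#' Subtract a constant from every voxel
#'
#' `v -> max(v - value, 0)`; the workflow's "pixel subtraction" step,
#' used to remove residual diffuse staining after background subtraction.
#'
#' @param stack an [image_stack()].
#' @param value constant in `[0, 255]`.
#' @return An [image_stack()].
#' @export
subtract_constant <- function(stack, value) {
  assert_stack(stack)
  if (value < 0 || value > 255) stop("value must be in [0, 255]")
  with_voxels(stack, pmax(stack$voxels - value, 0))
}

# reflect indices 1..n to length n + 2r with half-sample symmetric padding,
# tiling the reflection for radii wider than the image
reflect_index <- function(n, r) {
  if (r == 0) return(seq_len(n))
  i <- (1 - r):(n + r)
  m <- (i - 1) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

pad_reflect <- function(mat, r) {
  mat[reflect_index(nrow(mat), r), reflect_index(ncol(mat), r), drop = FALSE]
}

#' Median filter (disc neighbourhood)
#'
#' Replaces each pixel by the median of its disc neighbourhood of the
#' given radius, slice by slice, with reflective edge padding.
#'
#' @param stack an [image_stack()].
#' @param radius neighbourhood radius in pixels (>= 1).
#' @return An [image_stack()].
#' @export
median_filter <- function(stack, radius) {
  assert_stack(stack)
  if (radius < 1) stop("radius must be >= 1")
  off <- ball_offsets(radius)
  d <- dim(stack$voxels)
  h <- d[1]; w <- d[2]
  r <- floor(radius)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    p <- pad_reflect(stack$voxels[, , k], r)
    vals <- matrix(0, h * w, nrow(off))
    for (i in seq_len(nrow(off))) {
      vals[, i] <- as.vector(
        p[(1 + r + off$dy[i]):(h + r + off$dy[i]),
          (1 + r + off$dx[i]):(w + r + off$dx[i])])
    }
    out[, , k] <- matrix(apply(vals, 1, median), h, w)
  }
  with_voxels(stack, out)
}

#' Linear contrast enhancement with saturation
#'
#' Stretches intensities linearly so that the `saturated_fraction` and
#' `1 - saturated_fraction` quantiles map to 0 and 255, clamping outside.
#' The default saturation fraction follows the usual auto-contrast
#' convention (0.35% of pixels saturated).
#'
#' @param stack an [image_stack()].
#' @param saturated_fraction fraction in `[0, 0.5)` saturated at each end.
#' @return An 8-bit [image_stack()].
#' @export
enhance_contrast <- function(stack, saturated_fraction = 0.0035) {
  assert_stack(stack)
  if (saturated_fraction < 0 || saturated_fraction >= 0.5)
    stop("saturated_fraction must be in [0, 0.5)")
  v <- stack$voxels
  q <- quantile(v, c(saturated_fraction, 1 - saturated_fraction),
                names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate quantile range; contrast left unchanged")
    return(stack)
  }
  out <- round_half_up((v - q[1]) / (q[2] - q[1]) * 255)
  with_voxels(stack, pmin(pmax(out, 0), 255), bit_depth = 8L)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Gaussian blur
#'
#' Slice-wise separable Gaussian convolution with reflective padding,
#' kernel truncated at three sigma and renormalised (mass-preserving).
#'
#' @param stack an [image_stack()].
#' @param sigma standard deviation in pixels (> 0).
#' @return An [image_stack()].
#' @export
gaussian_blur <- function(stack, sigma) {
  assert_stack(stack)
  if (sigma <= 0) stop("sigma must be > 0")
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  d <- dim(stack$voxels)
  h <- d[1]; w <- d[2]
  out <- array(0, d)
  for (s in seq_len(d[3])) {
    m <- stack$voxels[, , s]
    # rows
    p <- m[reflect_index(h, r), , drop = FALSE]
    acc <- matrix(0, h, w)
    for (i in seq_along(k))
      acc <- acc + k[i] * p[(i):(i + h - 1L), , drop = FALSE]
    # columns
    p <- acc[, reflect_index(w, r), drop = FALSE]
    acc <- matrix(0, h, w)
    for (i in seq_along(k))
      acc <- acc + k[i] * p[, (i):(i + w - 1L), drop = FALSE]
    out[, , s] <- acc
  }
  with_voxels(stack, pmin(pmax(out, 0), 2^stack$bit_depth - 1))
}

#' 256-bin intensity histogram of an 8-bit stack
#'
#' @param stack an 8-bit [image_stack()].
#' @return Integer vector of 256 counts (bins 0..255).
#' @export
histogram256 <- function(stack) {
  assert_stack(stack)
  if (stack$bit_depth != 8L) stop("histogram256 expects an 8-bit stack")
  tabulate(as.integer(stack$voxels) + 1L, nbins = 256L)
}

#' Moment-preserving (Tsai) threshold
#'
#' Computes the automatic threshold that preserves the first three
#' gray-level moments of the image in a two-level (binary) image: the two
#' representative levels `z0 < z1` and the background fraction `p0` are
#' obtained in closed form from the moments, and the threshold is placed
#' at the `p0`-tile of the histogram — the smallest bin whose cumulative
#' fraction reaches `p0`. This is the "Moments" auto-threshold of common
#' image-analysis software.
#'
#' @param histogram numeric vector of 256 bin counts (gray levels 0..255).
#' @return Integer threshold in 0..255. Foreground is conventionally
#'   `value > threshold`.
#' @export
moments_threshold <- function(histogram) {
  if (length(histogram) != 256L) stop("histogram must have 256 bins")
  if (any(histogram < 0)) stop("negative histogram counts")
  total <- sum(histogram)
  if (total == 0) stop("empty histogram")
  populated <- which(histogram > 0)
  if (length(populated) == 1L) return(populated - 1L)
  z <- 0:255
  p <- histogram / total
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (!is.finite(disc) || disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- if (z1 == z0) 0.5 else (z1 - m1) / (z1 - z0)
  p0 <- min(max(p0, 0), 1)
  cum <- cumsum(p)
  idx <- which(cum >= p0 - 1e-12)[1]
  as.integer(idx - 1L)
}

#' Binarise an 8-bit stack at a threshold
#'
#' Foreground is `value > threshold` (the threshold level itself belongs
#' to the background).
#'
#' @param stack an 8-bit [image_stack()].
#' @param threshold integer 0..255, e.g. from [moments_threshold()].
#' @return A `binary_stack`: logical array with calibration attached.
#' @export
binarize <- function(stack, threshold) {
  assert_stack(stack)
  structure(
    list(voxels = stack$voxels > threshold, pixel_size = stack$pixel_size,
         z_step = stack$z_step),
    class = "binary_stack"
  )
}

# linear-index offsets of the 13 "forward" 26-connected neighbours
neighbour_offsets <- function(connectivity) {
  if (connectivity == 26) {
    g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
    g <- g[g$dz > 0 | (g$dz == 0 & (g$dx > 0 | (g$dx == 0 & g$dy > 0))), ]
  } else if (connectivity == 6) {
    g <- data.frame(dy = c(1, 0, 0), dx = c(0, 1, 0), dz = c(0, 0, 1))
  } else stop("connectivity must be 6 or 26")
  g
}

#' Label connected foreground components of a binary stack
#'
#' Finds maximal connected components (default 26-connectivity in 3-D;
#' for a depth-1 stack this is 8-connectivity in 2-D) and summarises each
#' particle: voxel count, physical volume
#' (`voxels * pixel_size^2 * z_step`), the maximum single-slice
#' cross-sectional area, and the intensity-unweighted centroid in
#' micrometres.
#'
#' @param binary a `binary_stack` from [binarize()].
#' @param connectivity 26 (default) or 6.
#' @return A `particle_set`: list with `particles` (one row per component),
#'   `labels` (integer array, 0 = background) and the calibration.
#' @export
connected_components <- function(binary, connectivity = 26) {
  if (!inherits(binary, "binary_stack")) stop("expected a binary_stack")
  v <- binary$voxels
  d <- dim(v)
  fg <- which(v)
  labels <- array(0L, d)
  if (length(fg) == 0L) {
    particles <- data.frame(particle = integer(0), n_voxels = integer(0),
                            volume_um3 = numeric(0),
                            max_slice_area_um2 = numeric(0),
                            x_um = numeric(0), y_um = numeric(0),
                            z_um = numeric(0))
    return(structure(list(particles = particles, labels = labels,
                          pixel_size = binary$pixel_size,
                          z_step = binary$z_step),
                     class = "particle_set"))
  }
  rank_of <- array(0L, d)
  rank_of[fg] <- seq_along(fg)
  coord <- arrayInd(fg, d)   # (y, x, z)
  offs <- neighbour_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    ny <- coord[, 1] + offs$dy[i]
    nx <- coord[, 2] + offs$dx[i]
    nz <- coord[, 3] + offs$dz[i]
    ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nb <- rank_of[cbind(ny[ok], nx[ok], nz[ok])]
    src <- which(ok)[nb > 0L]
    if (length(src)) edges[[i]] <- cbind(src, nb[nb > 0L])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  labels[fg] <- memb
  px <- binary$pixel_size; zs <- binary$z_step
  n_vox <- tabulate(memb)
  # max single-slice pixel count per particle
  slice_key <- paste(memb, coord[, 3], sep = "_")
  per_slice <- table(slice_key)
  slice_lab <- as.integer(sub("_.*", "", names(per_slice)))
  max_px <- vapply(seq_along(n_vox),
                   function(l) max(per_slice[slice_lab == l]), numeric(1))
  particles <- data.frame(
    particle = seq_along(n_vox),
    n_voxels = n_vox,
    volume_um3 = n_vox * px^2 * zs,
    max_slice_area_um2 = max_px * px^2,
    x_um = vapply(seq_along(n_vox),
                  function(l) mean(coord[memb == l, 2] - 0.5) * px, numeric(1)),
    y_um = vapply(seq_along(n_vox),
                  function(l) mean(coord[memb == l, 1] - 0.5) * px, numeric(1)),
    z_um = vapply(seq_along(n_vox),
                  function(l) mean(coord[memb == l, 3] - 0.5) * zs, numeric(1))
  )
  structure(list(particles = particles, labels = labels,
                 pixel_size = px, z_step = zs),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set: %d particle(s)\n", nrow(x$particles)))
  if (nrow(x$particles)) print(head(x$particles, 10))
  invisible(x)
}
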