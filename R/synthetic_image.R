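#' Configuration for synthetic swelling-stack simulation
#'
#' Describes a synthetic immunostained z-stack: faint curvilinear fibres of
#' sub-threshold calibre plus ellipsoidal axonal-swelling blobs with known
#' positions and sizes. Two object classes are generated: "large"
#' swellings whose geometry exceeds both particle filters (maximum
#' cross-sectional area > `min area`, voxel count >= minimum), and
#' "small" ones that fail at least one filter. The default calibration
#' (0.1 um/pixel, 1 um z-step, matching a 60x oil objective with 1 um
#' z-interval) makes the 0.53 um^2 area filter equal to 53 pixels.
#'
#' Rendering modes: `"brightfield"` (default) emulates a scanned or
#' transmitted-light immunostain — a bright background from which objects
#' absorb intensity; this is what the swelling-quantification pipeline
#' (which inverts contrast) consumes. `"fluorescence"` renders additive
#' bright objects on a dark background.
#'
#' @param width,height,depth stack dimensions in pixels / slices.
#' @param pixel_size,z_step calibration in micrometres.
#' @param n_fibres number of fibre polylines.
#' @param fibre_intensity peak fibre absorbance/intensity, 8-bit units.
#' @param n_swellings_large,n_swellings_small object counts per class.
#' @param swelling_radius_range lateral radius range (um) of large
#'   swellings; the radius is the 2-sigma truncation extent of the
#'   rendered Gaussian blob.
#' @param small_radius_range lateral radius range (um) of small swellings.
#' @param swelling_intensity peak swelling absorbance/intensity.
#' @param background_level base background intensity (8-bit units).
#' @param background_gradient_amplitude amplitude of a smooth linear
#'   illumination gradient.
#' @param noise_sd additive Gaussian pixel noise SD (8-bit units).
#' @param mode `"brightfield"` or `"fluorescence"` (see above).
#' @param min_separation minimum distance between swelling centres (um).
#' @param on_boundary `"reposition"` (default) redraws objects that would
#'   overlap the stack boundary; `"error"` aborts instead.
#' @param seed integer RNG seed; fixed seed gives bit-identical stacks.
#' @return An `image_sim_config` list.
#' @export
image_sim_config <- function(width = 96, height = 96, depth = 10,
                             pixel_size = 0.1, z_step = 1,
                             n_fibres = 6, fibre_intensity = 40,
                             n_swellings_large = 12, n_swellings_small = 5,
                             swelling_radius_range = c(0.8, 1.1),
                             small_radius_range = c(0.2, 0.3),
                             swelling_intensity = 160,
                             background_level = NULL,
                             background_gradient_amplitude = 10,
                             noise_sd = 3,
                             mode = c("brightfield", "fluorescence"),
                             min_separation = 2.5,
                             on_boundary = c("reposition", "error"),
                             seed = 1L) {
  mode <- match.arg(mode)
  on_boundary <- match.arg(on_boundary)
  if (is.null(background_level))
    background_level <- if (mode == "brightfield") 230 else 10
  stopifnot(width > 0, height > 0, depth > 0, pixel_size > 0, z_step > 0,
            n_fibres >= 0, n_swellings_large >= 0, n_swellings_small >= 0,
            noise_sd >= 0)
  if (length(swelling_radius_range) != 2 || any(swelling_radius_range <= 0) ||
      diff(swelling_radius_range) < 0)
    stop("swelling_radius_range must be positive and ordered")
  if (length(small_radius_range) != 2 || any(small_radius_range <= 0) ||
      diff(small_radius_range) < 0)
    stop("small_radius_range must be positive and ordered")
  structure(as.list(environment()), class = "image_sim_config")
}

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# geometric filter prediction for a truncated-Gaussian blob:
# max cross-section area (um^2) and analytic voxel count
blob_geometry <- function(r_xy, r_z, pixel_size, z_step) {
  area <- pi * r_xy^2
  volume <- 4 / 3 * pi * r_xy^2 * r_z
  list(area_um2 = area, volume_um3 = volume,
       n_voxels = volume / (pixel_size^2 * z_step))
}

#' Recompute ground-truth filter flags from object geometry
#'
#' Applies the particle filters (maximum cross-sectional area strictly
#' greater than `min_area`, analytic voxel count at least `min_voxels`) to
#' the geometry stored in a [generate_image_stack()] ground truth.
#'
#' @param truth the `truth` data frame of a synthetic stack.
#' @param pixel_size,z_step calibration in micrometres.
#' @param min_area area filter in um^2.
#' @param min_voxels voxel-count filter.
#' @return Logical vector, one flag per object.
#' @export
recompute_filter_flags <- function(truth, pixel_size, z_step,
                                   min_area = 0.53, min_voxels = 5) {
  g <- blob_geometry(truth$radius_xy_um, truth$radius_z_um,
                     pixel_size, z_step)
  g$area_um2 > min_area & g$n_voxels >= min_voxels
}

#' Generate a synthetic swelling stack with known ground truth
#'
#' Renders fibres as curvilinear tubes of sub-threshold calibre and axonal
#' swellings as anisotropic Gaussian blobs truncated at two sigma, over a
#' smooth background gradient with additive pixel noise (see
#' [image_sim_config()] for the rendering modes). Object fields are
#' combined by pointwise maximum, so overlapping stamps do not add.
#'
#' @param config an [image_sim_config()].
#' @return A list with `stack` (an [image_stack()]) and `truth`, a data
#'   frame of object centres (um), radii, analytic volumes
#'   (`4/3 * pi * r_xy^2 * r_z`), size class and `passes_filter` flags,
#'   with the fibre polylines attached as `attr(truth, "fibre_paths")`.
#' @export
generate_image_stack <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed(config$seed, generate_image_stack_impl(config))
}

generate_image_stack_impl <- function(cfg) {
  W <- cfg$width; H <- cfg$height; D <- cfg$depth
  px <- cfg$pixel_size; zs <- cfg$z_step
  wx <- W * px; wy <- H * px; wz <- D * zs   # physical extent, um
  dens <- array(0, c(H, W, D))               # object absorbance field

  # fibres: smooth random walks in physical space, stamped as thin
  # Gaussian discs (sigma ~ 1 px) at the nearest pixel centre
  fibre_paths <- list()
  if (cfg$n_fibres > 0) {
    step_um <- px                          # one-pixel steps
    n_steps <- round(0.8 * max(W, H))
    for (f in seq_len(cfg$n_fibres)) {
      pos <- c(runif(1, 0.1 * wx, 0.9 * wx), runif(1, 0.1 * wy, 0.9 * wy))
      ang <- runif(1, 0, 2 * pi)
      z <- sample.int(D, 1)
      path <- matrix(0, n_steps, 3)
      for (s in seq_len(n_steps)) {
        ang <- ang + rnorm(1, 0, 0.15)
        pos <- pos + step_um * c(cos(ang), sin(ang))
        pos <- pmin(pmax(pos, px), c(wx - px, wy - px))
        path[s, ] <- c(pos, (z - 0.5) * zs)
        ci <- pmin(pmax(round(pos / px + 0.5), 1), c(W, H))
        dens[, , z] <- stamp_disc(dens[, , z], ci[2], ci[1],
                                  cfg$fibre_intensity, sigma_px = 1)
      }
      fibre_paths[[f]] <- path
    }
  }

  # swellings: rejection-sample well-separated centres with a boundary
  # margin equal to each object's truncation extent
  n_l <- cfg$n_swellings_large; n_s <- cfg$n_swellings_small
  n_obj <- n_l + n_s
  truth <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      radius_xy_um = numeric(0), radius_z_um = numeric(0),
                      volume_um3 = numeric(0), size_class = character(0),
                      passes_filter = logical(0))
  if (n_obj > 0) {
    cls <- c(rep("large", n_l), rep("small", n_s))
    r_xy <- c(runif(n_l, cfg$swelling_radius_range[1],
                    cfg$swelling_radius_range[2]),
              runif(n_s, cfg$small_radius_range[1],
                    cfg$small_radius_range[2]))
    r_z <- ifelse(cls == "large", pmax(r_xy, 1.5), 0.8)
    centres <- matrix(NA_real_, n_obj, 3)
    for (i in seq_len(n_obj)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- c(runif(1, r_xy[i], wx - r_xy[i]),
                  runif(1, r_xy[i], wy - r_xy[i]),
                  runif(1, r_z[i], wz - r_z[i]))
        if (cand[1] < r_xy[i] || cand[1] > wx - r_xy[i]) next
        if (i > 1) {
          dd <- sqrt(colSums((t(centres[seq_len(i - 1), , drop = FALSE]) -
                                cand)^2))
          if (any(dd < cfg$min_separation)) next
        }
        centres[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        if (cfg$on_boundary == "error")
          stop("could not place object ", i, " inside the stack boundary")
        stop("failed to place object ", i,
             " after 200 attempts; reduce counts or min_separation")
      }
    }
    for (i in seq_len(n_obj))
      dens <- stamp_blob(dens, centres[i, ], r_xy[i], r_z[i],
                         cfg$swelling_intensity, px, zs)
    geo <- blob_geometry(r_xy, r_z, px, zs)
    truth <- data.frame(
      x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
      radius_xy_um = r_xy, radius_z_um = r_z,
      volume_um3 = geo$volume_um3, size_class = cls,
      passes_filter = recompute_filter_flags(
        data.frame(radius_xy_um = r_xy, radius_z_um = r_z), px, zs)
    )
  }
  attr(truth, "fibre_paths") <- fibre_paths

  # illumination: base level plus smooth linear gradient
  gx <- matrix(rep(seq_len(W) - 1, each = H), H, W) / max(W - 1, 1)
  grad <- cfg$background_gradient_amplitude * gx
  img <- array(0, c(H, W, D))
  for (k in seq_len(D)) {
    base <- cfg$background_level + grad
    img[, , k] <- if (cfg$mode == "brightfield") base - dens[, , k]
                  else base + dens[, , k]
  }
  if (cfg$noise_sd > 0)
    img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img <- pmin(pmax(round_half_up(img), 0), 255)

  list(stack = image_stack(img, pixel_size = px, z_step = zs, bit_depth = 8),
       truth = truth, config = cfg)
}

# max-combine a Gaussian disc of peak `amp` centred on pixel (row, col)
stamp_disc <- function(mat, row, col, amp, sigma_px) {
  r <- ceiling(2 * sigma_px)
  rows <- max(1, row - r):min(nrow(mat), row + r)
  cols <- max(1, col - r):min(ncol(mat), col + r)
  d2 <- outer((rows - row)^2, (cols - col)^2, "+")
  patch <- amp * exp(-d2 / (2 * sigma_px^2))
  patch[d2 > (2 * sigma_px)^2] <- 0
  mat[rows, cols] <- pmax(mat[rows, cols], patch)
  mat
}

# max-combine an anisotropic Gaussian blob truncated at 2 sigma;
# centre in um, radii are the 2-sigma truncation extents
stamp_blob <- function(dens, centre, r_xy, r_z, amp, px, zs) {
  d <- dim(dens)
  sx <- r_xy / 2; sz <- r_z / 2
  xs <- (seq_len(d[2]) - 0.5) * px
  ys <- (seq_len(d[1]) - 0.5) * px
  zvals <- (seq_len(d[3]) - 0.5) * zs
  ci <- which(abs(xs - centre[1]) <= r_xy)
  ri <- which(abs(ys - centre[2]) <= r_xy)
  ki <- which(abs(zvals - centre[3]) <= r_z)
  if (!length(ci) || !length(ri) || !length(ki)) return(dens)
  mx2 <- ((xs[ci] - centre[1]) / sx)^2
  my2 <- ((ys[ri] - centre[2]) / sx)^2       # isotropic in-plane
  for (k in ki) {
    mz2 <- ((zvals[k] - centre[3]) / sz)^2
    m2 <- outer(my2, mx2, "+") + mz2
    patch <- amp * exp(-m2 / 2)
    patch[m2 > 4] <- 0                       # 2-sigma truncation
    dens[ri, ci, k] <- pmax(dens[ri, ci, k], patch)
  }
  dens
}
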