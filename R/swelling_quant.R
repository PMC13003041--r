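#' Parameters of the axonal-swelling quantification macro
#'
#' The processing chain applied to each z-stack is fixed: 8-bit
#' conversion, contrast inversion, rolling-ball background subtraction,
#' pixel subtraction, median smoothing, contrast enhancement, automatic
#' thresholding and 3-D particle analysis. Particles count as axonal
#' swellings only when their maximum single-slice cross-section is
#' strictly larger than `min_area` (0.53 um^2) AND they contain at least
#' `min_voxels` (5) voxels. The enhancement constants (subtraction value,
#' median radius, contrast saturation, rolling-ball radius) are exposed
#' here with documented defaults.
#'
#' @param min_area area filter, um^2; strict inequality ("larger than").
#' @param min_voxels voxel filter; non-strict ("a minimum of").
#' @param rolling_ball_radius background-subtraction ball radius, pixels.
#' @param subtract_value constant removed after background subtraction
#'   (suppresses residual diffuse staining and faint fibres), 0-255.
#' @param median_radius median-smoothing disc radius, pixels.
#' @param contrast_saturation saturated fraction of the contrast stretch.
#' @param threshold_method automatic threshold; only `"moments"` is
#'   currently implemented.
#' @param projection if TRUE, analyse the maximum-intensity projection
#'   (2-D particles, "voxels" = pixels) instead of 3-D components.
#' @return A `swelling_params` list.
#' @export
swelling_params <- function(min_area = 0.53, min_voxels = 5,
                            rolling_ball_radius = 20, subtract_value = 50,
                            median_radius = 1, contrast_saturation = 0.0035,
                            threshold_method = "moments",
                            projection = FALSE) {
  stopifnot(min_area > 0, min_voxels >= 1, rolling_ball_radius >= 1,
            subtract_value >= 0, subtract_value <= 255, median_radius >= 1)
  threshold_method <- match.arg(threshold_method, "moments")
  structure(as.list(environment()), class = "swelling_params")
}

filter_particles <- function(particles, min_area, min_voxels) {
  particles[particles$max_slice_area_um2 > min_area &
              particles$n_voxels >= min_voxels, , drop = FALSE]
}

#' Quantify axonal swellings in one calibrated z-stack
#'
#' Runs the full macro (see [swelling_params()]) and applies the physical
#' size filters. The stack must carry micrometre calibration: the area
#' filter is physical.
#'
#' @param stack an [image_stack()] (brightfield convention: staining is
#'   dark on a bright background; the pipeline inverts contrast).
#' @param params a [swelling_params()].
#' @param stack_id optional identifier recorded in the result.
#' @return A `swelling_result`: `n_swellings`, `median_volume` (um^3; `NA`
#'   and flagged undefined when no swelling is found), the post-filter
#'   `particles` data frame, the threshold used, and the parameters.
#' @export
quantify_stack <- function(stack, params = swelling_params(),
                           stack_id = NULL) {
  assert_stack(stack)
  if (is.null(stack$pixel_size) || is.null(stack$z_step))
    stop("stack is uncalibrated; the area filter is physical")
  s <- to_uint8(stack)
  s <- invert(s)
  s <- rolling_ball_background(s, params$rolling_ball_radius)$corrected
  s <- subtract_constant(s, params$subtract_value)
  s <- median_filter(s, params$median_radius)
  s <- suppressWarnings(enhance_contrast(s, params$contrast_saturation))
  if (isTRUE(params$projection)) {
    proj <- apply(s$voxels, c(1, 2), max)
    s <- image_stack(proj, pixel_size = s$pixel_size, z_step = s$z_step,
                     bit_depth = 8)
  }
  thr <- moments_threshold(histogram256(s))
  cc <- connected_components(binarize(s, thr), connectivity = 26)
  kept <- filter_particles(cc$particles, params$min_area, params$min_voxels)
  rownames(kept) <- NULL
  structure(
    list(n_swellings = nrow(kept),
         median_volume = if (nrow(kept)) median(kept$volume_um3) else NA_real_,
         median_volume_defined = nrow(kept) > 0,
         particles = kept, threshold = thr, params = params,
         stack_id = stack_id),
    class = "swelling_result"
  )
}

#' @export
print.swelling_result <- function(x, ...) {
  cat(sprintf("swelling_result%s: %d swelling(s), median volume %s um^3, threshold %d\n",
              if (is.null(x$stack_id)) "" else paste0(" [", x$stack_id, "]"),
              x$n_swellings,
              if (x$median_volume_defined) sprintf("%.3g", x$median_volume)
              else "undefined",
              x$threshold))
  invisible(x)
}

#' Summarise swelling results across an animal's stacks
#'
#' Per animal (typically 12 stacks: 6 sections x 2 hemispheres), the total
#' swelling count is the sum over stacks and the median volume is taken
#' over the pooled per-particle volumes.
#'
#' @param results non-empty list of [quantify_stack()] results.
#' @param animal_id identifier for the animal.
#' @return An `animal_swelling_summary` with `animal_id`, `n_stacks`,
#'   `total_swellings`, `median_volume` (um^3, `NA` when no particle).
#' @export
summarize_animal <- function(results, animal_id) {
  if (!length(results)) stop("empty result list")
  if (!all(vapply(results, inherits, logical(1), "swelling_result")))
    stop("all elements must be swelling_result objects")
  vols <- unlist(lapply(results, function(r) r$particles$volume_um3))
  structure(
    list(animal_id = animal_id,
         n_stacks = length(results),
         total_swellings = sum(vapply(results, `[[`, numeric(1),
                                      "n_swellings")),
         median_volume = if (length(vols)) median(vols) else NA_real_),
    class = "animal_swelling_summary"
  )
}

#' Match detected swellings to ground-truth objects
#'
#' Greedy nearest-neighbour matching of detected particle centroids to
#' true object centres within `max_dist` micrometres; used to score the
#' detector against synthetic stacks.
#'
#' @param particles post-filter particle data frame from
#'   [quantify_stack()].
#' @param truth ground-truth data frame from [generate_image_stack()];
#'   only objects with `passes_filter = TRUE` count as targets.
#' @param max_dist matching radius in micrometres.
#' @return List with `recall`, `precision`, `n_matched`, `n_true`,
#'   `n_detected`.
#' @export
match_detections <- function(particles, truth, max_dist = 1.5) {
  tpos <- truth[truth$passes_filter, , drop = FALSE]
  n_true <- nrow(tpos); n_det <- nrow(particles)
  if (n_true == 0 || n_det == 0)
    return(list(recall = if (n_true == 0) NA_real_ else 0,
                precision = if (n_det == 0) NA_real_ else 0,
                n_matched = 0L, n_true = n_true, n_detected = n_det))
  dmat <- outer(particles$x_um, tpos$x_um, "-")^2 +
    outer(particles$y_um, tpos$y_um, "-")^2 +
    outer(particles$z_um, tpos$z_um, "-")^2
  dmat <- sqrt(dmat)
  matched <- 0L
  while (TRUE) {
    m <- which.min(dmat)
    if (!length(m) || min(dmat, na.rm = TRUE) > max_dist) break
    ij <- arrayInd(m, dim(dmat))
    matched <- matched + 1L
    dmat[ij[1], ] <- Inf
    dmat[, ij[2]] <- Inf
    if (all(!is.finite(dmat))) break
  }
  list(recall = matched / n_true, precision = matched / n_det,
       n_matched = matched, n_true = n_true, n_detected = n_det)
}
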