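#' Region-of-interest densitometry, glial area fractions and stereology
#'
#' Operators for the region-level quantifications: background-normalised
#' optical density of immunostained sections, glial (GFAP/IBA-1) positive
#' area fractions, and the optical-fractionator / Cavalieri stereological
#' estimators.
#'
#' @name region_quant
NULL

#' Region of interest
#'
#' @param label region name (e.g. `"striatum"`, `"SNr"`, `"NAcc"`,
#'   `"corpus_callosum"`).
#' @param mask logical 2-D matrix, TRUE inside the region.
#' @return An `roi` object.
#' @export
roi <- function(label, mask) {
  if (!nzchar(label)) stop("label must be non-empty")
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) stop("empty ROI mask")
  structure(list(label = label, mask = mask), class = "roi")
}

#' Background-normalised optical density of a section
#'
#' Mean staining intensity over the region minus the mean over an
#' anatomical background region (corpus callosum or basal cerebral
#' peduncle), on the same section. Scanned brightfield sections are
#' inverted first (`invert_input = TRUE`, the default) so that more
#' staining gives a larger OD. The result may be negative; it is reported,
#' not clamped, and is invariant to adding a constant to the whole image.
#'
#' @param image a depth-1 [image_stack()] (a scanned section).
#' @param region,background_roi [roi()] objects within the image bounds.
#' @param invert_input invert the 8-bit image before measuring.
#' @return Optical density in arbitrary units.
#' @export
optical_density <- function(image, region, background_roi,
                            invert_input = TRUE) {
  assert_stack(image)
  if (dim(image$voxels)[3] != 1L) stop("expected a single-section image")
  sl <- image$voxels[, , 1]
  for (r in list(region, background_roi)) {
    if (!inherits(r, "roi")) stop("regions must be roi objects")
    if (!all(dim(r$mask) == dim(sl))) stop("ROI mask does not match image size")
  }
  if (invert_input) sl <- (2^image$bit_depth - 1) - sl
  mean(sl[region$mask]) - mean(sl[background_roi$mask])
}

#' Per-animal regional OD from per-section values
#'
#' Animals contribute several sections per region (e.g. 9-15 striatal
#' sections); the per-animal value is the mean across sections.
#'
#' @param section_od numeric vector of per-section OD values (>= 1).
#' @param region region label recorded in the output.
#' @return List with `region`, `n_sections`, `od`.
#' @export
animal_region_od <- function(section_od, region = NA_character_) {
  if (!length(section_od)) stop("no sections")
  list(region = region, n_sections = length(section_od),
       od = mean(section_od))
}

#' Glial quantification parameters
#'
#' Defaults follow the batch settings of the glial-activation workflow:
#' rolling-ball radius 20 pixels, Gaussian blur sigma 2 pixels, Moments
#' auto-threshold.
#'
#' @param rolling_ball_radius background-subtraction radius, pixels;
#'   0 skips background subtraction (pre-corrected images).
#' @param gaussian_sigma blur SD in pixels.
#' @param threshold_method only `"moments"` is implemented.
#' @param contrast_saturation saturation of the automatic
#'   brightness/contrast adjustment.
#' @return A `glia_params` list.
#' @export
glia_params <- function(rolling_ball_radius = 20, gaussian_sigma = 2,
                        threshold_method = "moments",
                        contrast_saturation = 0.0035) {
  stopifnot(rolling_ball_radius >= 0, gaussian_sigma > 0)
  threshold_method <- match.arg(threshold_method, "moments")
  structure(as.list(environment()), class = "glia_params")
}

#' Positive-area fraction of a glial marker image
#'
#' Batch pipeline for GFAP+/IBA-1+ area quantification: rolling-ball
#' background subtraction, Gaussian blur, automatic contrast adjustment,
#' Moments threshold; the positive fraction is the thresholded foreground
#' fraction, also returned as absolute area relative to the calibrated
#' field size.
#'
#' @param image a calibrated 2-D (depth-1) [image_stack()]; fluorescence
#'   convention (signal bright on dark), no inversion.
#' @param params a [glia_params()].
#' @return List with `fraction` (positive area / total area),
#'   `positive_area_mm2`, `total_area_mm2`, `threshold`.
#' @export
positive_area_fraction <- function(image, params = glia_params()) {
  assert_stack(image)
  if (is.null(image$pixel_size)) stop("uncalibrated image")
  s <- to_uint8(image)
  if (params$rolling_ball_radius >= 1)
    s <- rolling_ball_background(s, params$rolling_ball_radius)$corrected
  s <- gaussian_blur(s, params$gaussian_sigma)
  s <- with_voxels(s, round_half_up(s$voxels))
  s <- suppressWarnings(enhance_contrast(s, params$contrast_saturation))
  thr <- moments_threshold(histogram256(s))
  bin <- binarize(s, thr)
  frac <- mean(bin$voxels)
  total_mm2 <- prod(dim(image$voxels)[1:2]) * (image$pixel_size / 1000)^2
  list(fraction = frac, positive_area_mm2 = frac * total_mm2,
       total_area_mm2 = total_mm2, threshold = thr)
}

#' Stereology sampling parameters
#'
#' Defaults are the sampling design of the nigral counts this pipeline
#' targets: section sampling fraction 1/5, 50 x 50 um counting frames
#' separated by 60 um, height sampling fraction 0.95.
#'
#' @param ssf section sampling fraction, in (0, 1].
#' @param frame_side counting-frame side, um.
#' @param frame_separation separation between dissector frames, um. Read
#'   as the inter-frame gap by default, so the grid step is
#'   `frame_side + frame_separation`; set `separation_is_step = TRUE` to
#'   read it as the full grid step instead.
#' @param hsf height sampling fraction, in (0, 1].
#' @param section_thickness section thickness, um (for Cavalieri volumes).
#' @param separation_is_step see `frame_separation`.
#' @return A `stereology_params` list.
#' @export
stereology_params <- function(ssf = 1 / 5, frame_side = 50,
                              frame_separation = 60, hsf = 0.95,
                              section_thickness = 40,
                              separation_is_step = FALSE) {
  stopifnot(ssf > 0, ssf <= 1, hsf > 0, hsf <= 1,
            frame_side > 0, frame_separation > 0, section_thickness > 0)
  if (separation_is_step && frame_separation < frame_side)
    stop("grid step smaller than the counting frame")
  structure(as.list(environment()), class = "stereology_params")
}

area_sampling_fraction <- function(params) {
  step <- if (params$separation_is_step) params$frame_separation
          else params$frame_side + params$frame_separation
  params$frame_side^2 / step^2
}

#' Optical-fractionator estimate of total cell number
#'
#' `N = sum(Q) * (1/ssf) * (1/asf) * (1/hsf)`, where `Q` are the cells
#' counted in the dissector frames and `asf` is the area sampling
#' fraction `frame_side^2 / grid_step^2`.
#'
#' @param section_counts non-negative counted cells per section.
#' @param params a [stereology_params()].
#' @return Estimated total number of cells.
#' @export
optical_fractionator <- function(section_counts, params = stereology_params()) {
  if (any(section_counts < 0)) stop("negative counts")
  sum(section_counts) / (params$ssf * area_sampling_fraction(params) *
                           params$hsf)
}

#' Cavalieri volume and cell density
#'
#' Reference volume from summed section areas:
#' `V = sum(areas) * section_thickness * (1/ssf)` (thickness converted
#' from um to mm), and density `N / V` in cells/mm^3.
#'
#' @param section_areas per-section areas in mm^2 (>= 0).
#' @param params a [stereology_params()].
#' @param N total cell number, e.g. from [optical_fractionator()].
#' @return List with `volume_mm3` and `density_per_mm3`.
#' @export
cavalieri_density <- function(section_areas, params = stereology_params(),
                              N) {
  if (any(section_areas < 0)) stop("negative section areas")
  V <- sum(section_areas) * (params$section_thickness / 1000) / params$ssf
  if (V == 0 && N > 0) stop("zero reference volume with a positive count")
  list(volume_mm3 = V,
       density_per_mm3 = if (V > 0) N / V else NA_real_)
}
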