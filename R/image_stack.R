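#' Calibrated image stack
#'
#' Container for a 3-D grayscale microscopy stack with physical calibration.
#' Voxels are stored as a numeric array of dimension `(y, x, z)`, so
#' `voxels[, , k]` is the k-th z-slice as a matrix. A 2-D image is a
#' depth-1 stack.
#'
#' @param voxels numeric matrix (single slice) or 3-D array `(y, x, z)`.
#' @param pixel_size lateral calibration, micrometres per pixel.
#' @param z_step axial calibration, micrometres per z-slice.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size, z_step = 1, bit_depth = 8) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(z_step) || z_step <= 0) stop("z_step must be > 0")
  vmax <- 2^bit_depth - 1
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("intensities outside [0, %d] for bit depth %d", vmax, bit_depth))
  structure(
    list(voxels = voxels, bit_depth = as.integer(bit_depth),
         pixel_size = pixel_size, z_step = z_step),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d x %d px, %d slice(s), %d-bit, %.4g um/px, %.4g um z-step\n",
    d[2], d[1], d[3], x$bit_depth, x$pixel_size, x$z_step))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

is_image_stack <- function(x) inherits(x, "image_stack")

assert_stack <- function(stack) {
  if (!is_image_stack(stack)) stop("expected an image_stack")
  invisible(stack)
}

# rebuild a stack with new voxel data, keeping calibration
with_voxels <- function(stack, voxels, bit_depth = stack$bit_depth) {
  image_stack(voxels, pixel_size = stack$pixel_size, z_step = stack$z_step,
              bit_depth = bit_depth)
}

#' Read a calibrated stack from a multi-page TIFF
#'
#' Reads a (multi-page) grayscale TIFF into an [image_stack()]. Calibration
#' is taken from the function arguments or, when present, from a JSON
#' sidecar `<file>.json` written by [write_stack_tiff()].
#'
#' @param path TIFF file path.
#' @param pixel_size,z_step calibration in micrometres; overridden by a
#'   sidecar file when one exists.
#' @param bit_depth target bit depth of the returned stack.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size = NULL, z_step = NULL,
                            bit_depth = 8) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size)) pixel_size <- meta$pixel_size
    if (!is.null(meta$z_step)) z_step <- meta$z_step
    if (!is.null(meta$bit_depth)) bit_depth <- meta$bit_depth
  }
  if (is.null(pixel_size) || is.null(z_step))
    stop("no calibration: supply pixel_size and z_step or provide a sidecar")
  vmax <- 2^bit_depth - 1
  vox <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    round(p * vmax)
  }, matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  image_stack(vox, pixel_size = pixel_size, z_step = z_step,
              bit_depth = bit_depth)
}

#' Write a stack as multi-page TIFF with a JSON calibration sidecar
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; a sidecar `<path>.json` with calibration
#'   (and any `extra` metadata, e.g. ground truth) is written alongside.
#' @param extra optional named list merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, extra = NULL) {
  assert_stack(stack)
  vmax <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$voxels)[3]),
                  function(k) stack$voxels[, , k] / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  meta <- c(list(pixel_size = stack$pixel_size, z_step = stack$z_step,
                 bit_depth = stack$bit_depth), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
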