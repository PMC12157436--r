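#' Recorded image stack
#'
#' Container for an N-frame movie of I x J pixel measurements together with
#' the acquisition metadata the likelihood needs. Values are stored as an
#' `I x J x N` array indexed `values[i, j, n]` where `i` is the x (column)
#' pixel index and `j` the y (row) pixel index; pixel `(i, j)` (1-based in R)
#' covers the half-open square
#' `[(i-1) d, i d) x [(j-1) d, j d)` in nm, with `d` the pixel pitch.
#'
#' @param values Numeric `I x J x N` array (a matrix is taken as one frame).
#'   ADU counts for an EMCCD, 0/1 for a SPAD array.
#' @param pixel_size_nm Pixel pitch in nm.
#' @param exposure_time_s Frame exposure time in seconds.
#' @return Object of class `image_stack` with fields `values`, `n_frames`,
#'   `height` (I), `width` (J), `pixel_size_nm`, `exposure_time_s`.
#' @export
image_stack <- function(values, pixel_size_nm, exposure_time_s) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  .assert(is.array(values) && length(dim(values)) == 3L,
          "values must be an I x J x N array")
  .assert(all(is.finite(values)), "image stack values must be finite")
  .assert(.is_scalar(pixel_size_nm) && pixel_size_nm > 0,
          "pixel_size_nm must be > 0")
  .assert(.is_scalar(exposure_time_s) && exposure_time_s > 0,
          "exposure_time_s must be > 0")
  d <- dim(values)
  structure(list(values = values, n_frames = d[3L], height = d[1L],
                 width = d[2L], pixel_size_nm = pixel_size_nm,
                 exposure_time_s = exposure_time_s),
            class = "image_stack")
}

#' Validate an image stack against a camera model
#'
#' SPAD stacks must be strictly binary; EMCCD stacks only need finite values.
#'
#' @param stack An [image_stack()].
#' @param camera A [camera_emccd()] or [camera_spad()].
#' @return The stack, invisibly; errors with a diagnostic otherwise.
#' @export
validate_stack <- function(stack, camera) {
  .assert(inherits(stack, "image_stack"), "expected an image_stack")
  if (inherits(camera, "camera_spad")) {
    bad <- !(stack$values %in% c(0, 1))
    if (any(bad)) {
      stop(sprintf(
        "SPAD stack must be binary: %d pixel(s) outside {0,1} (first bad value %g)",
        sum(bad), stack$values[which(bad)[1L]]), call. = FALSE)
    }
  }
  invisible(stack)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d frames of %d x %d px, pixel %g nm, exposure %g s\n",
              x$n_frames, x$height, x$width, x$pixel_size_nm, x$exposure_time_s))
  invisible(x)
}
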