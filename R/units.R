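#' Convert an area in square micrometres to a pixel count
#'
#' Object-size thresholds in the pipeline are stated in physical units
#' (square micrometres); masks are measured in pixels. With an isotropic
#' pixel size `s` (micrometres per pixel), one pixel covers `s^2` um^2.
#'
#' @param area_um2 Area in square micrometres (>= 0).
#' @param pixel_size_um Isotropic pixel size in micrometres per pixel (> 0).
#' @return Equivalent area in pixels (real-valued, not rounded).
#' @examples
#' area_um2_to_px(3, 0.173)
#' @export
area_um2_to_px <- function(area_um2, pixel_size_um) {
  check_pixel_size(pixel_size_um)
  if (any(area_um2 < 0)) stop("area_um2 must be >= 0", call. = FALSE)
  area_um2 / pixel_size_um^2
}

#' Convert a pixel count to an area in square micrometres
#'
#' @param area_px Area in pixels (>= 0).
#' @inheritParams area_um2_to_px
#' @return Area in square micrometres.
#' @export
px_to_area_um2 <- function(area_px, pixel_size_um) {
  check_pixel_size(pixel_size_um)
  area_px * pixel_size_um^2
}

#' Convert a length in micrometres to pixels
#'
#' @param length_um Length in micrometres (>= 0).
#' @inheritParams area_um2_to_px
#' @return Length in pixels (real-valued).
#' @examples
#' length_um_to_px(10, 0.173)
#' @export
length_um_to_px <- function(length_um, pixel_size_um) {
  check_pixel_size(pixel_size_um)
  if (any(length_um < 0)) stop("length_um must be >= 0", call. = FALSE)
  length_um / pixel_size_um
}

#' Convert a length in pixels to micrometres
#'
#' @param length_px Length in pixels (>= 0).
#' @inheritParams area_um2_to_px
#' @return Length in micrometres.
#' @export
px_to_length_um <- function(length_px, pixel_size_um) {
  check_pixel_size(pixel_size_um)
  length_px * pixel_size_um
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single finite value > 0", call. = FALSE)
  }
  invisible(pixel_size_um)
}
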