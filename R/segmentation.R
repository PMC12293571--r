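#' Segment nuclei from the DAPI channel
#'
#' The `classical` backend is fully deterministic: Gaussian smoothing
#' (sigma = diameter/8), Otsu threshold on the smoothed image, then a
#' distance-transform watershed that splits touching nuclei. Objects
#' smaller than `min_area_nm2` are removed. The `learned` backend refers
#' to a pretrained generalist cell-segmentation network; no such backend
#' is bundled with this package, and requesting it raises an error
#' pointing at the classical fallback.
#'
#' @param dapi Numeric matrix (DAPI channel).
#' @param cell_diameter_um Expected nucleus diameter in micrometres
#'   (default 10).
#' @param min_area_nm2 Minimum object area in square nanometres
#'   (default 41994, the reference configuration value as printed).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param backend `"classical"` (default) or `"learned"`.
#' @return A `label_mask` of kind `nuclei`.
#' @export
segment_nuclei <- function(dapi, cell_diameter_um = 10,
                           min_area_nm2 = 41994, pixel_size_um = 0.173,
                           backend = c("classical", "learned")) {
  backend <- match.arg(backend)
  if (backend == "learned") {
    stop("the learned nuclei-segmentation backend is not available in this ",
         "installation; use backend = \"classical\"", call. = FALSE)
  }
  if (cell_diameter_um <= 0) stop("cell_diameter_um must be > 0", call. = FALSE)
  d_px <- length_um_to_px(cell_diameter_um, pixel_size_um)
  empty <- label_mask(matrix(0L, nrow(dapi), ncol(dapi)), "nuclei",
                      pixel_size_um)
  if (max(dapi) <= min(dapi)) return(empty)

  sigma <- max(1, d_px / 8)
  sm <- fft_convolve(dapi, kernel_fft(gaussian_kernel(sigma), dim(dapi)))
  rng <- range(sm)
  norm <- (sm - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) return(empty)

  dm <- EBImage::distmap(mask)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1,
                                               ext = max(1L, as.integer(round(d_px / 8)))))
  storage.mode(lab) <- "integer"

  min_area_px <- area_um2_to_px(min_area_nm2 / 1e6, pixel_size_um)
  lab <- drop_small_labels(lab, min_area_px)
  label_mask(lab, "nuclei", pixel_size_um)
}

# remove labels with pixel area < min_area_px (strictly below), keeping
# original label ids
drop_small_labels <- function(lab, min_area_px) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab, nbins = max(lab))
  drop <- which(areas > 0 & areas < min_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Segment epithelial regions from the pan-cytokeratin channel
#'
#' Bright-object intensity threshold segmentation: connected components of
#' pixels strictly above `threshold`, components kept only when their area
#' strictly exceeds `min_region_area_um2`, then internal holes filled
#' (the reference "fill inclusions" step, tissue mode only). An empty
#' mask is a valid result.
#'
#' @param pan_ck Numeric matrix (pan-cytokeratin channel).
#' @param threshold Intensity threshold; pixels `> threshold` are
#'   foreground (default 500).
#' @param min_region_area_um2 Area filter; regions with area
#'   `> min_region_area_um2` are kept (default 15).
#' @param fill_holes Fill internal holes of each region (default TRUE).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return A `label_mask` of kind `epithelium`.
#' @export
segment_epithelium <- function(pan_ck, threshold = 500,
                               min_region_area_um2 = 15, fill_holes = TRUE,
                               pixel_size_um = 0.173) {
  mask <- pan_ck > threshold
  lab <- matrix(0L, nrow(pan_ck), ncol(pan_ck))
  if (any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(mask))
    storage.mode(lab) <- "integer"
    min_px <- area_um2_to_px(min_region_area_um2, pixel_size_um)
    if (max(lab) > 0L) {
      areas <- tabulate(lab, nbins = max(lab))
      drop <- which(areas > 0 & areas <= min_px)   # keep strictly > min
      if (length(drop)) lab[lab %in% drop] <- 0L
    }
    if (fill_holes && max(lab) > 0L) {
      lab <- EBImage::imageData(EBImage::fillHull(lab))
      storage.mode(lab) <- "integer"
    }
  }
  label_mask(lab, "epithelium", pixel_size_um)
}

#' Detect nucleoli in a dark-sphere response map
#'
#' Runs the blob finder on the output of [enhance_dark_spheres()]:
#' response basins whose peak reaches `probability_threshold_pct` of the
#' global response maximum become nucleoli; adjacent basins are merged
#' unless the saddle-to-peak ratio falls below `split_sensitivity_pct`.
#'
#' @param response Non-negative response map from [enhance_dark_spheres()].
#' @param params A [blob_params()]; reference configuration:
#'   diameter 3 um, probability threshold 5.03%, split sensitivity 65.23%.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param min_contrast Absolute response floor for detection (default 100
#'   detector counts of band-pass contrast; see vignette).
#' @return A `label_mask` of kind `nucleoli`.
#' @export
detect_nucleoli <- function(response,
                            params = blob_params(3, 5.03, 65.23),
                            pixel_size_um = 0.173, min_contrast = 100) {
  d_px <- length_um_to_px(params$diameter_um, pixel_size_um)
  lab <- blob_finder(response, d_px, params$probability_threshold_pct,
                     params$split_sensitivity_pct, min_contrast)
  label_mask(lab, "nucleoli", pixel_size_um)
}

#' Detect candidate marker foci
#'
#' Small-scale bright-blob detection on the marker channel at the
#' configured diameter (reference: 0.7 um, probability threshold 13%,
#' split sensitivity 65%). Detection may run on an enhanced copy of the
#' channel; per-focus intensity statistics are always measured on
#' `measure_on` (the original, unenhanced marker channel).
#'
#' @param marker Numeric matrix used for detection.
#' @param params A [blob_params()].
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param measure_on Channel for intensity measurement (default `marker`).
#' @param min_contrast Absolute response floor (default 100).
#' @param noise_floor_k Noise-referenced floor: candidate blobs must also
#'   exceed `noise_floor_k` times the robust noise scale (MAD) of the
#'   unclamped band-pass response (default 45). Shot noise produces
#'   spurious response maxima up to roughly 40x this scale over a
#'   megapixel image, while diffraction-limited foci of meaningful
#'   contrast sit above it; on noise-free input the scale collapses to
#'   zero and only `min_contrast` applies. This keeps the relative
#'   probability threshold well-defined on images with no true foci.
#' @return List with `mask` (a `label_mask` of kind `foci`) and
#'   `features`: data frame with one row per focus (label, centroid row
#'   and column, `area_px`, `max_intensity`, `sum_intensity`).
#' @export
detect_foci <- function(marker, params = blob_params(0.7, 13, 65),
                        pixel_size_um = 0.173, measure_on = marker,
                        min_contrast = 100, noise_floor_k = 45) {
  d_px <- length_um_to_px(params$diameter_um, pixel_size_um)
  response <- bright_blob_response(marker, d_px)
  noise <- attr(response, "noise_scale") %||% 0
  floor_eff <- max(min_contrast, noise_floor_k * noise)
  lab <- blob_finder(response, d_px, params$probability_threshold_pct,
                     params$split_sensitivity_pct, floor_eff)
  list(mask = label_mask(lab, "foci", pixel_size_um),
       features = object_features(lab, measure_on))
}

#' Per-object geometry and intensity statistics for a label mask
#'
#' @param lab Integer label matrix or `label_mask`.
#' @param intensity Numeric matrix to measure on.
#' @return Data frame: `label`, `centroid_row`, `centroid_col`, `area_px`,
#'   `max_intensity`, `sum_intensity`, `mean_intensity`.
#' @export
object_features <- function(lab, intensity) {
  lab <- resolve_labels(lab)
  labels <- mask_labels(lab)
  if (!length(labels)) {
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      max_intensity = numeric(0), sum_intensity = numeric(0),
                      mean_intensity = numeric(0)))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  v <- intensity[idx]
  f <- factor(l, levels = labels)
  data.frame(
    label = labels,
    centroid_row = as.numeric(tapply(rows, f, mean)),
    centroid_col = as.numeric(tapply(cols, f, mean)),
    area_px = as.integer(tapply(rep(1L, length(l)), f, sum)),
    max_intensity = as.numeric(tapply(v, f, max)),
    sum_intensity = as.numeric(tapply(v, f, sum)),
    mean_intensity = as.numeric(tapply(v, f, mean)),
    row.names = NULL
  )
}
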