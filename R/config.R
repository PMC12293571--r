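#' Pipeline configuration with the reference parameter set
#'
#' Returns the full set of tunable pipeline parameters. Defaults are the
#' reference high-throughput configuration: every filter threshold and
#' blob-detection setting carries the value used on the slide-scanner data
#' (0.173 um/px). Override any subset via `...`.
#'
#' Comparison directions are fixed and follow the reference rules
#' verbatim: pan-CK regions are kept at intensity `> 500` and area
#' `> 15` um^2; nucleoli at area `> 3` um^2; nuclei at area `< 400` um^2,
#' DAPI sum `> 50000`, at least one assigned nucleolus, and no
#' border-touching pixel; a nucleolus is assigned to a nucleus when inside
#' it or overlapping `>= 95%`; a nucleus is epithelial when `>= 50%` of its
#' pixels fall in one pan-CK region; a focus is nucleolar when inside a
#' dilated nucleolus or overlapping `>= 10%`, and is kept at max marker
#' intensity `> 400`; a nucleolus is stressed when its retained focus
#' count lies in `[1, 5]`.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "tissue",                 # "tissue" or "cellblock"
    pixel_size_um = 0.173,
    # epithelium (pan-cytokeratin) segmentation -- tissue mode only
    pan_ck_threshold = 500,
    pan_ck_min_area_um2 = 15,
    pan_ck_fill_holes = TRUE,
    # nuclei segmentation
    nucleus_diameter_um = 10,
    nucleus_min_area_nm2 = 41994,
    nuclei_backend = "classical",    # "classical" or "learned"
    # nuclei filtering
    nucleus_max_area_um2 = 400,
    nucleus_min_dapi_sum = 50000,
    # dark-sphere (nucleolus) enhancement of the RNA Pol II channel
    dark_sphere = list(size_min_um = 3, size_max_um = 15, sensitivity = 1133),
    # nucleolus blob finder + filters
    nucleolus_blob = list(diameter_um = 3, probability_threshold_pct = 5.03,
                          split_sensitivity_pct = 65.23),
    nucleolus_min_area_um2 = 3,
    nucleolus_containment_fraction = 0.95,
    # epithelial assignment
    epithelial_fraction = 0.50,
    # focus blob finder + filters
    focus_blob = list(diameter_um = 0.7, probability_threshold_pct = 13,
                      split_sensitivity_pct = 65),
    focus_overlap_fraction = 0.10,
    focus_max_intensity_min = 400,
    foci_count_min = 1,
    foci_count_max = 5,
    dilation_px = 1,
    # foci count window applied per nucleolus (reference manual rule:
    # a cell is positive if >= 1 nucleolus is in the window); set to
    # "nucleus" to pool retained foci across the cell's nucleoli instead
    foci_window_scope = "nucleolus",
    # nucleoplasm = nucleus minus UNDILATED nucleoli by default
    nucleoplasm_use_dilated = FALSE,
    # deconvolution-style enhancement feeding segmentation only
    enhancement = list(psf_sigma_px = 1.5, iterations = 10),
    seed = 1L
  )
  override_config(cfg, list(...))
}

override_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      sub <- overrides[[nm]]
      bad <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config field: ", nm, "$", bad[1], call. = FALSE)
      cfg[[nm]][names(sub)] <- sub
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$mode %in% c("tissue", "cellblock"))
  check_pixel_size(cfg$pixel_size_um)
  fracs <- c(cfg$nucleolus_containment_fraction, cfg$epithelial_fraction,
             cfg$focus_overlap_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("overlap fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$foci_count_min > cfg$foci_count_max) {
    stop("foci_count_min must be <= foci_count_max", call. = FALSE)
  }
  nums <- c(cfg$pan_ck_threshold, cfg$pan_ck_min_area_um2,
            cfg$nucleus_max_area_um2, cfg$nucleus_min_dapi_sum,
            cfg$nucleolus_min_area_um2, cfg$focus_max_intensity_min)
  if (any(!is.finite(nums))) stop("thresholds must be finite", call. = FALSE)
  if (cfg$dark_sphere$size_min_um <= 0 ||
      cfg$dark_sphere$size_min_um >= cfg$dark_sphere$size_max_um) {
    stop("dark_sphere sizes must satisfy 0 < size_min < size_max",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields absent from the file keep their [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  override_config(unclass(pipeline_config()), overrides)
}

#' Write a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
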