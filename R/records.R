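#' Build scored per-cell records from label masks
#'
#' Applies the full assignment-and-filter ledger to already-segmented
#' masks: nucleolus size filter, nucleolus-to-nucleus containment
#' assignment, epithelial assignment (tissue mode), the nucleus filters
#' (area, DAPI sum, nucleolar content, border, epithelium), nucleolus
#' dilation, focus assignment and filters, nucleoplasm subtraction, and
#' foci-count scoring. Intensity statistics are measured on the original
#' channels of `image`.
#'
#' @param nuclei,nucleoli,foci_mask `label_mask` objects (or matrices)
#'   for nuclei, candidate nucleoli and candidate foci.
#' @param foci_features Per-focus intensity table measured on the
#'   original marker channel (see [detect_foci()]); pass `NULL` to have
#'   it computed from `image`.
#' @param epithelium Epithelial `label_mask` or `NULL` (cell-block mode).
#' @param image A `multiplex_image` (original intensities).
#' @param config A [pipeline_config()].
#' @return An object of class `cell_records`: list with data frames
#'   `cells`, `nucleoli`, `foci`, the masks actually used (retained
#'   nuclei / nucleoli / dilated nucleoli / retained foci / nucleoplasm),
#'   and the configuration.
#' @export
build_cell_records <- function(nuclei, nucleoli, foci_mask,
                               foci_features = NULL, epithelium = NULL,
                               image, config = pipeline_config()) {
  px <- config$pixel_size_um
  nuc_lab <- resolve_labels(nuclei)
  ncl_lab <- resolve_labels(nucleoli)
  foc_lab <- resolve_labels(foci_mask)
  marker <- get_channel(image, "marker")
  dapi <- get_channel(image, "dapi")
  if (is.null(foci_features)) foci_features <- object_features(foc_lab, marker)

  # nucleolus size filter (> min area), then containment assignment
  ncl_filter <- filter_nucleoli(ncl_lab, config$nucleolus_min_area_um2, px)
  ncl_sized <- keep_labels(ncl_lab, ncl_filter$label[ncl_filter$kept])
  assignment <- assign_nucleoli(nuc_lab, ncl_sized,
                                config$nucleolus_containment_fraction)
  ncl_assigned <- keep_labels(ncl_sized, assignment$nucleolus)

  # epithelial flags (tissue mode with an epithelium mask)
  tissue <- identical(config$mode, "tissue") && !is.null(epithelium)
  epi_flags <- NULL
  epi_df <- NULL
  if (tissue) {
    epi_df <- assign_epithelial(nuc_lab, epithelium,
                                config$epithelial_fraction)
    epi_flags <- setNames(epi_df$epithelial, epi_df$nucleus)
  }

  counts <- table(assignment$nucleus)
  nuc_filter <- filter_nuclei(nuc_lab, dapi, counts,
                              max_area_um2 = config$nucleus_max_area_um2,
                              min_dapi_sum = config$nucleus_min_dapi_sum,
                              epithelial = epi_flags, pixel_size_um = px)
  kept_nuclei <- nuc_filter$nucleus[nuc_filter$kept]
  nuc_kept <- keep_labels(nuc_lab, kept_nuclei)

  # nucleoli belonging to retained nuclei
  assignment_kept <- assignment[assignment$nucleus %in% kept_nuclei, ,
                                drop = FALSE]
  ncl_kept <- keep_labels(ncl_assigned, assignment_kept$nucleolus)
  ncl_dilated <- dilate_nucleoli(ncl_kept, config$dilation_px)

  foci <- assign_and_filter_foci(foc_lab, foci_features, ncl_dilated,
                                 config$focus_overlap_fraction,
                                 config$focus_max_intensity_min)
  foci$nucleus <- assignment_kept$nucleus[match(foci$nucleolus,
                                                assignment_kept$nucleolus)]
  foc_kept <- keep_labels(foc_lab, foci$focus[foci$kept])

  sub <- if (isTRUE(config$nucleoplasm_use_dilated)) ncl_dilated else ncl_kept
  nucleoplasm <- compute_nucleoplasm(nuc_kept, sub)

  # per-nucleolus retained foci counts and scoring
  kept_foci <- foci[foci$kept, , drop = FALSE]
  per_ncl <- data.frame(nucleolus = assignment_kept$nucleolus,
                        nucleus = assignment_kept$nucleus)
  per_ncl$foci_count <- as.integer(
    table(factor(kept_foci$nucleolus, levels = per_ncl$nucleolus)))
  scores <- score_cells(per_ncl, kept_nuclei, config$foci_count_min,
                        config$foci_count_max, config$foci_window_scope)

  ncl_areas <- ncl_filter[match(per_ncl$nucleolus, ncl_filter$label), ,
                          drop = FALSE]
  nucleoli_df <- data.frame(
    label = per_ncl$nucleolus, nucleus = per_ncl$nucleus,
    area_px = ncl_areas$area_px, area_um2 = ncl_areas$area_um2,
    foci_count = per_ncl$foci_count,
    stressed = per_ncl$foci_count >= config$foci_count_min &
      per_ncl$foci_count <= config$foci_count_max)

  cells <- nuc_filter
  m <- match(cells$nucleus, scores$nucleus)
  cells$foci_count <- ifelse(is.na(m), NA_integer_, scores$foci_count[m])
  cells$n_stressed_nucleoli <- ifelse(is.na(m), NA_integer_,
                                      scores$n_stressed_nucleoli[m])
  cells$foci_positive <- ifelse(is.na(m), NA, scores$foci_positive[m])

  structure(list(
    cells = cells, nucleoli = nucleoli_df, foci = foci,
    masks = list(
      nuclei = label_mask(nuc_kept, "nuclei", px),
      nucleoli = label_mask(ncl_kept, "nucleoli", px),
      nucleoli_dilated = label_mask(resolve_labels(ncl_dilated), "nucleoli", px),
      foci = label_mask(foc_kept, "foci", px),
      nucleoplasm = label_mask(resolve_labels(nucleoplasm), "nucleoplasm", px),
      epithelium = if (tissue) {
        label_mask(resolve_labels(epithelium), "epithelium", px)
      } else NULL),
    epithelial = epi_df,
    config = config,
    image_name = image$name
  ), class = "cell_records")
}

#' @export
print.cell_records <- function(x, ...) {
  cat(sprintf("<cell_records '%s'> %d nuclei (%d retained), %d nucleoli, %d retained foci, %d foci-positive\n",
              x$image_name, nrow(x$cells), sum(x$cells$kept),
              nrow(x$nucleoli), sum(x$foci$kept),
              sum(x$cells$foci_positive[x$cells$kept], na.rm = TRUE)))
  invisible(x)
}

#' Run the full analysis pipeline on one multiplex image
#'
#' Enhancement (Richardson-Lucy on the channels feeding segmentation),
#' dark-sphere enhancement of the RNA Pol II channel, epithelium
#' segmentation (tissue mode), nuclei segmentation, nucleolus and focus
#' blob detection, then [build_cell_records()] and
#' [extract_feature_table()]. All intensity statistics are measured on
#' the original channels.
#'
#' @param image A `multiplex_image`.
#' @param config A [pipeline_config()]; its `pixel_size_um` is taken from
#'   the image.
#' @param quiet Suppress per-stage object counts on stderr.
#' @return List: `records` (a `cell_records`), `features` (the feature
#'   table), and `masks`.
#' @export
analyze_image <- function(image, config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(image, "multiplex_image"))
  config <- override_config(unclass(config),
                            list(pixel_size_um = image$pixel_size_um))
  px <- config$pixel_size_um
  say <- function(...) if (!quiet) message(sprintf(...))

  enh <- config$enhancement
  enhance <- function(ch) {
    enhance_richardson_lucy(ch, enh$psf_sigma_px, enh$iterations)
  }
  dapi <- get_channel(image, "dapi")
  rnapol2 <- get_channel(image, "rnapol2")
  marker <- get_channel(image, "marker")

  response <- enhance_dark_spheres(enhance(rnapol2),
                                   config$dark_sphere$size_min_um,
                                   config$dark_sphere$size_max_um,
                                   config$dark_sphere$sensitivity, px)

  epithelium <- NULL
  if (identical(config$mode, "tissue") && has_pan_ck(image)) {
    epithelium <- segment_epithelium(get_channel(image, "pan_ck"),
                                     config$pan_ck_threshold,
                                     config$pan_ck_min_area_um2,
                                     config$pan_ck_fill_holes, px)
    say("epithelium: %d region(s)", length(mask_labels(epithelium)))
  }

  nuclei <- segment_nuclei(enhance(dapi), config$nucleus_diameter_um,
                           config$nucleus_min_area_nm2, px,
                           backend = config$nuclei_backend)
  say("nuclei: %d", length(mask_labels(nuclei)))

  ncl_par <- config$nucleolus_blob
  nucleoli <- detect_nucleoli(response,
                              blob_params(ncl_par$diameter_um,
                                          ncl_par$probability_threshold_pct,
                                          ncl_par$split_sensitivity_pct), px)
  say("nucleolus candidates: %d", length(mask_labels(nucleoli)))

  foc_par <- config$focus_blob
  foci <- detect_foci(enhance(marker),
                      blob_params(foc_par$diameter_um,
                                  foc_par$probability_threshold_pct,
                                  foc_par$split_sensitivity_pct),
                      px, measure_on = marker)
  say("focus candidates: %d", nrow(foci$features))

  records <- build_cell_records(nuclei, nucleoli, foci$mask,
                                foci_features = foci$features,
                                epithelium = epithelium,
                                image = image, config = config)
  say("retained nuclei: %d, foci-positive: %d", sum(records$cells$kept),
      sum(records$cells$foci_positive[records$cells$kept], na.rm = TRUE))

  list(records = records,
       features = extract_feature_table(records, image),
       masks = records$masks)
}
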