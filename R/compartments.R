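# Pixel-overlap bookkeeping between label masks ------------------------

label_areas <- function(lab) {
  lab <- resolve_labels(lab)
  if (max(lab) == 0L) return(integer(0))
  a <- tabulate(lab, nbins = max(lab))
  setNames(a[a > 0], which(a > 0))
}

# counts of overlapping pixels for every (child, parent) label pair with
# parent > 0
overlap_table <- function(child, parent) {
  child <- resolve_labels(child); parent <- resolve_labels(parent)
  idx <- which(child > 0L & parent > 0L)
  if (!length(idx)) {
    return(data.frame(child = integer(0), parent = integer(0), n = integer(0)))
  }
  tab <- table(child = child[idx], parent = parent[idx])
  d <- as.data.frame(tab, stringsAsFactors = FALSE)
  d <- d[d$Freq > 0, ]
  data.frame(child = as.integer(d$child), parent = as.integer(d$parent),
             n = as.integer(d$Freq))
}

# labels that own at least one pixel on the image border
edge_labels <- function(lab) {
  lab <- resolve_labels(lab)
  border <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  sort(unique(border[border > 0L]))
}

keep_labels <- function(lab, labels) {
  lab <- resolve_labels(lab)
  out <- lab
  out[!(out %in% labels)] <- 0L
  out
}

# Assignment and filter operations --------------------------------------

#' Assign nucleoli to parent nuclei by containment
#'
#' A nucleolus is assigned to a nucleus when it lies fully inside it or
#' when at least `containment_fraction` of its pixels intersect that
#' nucleus (reference rule: inside or 95% intersection). Ties are broken
#' by larger overlap, then lower nucleus label. Nucleoli assigned to no
#' nucleus are dropped from the result.
#'
#' @param nuclei,nucleoli `label_mask` objects or integer label matrices
#'   of identical dimensions.
#' @param containment_fraction Required overlap fraction in `[0, 1]`
#'   (default 0.95, inclusive).
#' @return Data frame: `nucleolus`, `nucleus`, `overlap_px`,
#'   `overlap_fraction`.
#' @export
assign_nucleoli <- function(nuclei, nucleoli, containment_fraction = 0.95) {
  areas <- label_areas(nucleoli)
  ov <- overlap_table(nucleoli, nuclei)
  if (!nrow(ov)) {
    return(data.frame(nucleolus = integer(0), nucleus = integer(0),
                      overlap_px = integer(0), overlap_fraction = numeric(0)))
  }
  ov$area <- as.integer(areas[as.character(ov$child)])
  ov$frac <- ov$n / ov$area
  ov <- ov[ov$n == ov$area | ov$frac >= containment_fraction, , drop = FALSE]
  if (!nrow(ov)) {
    return(data.frame(nucleolus = integer(0), nucleus = integer(0),
                      overlap_px = integer(0), overlap_fraction = numeric(0)))
  }
  ov <- ov[order(ov$child, -ov$n, ov$parent), , drop = FALSE]
  best <- ov[!duplicated(ov$child), , drop = FALSE]
  data.frame(nucleolus = best$child, nucleus = best$parent,
             overlap_px = best$n, overlap_fraction = best$frac,
             row.names = NULL)
}

#' Filter nucleoli by area
#'
#' Nucleoli are retained when their area strictly exceeds
#' `min_area_um2` (reference rule: surface area > 3 um^2).
#'
#' @param nucleoli `label_mask` or integer label matrix.
#' @param min_area_um2 Strict lower area bound in square micrometres.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return Data frame: `label`, `area_px`, `area_um2`, `kept`.
#' @export
filter_nucleoli <- function(nucleoli, min_area_um2 = 3,
                            pixel_size_um = 0.173) {
  areas <- label_areas(nucleoli)
  if (!length(areas)) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), kept = logical(0)))
  }
  um2 <- px_to_area_um2(as.numeric(areas), pixel_size_um)
  data.frame(label = as.integer(names(areas)), area_px = as.integer(areas),
             area_um2 = um2, kept = um2 > min_area_um2, row.names = NULL)
}

#' Flag epithelial nuclei by overlap with pan-cytokeratin regions
#'
#' A nucleus is epithelial when at least `min_fraction` of its pixels lie
#' inside one single epithelial region (reference rule: at least 50%
#' intersection, evaluated per region -- overlap is not summed across
#' regions).
#'
#' @param nuclei,epithelium `label_mask` objects or label matrices.
#' @param min_fraction Inclusive overlap fraction in `[0, 1]`
#'   (default 0.5).
#' @return Data frame: `nucleus`, `best_region`, `overlap_fraction`,
#'   `epithelial`.
#' @export
assign_epithelial <- function(nuclei, epithelium, min_fraction = 0.5) {
  areas <- label_areas(nuclei)
  labs <- as.integer(names(areas))
  out <- data.frame(nucleus = labs, best_region = NA_integer_,
                    overlap_fraction = 0, epithelial = FALSE)
  ov <- overlap_table(nuclei, epithelium)
  if (nrow(ov)) {
    ov$frac <- ov$n / as.integer(areas[as.character(ov$child)])
    ov <- ov[order(ov$child, -ov$frac, ov$parent), , drop = FALSE]
    best <- ov[!duplicated(ov$child), , drop = FALSE]
    m <- match(best$child, out$nucleus)
    out$best_region[m] <- best$parent
    out$overlap_fraction[m] <- best$frac
    out$epithelial <- out$overlap_fraction >= min_fraction
  }
  out
}

#' Filter nuclei by size, intensity, nucleolar content and image border
#'
#' A nucleus is retained iff its area is strictly below
#' `max_area_um2`, its summed DAPI intensity strictly exceeds
#' `min_dapi_sum`, it has at least one assigned nucleolus, it touches no
#' image border, and -- in tissue mode -- it is epithelial.
#'
#' @param nuclei `label_mask` or label matrix.
#' @param dapi DAPI intensity matrix (original, unenhanced channel).
#' @param nucleolus_counts Named integer vector: assigned (size-filtered)
#'   nucleolus count per nucleus label.
#' @param max_area_um2 Strict upper area bound (default 400).
#' @param min_dapi_sum Strict lower DAPI-sum bound (default 50000).
#' @param epithelial Optional logical vector named by nucleus label;
#'   when supplied, non-epithelial nuclei are excluded (tissue mode).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return Data frame with one row per nucleus: `nucleus`, `area_px`,
#'   `area_um2`, `dapi_sum`, `n_nucleoli`, `touches_edge`, `epithelial`,
#'   `kept`, `reason` (first failed rule, or `NA` when kept).
#' @export
filter_nuclei <- function(nuclei, dapi, nucleolus_counts,
                          max_area_um2 = 400, min_dapi_sum = 50000,
                          epithelial = NULL, pixel_size_um = 0.173) {
  lab <- resolve_labels(nuclei)
  areas <- label_areas(lab)
  labs <- as.integer(names(areas))
  if (!length(labs)) {
    return(data.frame(nucleus = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), dapi_sum = numeric(0),
                      n_nucleoli = integer(0), touches_edge = logical(0),
                      epithelial = logical(0), kept = logical(0),
                      reason = character(0)))
  }
  idx <- which(lab > 0L)
  sums <- tapply(dapi[idx], factor(lab[idx], levels = labs), sum)
  um2 <- px_to_area_um2(as.numeric(areas), pixel_size_um)
  counts <- integer(length(labs))
  m <- match(labs, as.integer(names(nucleolus_counts)))
  counts[!is.na(m)] <- as.integer(nucleolus_counts)[m[!is.na(m)]]
  edge <- labs %in% edge_labels(lab)
  epi <- if (is.null(epithelial)) rep(NA, length(labs)) else {
    e <- rep(FALSE, length(labs))
    me <- match(labs, as.integer(names(epithelial)))
    e[!is.na(me)] <- as.logical(epithelial)[me[!is.na(me)]]
    e
  }
  ok_area <- um2 < max_area_um2
  ok_dapi <- as.numeric(sums) > min_dapi_sum
  ok_nucleoli <- counts >= 1L
  ok_edge <- !edge
  ok_epi <- if (is.null(epithelial)) rep(TRUE, length(labs)) else epi
  kept <- ok_area & ok_dapi & ok_nucleoli & ok_edge & ok_epi
  reason <- rep(NA_character_, length(labs))
  reason[!ok_epi] <- "not_epithelial"
  reason[!ok_edge] <- "touches_edge"
  reason[!ok_nucleoli] <- "no_nucleolus"
  reason[!ok_dapi] <- "dapi_sum"
  reason[!ok_area] <- "area"
  data.frame(nucleus = labs, area_px = as.integer(areas), area_um2 = um2,
             dapi_sum = as.numeric(sums), n_nucleoli = counts,
             touches_edge = edge, epithelial = as.logical(epi), kept = kept,
             reason = reason, row.names = NULL)
}

#' Dilate labelled nucleoli with a square structuring element
#'
#' Morphological dilation by `pixels` with a `(2p+1) x (2p+1)` box,
#' performed label-wise: background pixels are claimed round by round, so
#' a contested pixel goes to the nearest original object (Chebyshev
#' distance), ties to the lower label. `pixels = 0` is the identity.
#'
#' @param nucleoli `label_mask` or integer label matrix.
#' @param pixels Dilation radius in pixels (default 1).
#' @return Dilated mask of the same class as the input.
#' @export
dilate_nucleoli <- function(nucleoli, pixels = 1L) {
  lab <- resolve_labels(nucleoli)
  p <- as.integer(pixels)
  if (p < 0) stop("pixels must be >= 0", call. = FALSE)
  for (round in seq_len(p)) {
    nbmin <- neighbour_min_label(lab)
    claim <- lab == 0L & nbmin > 0L
    lab[claim] <- nbmin[claim]
  }
  if (inherits(nucleoli, "label_mask")) {
    label_mask(lab, nucleoli$kind, nucleoli$pixel_size_um)
  } else lab
}

# minimum positive label among the 8 neighbours of each pixel (0 = none)
neighbour_min_label <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  big <- max(lab) + 1L
  acc <- matrix(big, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- shift_matrix(lab, dr, dc)
    sh[sh == 0L] <- big
    acc <- pmin(acc, sh)
  }
  acc[acc == big] <- 0L
  acc
}

shift_matrix <- function(m, dr, dc, fill = 0L) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(fill, n, k)
  rs <- seq_len(n) - dr; cs <- seq_len(k) - dc
  rok <- rs >= 1 & rs <= n; cok <- cs >= 1 & cs <= k
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Assign foci to nucleoli and apply the focus filters
#'
#' A focus is retained iff it lies inside a dilated nucleolus or at least
#' `overlap_fraction` of its pixels intersect one (reference rule: within
#' or intersecting with 10%), and its maximum marker intensity strictly
#' exceeds `max_intensity_threshold` (reference: > 400). Retained foci
#' are assigned to the nucleolus of maximal overlap (ties to the lower
#' label).
#'
#' @param foci `label_mask` or label matrix of candidate foci.
#' @param features Per-focus feature table from [detect_foci()] (or any
#'   data frame with columns `label`, `area_px`, `max_intensity`,
#'   `sum_intensity`).
#' @param dilated_nucleoli Dilated nucleolus mask ([dilate_nucleoli()]).
#' @param overlap_fraction Inclusive overlap fraction (default 0.10).
#' @param max_intensity_threshold Strict lower bound on the focus maximum
#'   marker intensity (default 400).
#' @return Data frame: `focus`, `nucleolus` (NA when unassigned),
#'   `overlap_fraction`, `area_px`, `max_intensity`, `sum_intensity`,
#'   `kept`.
#' @export
assign_and_filter_foci <- function(foci, features, dilated_nucleoli,
                                   overlap_fraction = 0.10,
                                   max_intensity_threshold = 400) {
  lab <- resolve_labels(foci)
  areas <- label_areas(lab)
  labs <- as.integer(names(areas))
  if (!length(labs)) {
    return(data.frame(focus = integer(0), nucleolus = integer(0),
                      overlap_fraction = numeric(0), area_px = integer(0),
                      max_intensity = numeric(0), sum_intensity = numeric(0),
                      kept = logical(0)))
  }
  out <- data.frame(focus = labs, nucleolus = NA_integer_,
                    overlap_fraction = 0)
  ov <- overlap_table(lab, dilated_nucleoli)
  if (nrow(ov)) {
    ov$frac <- ov$n / as.integer(areas[as.character(ov$child)])
    ov <- ov[order(ov$child, -ov$n, ov$parent), , drop = FALSE]
    best <- ov[!duplicated(ov$child), , drop = FALSE]
    m <- match(best$child, out$focus)
    out$nucleolus[m] <- best$parent
    out$overlap_fraction[m] <- best$frac
  }
  fm <- match(out$focus, features$label)
  out$area_px <- features$area_px[fm]
  out$max_intensity <- features$max_intensity[fm]
  out$sum_intensity <- features$sum_intensity[fm]
  nucleolar <- !is.na(out$nucleolus) & out$overlap_fraction >= overlap_fraction
  out$kept <- nucleolar & out$max_intensity > max_intensity_threshold
  out$nucleolus[!out$kept] <- NA_integer_
  out
}

#' Nucleoplasm mask: nuclei minus nucleoli
#'
#' Set difference labelled by nucleus: every nucleus pixel not covered by
#' a retained nucleolus. By default the undilated nucleolus pixels are
#' subtracted (dilation exists only to capture peripheral foci).
#'
#' @param nuclei,nucleoli `label_mask` objects or label matrices.
#' @return A `label_mask` of kind `nucleoplasm` (labels are nucleus
#'   labels) when `nuclei` is a `label_mask`, else an integer matrix.
#' @export
compute_nucleoplasm <- function(nuclei, nucleoli) {
  nl <- resolve_labels(nuclei); cl <- resolve_labels(nucleoli)
  out <- nl
  out[cl > 0L] <- 0L
  if (inherits(nuclei, "label_mask")) {
    label_mask(out, "nucleoplasm", nuclei$pixel_size_um)
  } else out
}

#' Score cells for nucleolar foci positivity
#'
#' Applies the foci-count window. With `scope = "nucleolus"` (default,
#' matching the manual reference rule) a nucleolus is stressed when its
#' retained focus count lies in `[min_foci, max_foci]` and a cell is
#' positive when at least one of its nucleoli is stressed. With
#' `scope = "nucleus"` the window is applied to the cell's pooled focus
#' count across nucleoli.
#'
#' @param nucleolus_foci Data frame with columns `nucleolus`, `nucleus`,
#'   `foci_count` (retained foci per nucleolus).
#' @param nuclei_labels Integer vector of retained nucleus labels.
#' @param min_foci,max_foci Inclusive count window (defaults 1 and 5).
#' @param scope `"nucleolus"` or `"nucleus"`.
#' @return Data frame: `nucleus`, `foci_count`, `n_stressed_nucleoli`,
#'   `foci_positive`.
#' @export
score_cells <- function(nucleolus_foci, nuclei_labels, min_foci = 1L,
                        max_foci = 5L, scope = c("nucleolus", "nucleus")) {
  scope <- match.arg(scope)
  nuclei_labels <- as.integer(nuclei_labels)
  if (!length(nuclei_labels)) {
    return(data.frame(nucleus = integer(0), foci_count = integer(0),
                      n_stressed_nucleoli = integer(0),
                      foci_positive = logical(0)))
  }
  out <- data.frame(nucleus = nuclei_labels, foci_count = 0L,
                    n_stressed_nucleoli = 0L, foci_positive = FALSE)
  if (nrow(nucleolus_foci)) {
    tot <- tapply(nucleolus_foci$foci_count, nucleolus_foci$nucleus, sum)
    m <- match(as.integer(names(tot)), out$nucleus)
    out$foci_count[m[!is.na(m)]] <- as.integer(tot)[!is.na(m)]
    stressed <- nucleolus_foci$foci_count >= min_foci &
      nucleolus_foci$foci_count <= max_foci
    ns <- tapply(stressed, nucleolus_foci$nucleus, sum)
    out$n_stressed_nucleoli[m[!is.na(m)]] <- as.integer(ns)[!is.na(m)]
  }
  out$foci_positive <- if (scope == "nucleolus") {
    out$n_stressed_nucleoli >= 1L
  } else {
    out$foci_count >= min_foci & out$foci_count <= max_foci
  }
  out
}
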