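#' Per-nucleus feature table
#'
#' One row per retained nucleus, with the compartment statistics of the
#' reference export: nucleolar marker intensities (mean and sum),
#' nucleolar area (mean over the cell's nucleoli, um^2), nucleolus count,
#' nucleoplasmic marker intensities (mean and sum), foci intensities
#' (mean and sum over retained-focus pixels; 0 when the cell has no
#' retained focus), nucleolar foci count, the foci-positive flag, the
#' epithelial flag (tissue mode) and the image name. Means are unweighted
#' pixel means; all statistics are measured on the original, unenhanced
#' channels.
#'
#' @param records A `cell_records` from [build_cell_records()].
#' @param image The `multiplex_image` the records came from.
#' @return Data frame with one row per retained nucleus (possibly zero
#'   rows, always with the full set of columns).
#' @export
extract_feature_table <- function(records, image) {
  stopifnot(inherits(records, "cell_records"))
  marker <- get_channel(image, "marker")
  tissue <- !is.null(records$masks$epithelium)

  kept <- records$cells[records$cells$kept, , drop = FALSE]
  empty <- data.frame(
    id = integer(0), nucleolar_intensity_mean = numeric(0),
    nucleolar_intensity_sum = numeric(0), nucleolar_area_mean = numeric(0),
    nucleolus_count = integer(0), nucleoplasm_intensity_mean = numeric(0),
    nucleoplasm_intensity_sum = numeric(0), foci_intensity_mean = numeric(0),
    foci_intensity_sum = numeric(0), nucleolar_foci_count = integer(0),
    foci_positive = logical(0), epithelial = logical(0), image = character(0))
  if (!tissue) empty$epithelial <- NULL
  if (!nrow(kept)) return(empty)

  ids <- kept$nucleus
  ncl <- records$nucleoli
  ncl_lab <- records$masks$nucleoli$labels
  npl_lab <- records$masks$nucleoplasm$labels
  foc_lab <- records$masks$foci$labels

  # nucleolus pixels grouped by parent nucleus
  ncl_parent <- matrix(0L, nrow(ncl_lab), ncol(ncl_lab))
  pos <- ncl_lab > 0L
  ncl_parent[pos] <- ncl$nucleus[match(ncl_lab[pos], ncl$label)]
  ncl_stats <- compartment_stats(ncl_parent, marker, ids)

  npl_stats <- compartment_stats(npl_lab, marker, ids)

  # retained focus pixels grouped by parent nucleus
  foc_parent <- matrix(0L, nrow(foc_lab), ncol(foc_lab))
  pos <- foc_lab > 0L
  foc_parent[pos] <- records$foci$nucleus[match(foc_lab[pos],
                                                records$foci$focus)]
  foc_stats <- compartment_stats(foc_parent, marker, ids, zero_if_empty = TRUE)

  area_mean <- vapply(ids, function(i) {
    a <- ncl$area_um2[ncl$nucleus == i]
    if (length(a)) mean(a) else NA_real_
  }, numeric(1))

  out <- data.frame(
    id = ids,
    nucleolar_intensity_mean = ncl_stats$mean,
    nucleolar_intensity_sum = ncl_stats$sum,
    nucleolar_area_mean = area_mean,
    nucleolus_count = kept$n_nucleoli,
    nucleoplasm_intensity_mean = npl_stats$mean,
    nucleoplasm_intensity_sum = npl_stats$sum,
    foci_intensity_mean = foc_stats$mean,
    foci_intensity_sum = foc_stats$sum,
    nucleolar_foci_count = kept$foci_count,
    foci_positive = kept$foci_positive,
    image = records$image_name,
    row.names = NULL)
  if (tissue) {
    out$epithelial <- kept$epithelial
    out <- out[, c(setdiff(names(out), c("epithelial", "image")),
                   "epithelial", "image")]
  }
  out
}

# pixel mean and sum of `intensity` over pixels labelled by nucleus id
compartment_stats <- function(parent_lab, intensity, ids,
                              zero_if_empty = FALSE) {
  idx <- which(parent_lab > 0L)
  fill <- if (zero_if_empty) 0 else NA_real_
  means <- rep(fill, length(ids)); sums <- rep(fill, length(ids))
  if (length(idx)) {
    f <- factor(parent_lab[idx], levels = ids)
    v <- intensity[idx]
    s <- tapply(v, f, sum); m <- tapply(v, f, mean)
    got <- !is.na(s)
    sums[got] <- s[got]; means[got] <- m[got]
    if (zero_if_empty) { sums[is.na(sums)] <- 0; means[is.na(means)] <- 0 }
  }
  list(mean = as.numeric(means), sum = as.numeric(sums))
}

#' Write a feature table to disk
#'
#' CSV (RFC 4180, UTF-8, "." decimal) is the canonical format and
#' round-trips losslessly through [read_feature_table()]. The `xlsx`
#' format of the reference export is not supported by this installation
#' and raises an informative error.
#'
#' @param table Feature table from [extract_feature_table()].
#' @param path Output path.
#' @param format `"csv"` (default) or `"xlsx"`.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("xlsx export is not supported by this installation; ",
         "write csv and convert externally", call. = FALSE)
  }
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
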