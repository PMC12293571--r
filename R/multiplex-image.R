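#' @importFrom stats rnorm rpois runif median setNames sd aggregate
#' @importFrom utils read.csv write.csv
NULL

# Channel roles understood by the pipeline. pan_ck is optional (cell-block
# mode has no epithelial marker); the other three are mandatory.
CHANNEL_ROLES <- c("dapi", "pan_ck", "rnapol2", "marker")
REQUIRED_ROLES <- c("dapi", "rnapol2", "marker")
MAX_INTENSITY <- 65535

#' Construct a multi-channel fluorescence image
#'
#' A `multiplex_image` bundles one 2-D intensity matrix per channel role
#' with the physical pixel size. Channels are stored in canonical role
#' order (dapi, pan_ck, rnapol2, marker); `pan_ck` may be absent
#' (cell-block mode). Intensities are non-negative integers on a 16-bit
#' detector scale (0-65535); the absolute intensity thresholds used by the
#' filtering rules (e.g. 500 for pan-cytokeratin, 400 for focus peaks)
#' refer to this raw scale.
#'
#' @param channels Named list of numeric matrices, names drawn from
#'   `dapi`, `pan_ck`, `rnapol2`, `marker`. All matrices must share the
#'   same dimensions.
#' @param pixel_size_um Isotropic pixel size in micrometres per pixel.
#' @param name Free-text image identifier (used in feature tables).
#' @return An object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, pixel_size_um, name = "image") {
  if (!is.list(channels) || is.null(names(channels))) {
    stop("channels must be a named list of matrices", call. = FALSE)
  }
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(REQUIRED_ROLES, names(channels))
  if (length(missing)) {
    stop("missing required channel role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  channels <- channels[intersect(CHANNEL_ROLES, names(channels))]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("every channel must be a matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share identical dimensions", call. = FALSE)
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  check_pixel_size(pixel_size_um)
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         name = as.character(name)[1]),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multiplex_image '%s'> %d x %d px, %.4g um/px, channels: %s\n",
              x$name, d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel from a multiplex image
#'
#' @param image A `multiplex_image`.
#' @param role Channel role (`dapi`, `pan_ck`, `rnapol2` or `marker`).
#' @return The intensity matrix for that role.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!role %in% names(image$channels)) {
    stop("channel role '", role, "' not present in image", call. = FALSE)
  }
  image$channels[[role]]
}

#' Does the image carry an epithelial (pan-cytokeratin) channel?
#' @param image A `multiplex_image`.
#' @return Logical.
#' @export
has_pan_ck <- function(image) {
  inherits(image, "multiplex_image") && "pan_ck" %in% names(image$channels)
}

#' Construct an integer label mask
#'
#' Labelled object raster: 0 is background, positive integers identify
#' connected objects. Labels need not be contiguous.
#'
#' @param labels Non-negative integer matrix.
#' @param kind One of `nuclei`, `nucleoli`, `foci`, `epithelium`,
#'   `nucleoplasm`.
#' @param pixel_size_um Isotropic pixel size in micrometres per pixel.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, kind, pixel_size_um) {
  kind <- match.arg(kind, c("nuclei", "nucleoli", "foci", "epithelium",
                            "nucleoplasm"))
  if (is.null(dim(labels))) stop("labels must be a matrix", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  check_pixel_size(pixel_size_um)
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  structure(list(labels = labels, kind = kind, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %s> %d x %d px, %d object(s)\n", x$kind,
              nrow(x$labels), ncol(x$labels), length(mask_labels(x))))
  invisible(x)
}

#' Labels present in a mask
#' @param mask A `label_mask` or integer matrix.
#' @return Sorted integer vector of positive labels.
#' @export
mask_labels <- function(mask) {
  m <- if (inherits(mask, "label_mask")) mask$labels else mask
  sort(unique(m[m > 0]))
}

resolve_labels <- function(mask) {
  if (inherits(mask, "label_mask")) mask$labels else mask
}

#' Read a multi-channel TIFF into a multiplex image
#'
#' Reads a single- or multi-page (OME-)TIFF and maps pages to channel
#' roles. Pixel size resolution order: explicit `pixel_size_um` argument,
#' then the TIFF x-resolution metadata (interpreted as pixels per
#' centimetre or inch according to the resolution unit), else an error.
#'
#' @param path Path to a readable TIFF file.
#' @param channel_map Named integer vector / list mapping roles to 1-based
#'   page indices, e.g. `c(dapi = 1, pan_ck = 2, rnapol2 = 3, marker = 4)`.
#'   Must cover `dapi`, `rnapol2` and `marker`; `pan_ck` is optional.
#' @param pixel_size_um Optional pixel-size override (micrometres/pixel).
#' @param name Image name; defaults to the file name without extension.
#' @return A `multiplex_image`.
#' @export
load_multiplex <- function(path, channel_map, pixel_size_um = NULL,
                           name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  channel_map <- unlist(channel_map)
  missing <- setdiff(REQUIRED_ROLES, names(channel_map))
  if (length(missing)) {
    stop("channel_map must cover role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(channel_map < 1 | channel_map > length(pages))) {
    stop("channel index out of range: file has ", length(pages), " page(s)",
         call. = FALSE)
  }
  channels <- lapply(channel_map, function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      stop("multi-sample (RGB) TIFF pages are not supported; ",
           "export single-sample grayscale channels", call. = FALSE)
    }
    matrix(as.numeric(pg), nrow(pg), ncol(pg))
  })
  if (is.null(pixel_size_um)) {
    pixel_size_um <- tiff_pixel_size(pages[[channel_map[[1]]]])
    if (is.null(pixel_size_um)) {
      stop("no pixel size: none supplied and no resolution metadata in ",
           path, call. = FALSE)
    }
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  multiplex_image(channels, pixel_size_um, name = name)
}

# x.resolution metadata -> um/px, honouring the resolution unit tag.
tiff_pixel_size <- function(page) {
  xres <- attr(page, "x.resolution")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- attr(page, "resolution.unit")
  um_per_unit <- switch(as.character(unit %||% "inch"),
                        inch = 25400, cm = 10000, 25400)
  um_per_unit / xres
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multiplex image as a multi-page 16-bit TIFF
#'
#' Pages are written in canonical role order. Integer intensities in
#' 0-65535 round-trip exactly through [load_multiplex()].
#'
#' @param image A `multiplex_image`.
#' @param path Output path.
#' @return Invisibly, the channel-role order written (role -> page index).
#' @export
write_multiplex <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  pages <- lapply(image$channels, function(m) {
    if (any(m > MAX_INTENSITY)) {
      stop("intensities exceed 16-bit range", call. = FALSE)
    }
    round(m) / MAX_INTENSITY
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  invisible(setNames(seq_along(pages), names(pages)))
}

#' Write a label mask as a 16-bit integer TIFF
#' @param mask A `label_mask`.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > MAX_INTENSITY) {
    stop("more than 65535 labels cannot be stored in a 16-bit TIFF",
         call. = FALSE)
  }
  tiff::writeTIFF(mask$labels / MAX_INTENSITY, path, bits.per.sample = 16L,
                  compression = "LZW", reduce = FALSE)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#' @param path TIFF path.
#' @inheritParams label_mask
#' @return A `label_mask`.
#' @export
read_mask <- function(path, kind, pixel_size_um) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_mask(matrix(as.integer(m), nrow(m), ncol(m)), kind, pixel_size_um)
}
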