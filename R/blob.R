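#' Blob detection parameters
#'
#' @param diameter_um Expected blob diameter in micrometres (> 0).
#' @param probability_threshold_pct Seed threshold as a percentage of the
#'   global response maximum (0-100).
#' @param split_sensitivity_pct Split criterion: two adjacent response
#'   basins remain separate blobs when the saddle-to-peak ratio falls
#'   below this percentage, and are merged otherwise (0-100). Higher
#'   values split more readily.
#' @return A `blob_params` list.
#' @export
blob_params <- function(diameter_um, probability_threshold_pct,
                        split_sensitivity_pct) {
  if (diameter_um <= 0) stop("diameter_um must be > 0", call. = FALSE)
  pct <- c(probability_threshold_pct, split_sensitivity_pct)
  if (any(pct < 0 | pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  structure(list(diameter_um = diameter_um,
                 probability_threshold_pct = probability_threshold_pct,
                 split_sensitivity_pct = split_sensitivity_pct),
            class = "blob_params")
}

# Core blob finder over a non-negative response map.
#
# 1. Catchment basins of the response (watershed on the positive support).
# 2. Adjacent basins are merged when the saddle response between them is
#    at least split_sensitivity% of the lower of the two basin peaks
#    (shallow saddle = one blob); processed in decreasing saddle order
#    with union-find, so merging is order-independent.
# 3. Merged basins whose peak response reaches probability_threshold% of
#    the global response maximum -- and a fixed contrast floor
#    min_contrast, which makes detection well-defined on signal-free
#    images where the global maximum is itself noise -- become blobs.
#
# Returns an integer label matrix (labels 1..n in raster order of the
# blob peaks; deterministic for a fixed input).
blob_finder <- function(response, diameter_px, probability_threshold_pct,
                        split_sensitivity_pct, min_contrast = 100,
                        footprint_fraction = 0.3) {
  dims <- dim(response)
  out <- matrix(0L, dims[1], dims[2])
  mx <- max(response)
  thr <- max(mx * probability_threshold_pct / 100, min_contrast)
  if (mx <= 0 || mx < min_contrast) return(out)
  support <- response > 0
  if (!any(support)) return(out)
  ext <- max(1L, as.integer(round(diameter_px / 4)))
  basins <- EBImage::imageData(EBImage::watershed(response * support,
                                                  tolerance = 0, ext = ext))
  storage.mode(basins) <- "integer"
  nb <- max(basins)
  if (nb == 0L) return(out)

  peaks <- rep(0, nb)
  pk <- tapply(response[basins > 0], basins[basins > 0], max)
  peaks[as.integer(names(pk))] <- pk

  merged <- merge_basins(basins, response, peaks, split_sensitivity_pct / 100)
  basins[] <- merged$map[basins + 1L]
  peaks <- merged$peaks

  keep <- which(peaks >= thr & peaks > 0)
  if (!length(keep)) return(out)
  relabel <- rep(0L, length(peaks))
  relabel[keep] <- seq_along(keep)
  pos <- basins > 0L
  out[pos] <- relabel[basins[pos]]
  # blob footprint: basin pixels above footprint_fraction of the basin
  # peak (calibrated so a top-hat disk at the matched scale keeps
  # approximately its true extent); the rest of the catchment basin is
  # background
  cut <- out > 0L & response < footprint_fraction * peaks[pmax(basins, 1L)]
  out[cut] <- 0L
  storage.mode(out) <- "integer"
  out
}

# Saddle-driven basin merging. Returns map (0-based lookup: map[label+1])
# from original basin label to merged representative, plus merged peaks.
merge_basins <- function(basins, response, peaks, split_ratio) {
  nb <- length(peaks)
  pairs <- basin_adjacency(basins, response)
  parent <- seq_len(nb)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    ord <- order(-pairs$saddle)
    for (k in ord) {
      a <- find(pairs$a[k]); b <- find(pairs$b[k])
      if (a == b) next
      lo <- min(peaks[a], peaks[b])
      if (lo <= 0) next
      if (pairs$saddle[k] / lo >= split_ratio) {
        root <- min(a, b); other <- max(a, b)
        parent[other] <- root
        peaks[root] <- max(peaks[a], peaks[b])
      }
    }
  }
  map <- c(0L, vapply(seq_len(nb), find, integer(1)))
  list(map = map, peaks = peaks)
}

# Saddle response between every 4-adjacent basin pair: the maximum over
# shared-boundary pixel pairs of the lower of the two responses.
basin_adjacency <- function(basins, response) {
  collect <- function(l1, l2, r1, r2) {
    sel <- l1 > 0L & l2 > 0L & l1 != l2
    if (!any(sel)) return(NULL)
    a <- pmin(l1[sel], l2[sel]); b <- pmax(l1[sel], l2[sel])
    data.frame(a = a, b = b, saddle = pmin(r1[sel], r2[sel]))
  }
  n <- nrow(basins); m <- ncol(basins)
  vert <- collect(basins[-n, , drop = FALSE], basins[-1, , drop = FALSE],
                  response[-n, , drop = FALSE], response[-1, , drop = FALSE])
  horz <- collect(basins[, -m, drop = FALSE], basins[, -1, drop = FALSE],
                  response[, -m, drop = FALSE], response[, -1, drop = FALSE])
  all <- rbind(vert, horz)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(a = integer(0), b = integer(0), saddle = numeric(0)))
  }
  key <- paste(all$a, all$b)
  sad <- tapply(all$saddle, key, max)
  ab <- do.call(rbind, strsplit(names(sad), " ", fixed = TRUE))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             saddle = as.numeric(sad))
}
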