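#' Parameters of the synthetic tissue-image generator
#'
#' Defaults emulate the high-throughput acquisition conditions: 0.173
#' um/px, densely packed ~10 um nuclei, 1-3 nucleoli of ~3 um per
#' nucleus, and -- in the stressed fraction of cells -- 1-5 marker foci of
#' 0.7 um per nucleolus. Intensity levels place the absolute filter
#' thresholds (pan-CK 500, focus 400, DAPI sum 50,000) in a realistic
#' 16-bit operating range: background 100, DAPI nucleus 1200,
#' nucleoplasmic RNA Pol II 2000 (background level inside nucleolar
#' holes), nucleolar marker 1500 over a nucleoplasmic marker level of
#' 250, focus peaks +3000, pan-CK cytoplasm 1500. Noise is
#' Poisson shot noise plus Gaussian read noise (sd 20).
#'
#' @param ... Named overrides of any default.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(...) {
  p <- list(
    width_px = 1024L, height_px = 1024L, pixel_size_um = 0.173,
    n_nuclei = 200L,
    nucleus_diameter_um_mean = 10, nucleus_diameter_um_sd = 0.8,
    nucleus_axis_ratio_range = c(0.85, 1),
    nucleoli_per_nucleus = c(1L, 3L),
    nucleolus_diameter_um_mean = 3, nucleolus_diameter_um_sd = 0.4,
    fraction_epithelial = 0.7,
    fraction_stressed = 0.3,
    foci_per_nucleolus = c(1L, 5L),
    focus_diameter_um = 0.7,
    levels = list(background = 100, dapi_nucleus = 1200,
                  rnapol2_nucleoplasm = 2000, marker_nucleolus = 1500,
                  marker_nucleoplasm = 250, focus_peak = 3000,
                  pan_ck_cytoplasm = 1500),
    autofluorescence_amplitude = 50,
    noise = list(poisson = TRUE, gaussian_sd = 20),
    scene_blur_sigma_px = 1,
    min_spacing_factor = 0.8,
    render_foci = TRUE,
    tissue_mode = TRUE,
    seed = 1L
  )
  for (nm in names(list(...))) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm, call. = FALSE)
    if (is.list(p[[nm]]) && is.list(list(...)[[nm]])) {
      p[[nm]][names(list(...)[[nm]])] <- list(...)[[nm]]
    } else p[[nm]] <- list(...)[[nm]]
  }
  stopifnot(p$fraction_epithelial >= 0, p$fraction_epithelial <= 1,
            p$fraction_stressed >= 0, p$fraction_stressed <= 1,
            p$nucleus_diameter_um_mean > 0, p$nucleolus_diameter_um_mean > 0,
            p$focus_diameter_um > 0,
            all(unlist(p$levels) >= 0), all(unlist(p$levels) <= 65535))
  structure(p, class = "simulation_params")
}

#' Simulate a multi-channel tissue image with complete ground truth
#'
#' Forward model: non-overlapping ellipsoidal nuclei placed by rejection
#' sampling with a minimum centroid spacing of
#' `min_spacing_factor x diameter`; 1-3 nucleolar holes per nucleus; the
#' DAPI channel carries the nuclei, the RNA Pol II channel carries
#' nucleoplasmic signal with nucleolar holes at background level, the
#' marker channel carries nucleolar signal plus -- in stressed cells --
#' Gaussian foci at the nucleolar interior and periphery, and the pan-CK
#' channel carries cytoplasmic annuli around the epithelial fraction of
#' nuclei (tissue mode). A smooth autofluorescent field is added, the
#' scene is blurred by a 1 px optical PSF, and Poisson + Gaussian noise
#' is applied before clipping to the 16-bit range.
#'
#' Deterministic for a fixed seed: the same seed reproduces images and
#' ground truth bit-exactly.
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed overriding `params$seed`.
#' @return List with `image` (a `multiplex_image`) and `truth` (a
#'   `ground_truth`: nuclei / nucleoli / foci masks, per-cell table with
#'   epithelial and stressed flags and true foci counts, per-nucleolus
#'   table, the parameter record and seed).
#' @export
simulate_tissue <- function(params = simulation_params(), seed = params$seed) {
  set.seed(as.integer(seed))
  H <- params$height_px; W <- params$width_px
  px <- params$pixel_size_um
  lv <- params$levels

  d_px <- length_um_to_px(params$nucleus_diameter_um_mean, px)
  centers <- pack_centers(params$n_nuclei, H, W,
                          spacing = params$min_spacing_factor * d_px,
                          margin = 0.30 * d_px)

  nuclei <- matrix(0L, H, W)
  nucleoli <- matrix(0L, H, W)
  foci <- matrix(0L, H, W)
  marker_extra <- matrix(0, H, W)

  n <- nrow(centers)
  cells <- data.frame(cell = seq_len(n), row = centers[, 1],
                      col = centers[, 2],
                      epithelial = runif(n) < params$fraction_epithelial,
                      stressed = runif(n) < params$fraction_stressed,
                      true_foci_count = integer(n))
  nucleoli_df <- NULL
  focus_sigma <- length_um_to_px(params$focus_diameter_um, px) / 2.355
  ncl_label <- 0L; foc_label <- 0L

  for (i in seq_len(n)) {
    dia <- max(rnorm(1, d_px, length_um_to_px(params$nucleus_diameter_um_sd, px)),
               0.5 * d_px)
    ratio <- runif(1, params$nucleus_axis_ratio_range[1],
                   params$nucleus_axis_ratio_range[2])
    theta <- runif(1, 0, pi)
    a <- dia / 2; b <- a * ratio
    ell <- rasterize_ellipse(H, W, centers[i, 1], centers[i, 2], a, b, theta)
    nuclei[ell] <- i

    k <- sample(seq(params$nucleoli_per_nucleus[1],
                    params$nucleoli_per_nucleus[2]), 1)
    for (j in seq_len(k)) {
      nd <- max(rnorm(1, length_um_to_px(params$nucleolus_diameter_um_mean, px),
                      length_um_to_px(params$nucleolus_diameter_um_sd, px)),
                length_um_to_px(1.5, px))
      r_ncl <- nd / 2
      pos <- place_inside_ellipse(centers[i, ], a, b, theta, r_ncl,
                                  avoid = nucleoli, H = H, W = W)
      if (is.null(pos)) next
      ncl_label <- ncl_label + 1L
      disk <- rasterize_ellipse(H, W, pos[1], pos[2], r_ncl, r_ncl, 0)
      nucleoli[disk] <- ncl_label
      nf <- 0L
      if (cells$stressed[i] && params$render_foci) {
        nf <- sample(seq(params$foci_per_nucleolus[1],
                         params$foci_per_nucleolus[2]), 1)
        placed <- place_foci(pos, r_ncl, nf,
                             min_sep = 2 * focus_sigma * 2.355, H = H, W = W)
        for (fp in seq_len(nrow(placed))) {
          foc_label <- foc_label + 1L
          spot <- rasterize_ellipse(H, W, placed[fp, 1], placed[fp, 2],
                                    focus_sigma * 1.18, focus_sigma * 1.18, 0)
          foci[spot] <- foc_label
          marker_extra <- add_gaussian_spot(marker_extra, placed[fp, 1],
                                            placed[fp, 2], focus_sigma,
                                            lv$focus_peak)
        }
        nf <- nrow(placed)
      }
      nucleoli_df <- rbind(nucleoli_df,
                           data.frame(label = ncl_label, cell = i,
                                      true_foci_count = nf))
    }
  }
  if (is.null(nucleoli_df)) {
    nucleoli_df <- data.frame(label = integer(0), cell = integer(0),
                              true_foci_count = integer(0))
  }
  if (nrow(nucleoli_df)) {
    tot <- tapply(nucleoli_df$true_foci_count, nucleoli_df$cell, sum)
    m <- match(as.integer(names(tot)), cells$cell)
    cells$true_foci_count[m] <- as.integer(tot)
  }
  cells$stressed <- cells$stressed & cells$true_foci_count > 0L

  # channel scenes ------------------------------------------------------
  in_nucleus <- nuclei > 0L
  in_nucleolus <- nucleoli > 0L
  dapi <- matrix(lv$background, H, W)
  dapi[in_nucleus] <- lv$dapi_nucleus
  rnapol2 <- matrix(lv$background, H, W)
  rnapol2[in_nucleus] <- lv$rnapol2_nucleoplasm
  rnapol2[in_nucleus & in_nucleolus] <- lv$background
  marker <- matrix(lv$background, H, W)
  marker[in_nucleus] <- lv$marker_nucleoplasm
  marker[in_nucleolus] <- lv$marker_nucleolus
  marker <- marker + marker_extra

  channels <- list(dapi = dapi, rnapol2 = rnapol2, marker = marker)
  if (params$tissue_mode) {
    pan_ck <- matrix(lv$background, H, W)
    pan_ck[cytoplasm_mask(nuclei, cells$epithelial)] <- lv$pan_ck_cytoplasm
    channels <- list(dapi = dapi, pan_ck = pan_ck, rnapol2 = rnapol2,
                     marker = marker)
  }

  af <- autofluorescence_field(H, W, params$autofluorescence_amplitude)
  channels <- lapply(channels, function(ch) {
    ch <- ch + af
    if (params$scene_blur_sigma_px > 0) {
      ch <- fft_convolve(ch, kernel_fft(
        gaussian_kernel(params$scene_blur_sigma_px), dim(ch)))
    }
    ch <- pmax(ch, 0)
    if (params$noise$poisson) {
      ch <- matrix(rpois(length(ch), lambda = ch), H, W)
    }
    if (params$noise$gaussian_sd > 0) {
      ch <- ch + matrix(rnorm(length(ch), 0, params$noise$gaussian_sd), H, W)
    }
    matrix(pmin(pmax(round(ch), 0), 65535), H, W)
  })

  image <- multiplex_image(channels, px,
                           name = sprintf("synthetic_seed%d", as.integer(seed)))
  truth <- structure(list(
    nuclei = label_mask(nuclei, "nuclei", px),
    nucleoli = label_mask(nucleoli, "nucleoli", px),
    foci = label_mask(foci, "foci", px),
    cells = cells, nucleoli_table = nucleoli_df,
    params = params, seed = as.integer(seed)), class = "ground_truth")
  list(image = image, truth = truth)
}

# rejection-sampled centres with minimum pairwise spacing; errors out
# when the requested count cannot be packed
pack_centers <- function(n, H, W, spacing, margin) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  centers <- matrix(0, n, 2)
  placed <- 0L
  tries <- 0L; max_tries <- 400L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("infeasible packing: could not place ", n, " nuclei of spacing ",
           round(spacing), " px in ", H, " x ", W, " px", call. = FALSE)
    }
    cand <- c(runif(1, 1 + margin, H - margin), runif(1, 1 + margin, W - margin))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < spacing^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# linear indices of an ellipse footprint, clipped at the image border
rasterize_ellipse <- function(H, W, cr, cc, a, b, theta) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(W, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  rr <- rows[(idx - 1L) %% length(rows) + 1L]
  cc2 <- cols[(idx - 1L) %/% length(rows) + 1L]
  (cc2 - 1L) * H + rr
}

# sample a nucleolus centre inside the nucleus ellipse (with clearance
# r_ncl from the boundary), avoiding pixels already claimed by another
# nucleolus; NULL when no position is found
place_inside_ellipse <- function(center, a, b, theta, r_ncl, avoid, H, W,
                                 tries = 25L) {
  ae <- a - r_ncl - 1; be <- b - r_ncl - 1
  if (ae <= 0 || be <= 0) return(NULL)
  for (t in seq_len(tries)) {
    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
    u <- ae * rad * cos(ang); v <- be * rad * sin(ang)
    pr <- center[1] + u * cos(theta) - v * sin(theta)
    pc <- center[2] + u * sin(theta) + v * cos(theta)
    ri <- round(pr); ci <- round(pc)
    if (ri < 1 || ri > H || ci < 1 || ci > W) next
    if (avoid[ri, ci] == 0L) {
      disk <- rasterize_ellipse(H, W, pr, pc, r_ncl, r_ncl, 0)
      if (!any(avoid[disk] > 0L)) return(c(pr, pc))
    }
  }
  NULL
}

# focus centres in the nucleolar interior/periphery with a preferred
# minimum separation (relaxed when the nucleolus is too small)
place_foci <- function(center, r_ncl, k, min_sep, H, W) {
  pts <- matrix(numeric(0), 0, 2)
  for (t in seq_len(60L * k)) {
    if (nrow(pts) >= k) break
    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * max(r_ncl - 2, 0.5)
    cand <- c(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
    if (cand[1] < 2 || cand[1] > H - 1 || cand[2] < 2 || cand[2] > W - 1) next
    if (nrow(pts) > 0L) {
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
      if (min(d2) < (min_sep * (if (t > 40L * k) 0.5 else 1))^2) next
    }
    pts <- rbind(pts, cand)
  }
  pts
}

add_gaussian_spot <- function(img, cr, cc, sigma, amplitude) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(4 * sigma)
  r0 <- max(1L, floor(cr - r)); r1 <- min(H, ceiling(cr + r))
  c0 <- max(1L, floor(cc - r)); c1 <- min(W, ceiling(cc + r))
  rows <- r0:r1; cols <- c0:c1
  g <- amplitude * exp(-(outer((rows - cr)^2, rep(1, length(cols))) +
                           outer(rep(1, length(rows)), (cols - cc)^2)) /
                         (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

# cytoplasmic annuli around epithelial nuclei. Each cell's cytoplasm is
# its grown footprint minus its OWN nucleus; in a 2-D projection the
# cytoplasm of one cell may overlie a neighbouring nucleus, which keeps
# the annuli closed in dense tissue (so the hole-filling step of the
# pipeline can reconstruct solid epithelial regions).
cytoplasm_mask <- function(nuclei, epithelial) {
  epi_labels <- which(epithelial)
  if (!length(epi_labels)) return(matrix(FALSE, nrow(nuclei), ncol(nuclei)))
  epi <- matrix(0L, nrow(nuclei), ncol(nuclei))
  epi[nuclei %in% epi_labels] <- nuclei[nuclei %in% epi_labels]
  grown <- epi
  for (i in 1:6) {   # ~1 um of cytoplasm at 0.173 um/px
    nb <- neighbour_min_label(grown)
    claim <- grown == 0L & nb > 0L
    grown[claim] <- nb[claim]
  }
  grown > 0L & !(nuclei > 0L & grown == nuclei)
}

# smooth additive autofluorescence: coarse uniform grid, bilinear upsample
autofluorescence_field <- function(H, W, amplitude) {
  if (amplitude <= 0) return(matrix(0, H, W))
  gh <- 8L; gw <- 8L
  g <- matrix(runif(gh * gw, 0, amplitude), gh, gw)
  ri <- seq(1, gh, length.out = H); ci <- seq(1, gw, length.out = W)
  r0 <- pmin(floor(ri), gh - 1L); c0 <- pmin(floor(ci), gw - 1L)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0, W), rep(c0, each = H))]
  b <- g[cbind(rep(r0 + 1, W), rep(c0, each = H))]
  cc <- g[cbind(rep(r0, W), rep(c0 + 1, each = H))]
  d <- g[cbind(rep(r0 + 1, W), rep(c0 + 1, each = H))]
  fr_m <- rep(fr, W); fc_m <- rep(fc, each = H)
  out <- a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
    cc * (1 - fr_m) * fc_m + d * fr_m * fc_m
  matrix(out, H, W)
}

#' Reference scoring directly from ground truth
#'
#' Pure bookkeeping, no image processing: the per-cell foci-positive
#' reference flag equals the simulator's stressed flag (a cell with at
#' least one nucleolus whose true focus count lies in the rendered 1-5
#' window), and the positive percentage is taken over epithelial cells in
#' tissue mode (all cells otherwise). An empty denominator yields an
#' `NA` percentage with `undefined = TRUE`.
#'
#' @param truth A `ground_truth` from [simulate_tissue()].
#' @param restrict_epithelial Use only epithelial cells as denominator
#'   (default: the simulation's tissue mode).
#' @return List: `flags` (named logical per cell), `percent_positive`,
#'   `n`, `undefined`.
#' @export
ground_truth_scoring <- function(truth,
                                 restrict_epithelial = truth$params$tissue_mode) {
  stopifnot(inherits(truth, "ground_truth"))
  cells <- truth$cells
  denom <- if (restrict_epithelial) cells[cells$epithelial, , drop = FALSE] else cells
  flags <- setNames(cells$stressed, cells$cell)
  if (!nrow(denom)) {
    return(list(flags = flags, percent_positive = NA_real_, n = 0L,
                undefined = TRUE))
  }
  list(flags = flags,
       percent_positive = 100 * sum(denom$stressed) / nrow(denom),
       n = nrow(denom), undefined = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth seed %d> %d cells (%d epithelial, %d stressed), %d nucleoli, %d foci\n",
              x$seed, nrow(x$cells), sum(x$cells$epithelial),
              sum(x$cells$stressed), nrow(x$nucleoli_table),
              length(mask_labels(x$foci))))
  invisible(x)
}
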