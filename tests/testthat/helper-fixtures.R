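# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures on disk.

PX <- 0.173  # um/px of the reference high-throughput configuration

# paint a filled circle into a matrix (value or label)
paint_disk <- function(m, cr, cc, r_px, value) {
  H <- nrow(m); W <- ncol(m)
  for (i in max(1, floor(cr - r_px)):min(H, ceiling(cr + r_px))) {
    for (j in max(1, floor(cc - r_px)):min(W, ceiling(cc + r_px))) {
      if ((i - cr)^2 + (j - cc)^2 <= r_px^2) m[i, j] <- value
    }
  }
  m
}

# additive Gaussian spot of given FWHM (um)
paint_spot <- function(m, cr, cc, fwhm_um, peak, pixel_size_um = PX) {
  s <- fwhm_um / pixel_size_um / 2.355
  r <- ceiling(4 * s)
  H <- nrow(m); W <- ncol(m)
  for (i in max(1, cr - r):min(H, cr + r)) {
    for (j in max(1, cc - r):min(W, cc + r)) {
      m[i, j] <- m[i, j] + peak * exp(-((i - cr)^2 + (j - cc)^2) / (2 * s^2))
    }
  }
  m
}

# rectangular block of labelled pixels
paint_rect <- function(m, r0, r1, c0, c1, value) {
  m[r0:r1, c0:c1] <- value
  m
}

# Random mask-level fixture for the filter-ledger tests: nuclei,
# nucleoli, foci and epithelium label masks plus DAPI and marker
# intensity images on a 256 x 256 raster. Object geometry and
# intensities are randomised so the filter boundaries are exercised from
# both sides.
random_compartment_fixture <- function(seed, size = 256L) {
  set.seed(seed)
  H <- size
  nuclei <- matrix(0L, H, H)
  nucleoli <- matrix(0L, H, H)
  foci <- matrix(0L, H, H)
  epith <- matrix(0L, H, H)
  dapi <- matrix(runif(H * H, 50, 150), H, H)
  marker <- matrix(runif(H * H, 100, 300), H, H)

  n_nuc <- sample(4:8, 1)
  ncl_id <- 0L; foc_id <- 0L
  for (i in seq_len(n_nuc)) {
    cr <- runif(1, 5, H - 5); cc <- runif(1, 5, H - 5)
    r <- runif(1, 12, 40)          # some nuclei pass 400 um2, some fail
    nuclei <- paint_disk(nuclei, cr, cc, r, i)
    dapi <- paint_disk(dapi, cr, cc, r, runif(1, 100, 1500))
    # 0-3 nucleoli, sometimes straddling the nucleus boundary
    for (k in seq_len(sample(0:3, 1))) {
      ncl_id <- ncl_id + 1L
      off <- runif(1, 0, r * 1.1)
      ang <- runif(1, 0, 2 * pi)
      rn <- runif(1, 4, 14)        # around the 3 um2 (~10 px radius) line
      nucleoli <- paint_disk(nucleoli, cr + off * cos(ang),
                             cc + off * sin(ang), rn, ncl_id)
      # 0-7 foci near the nucleolus (tests the 1-5 window from both ends)
      for (f in seq_len(sample(0:7, 1))) {
        foc_id <- foc_id + 1L
        fr <- cr + off * cos(ang) + runif(1, -rn - 3, rn + 3)
        fc <- cc + off * sin(ang) + runif(1, -rn - 3, rn + 3)
        foci <- paint_disk(foci, fr, fc, runif(1, 1.2, 2.5), foc_id)
        marker <- paint_disk(marker, fr, fc, 2.5, runif(1, 200, 1200))
      }
    }
  }
  # a few epithelial blocks
  for (e in seq_len(sample(1:3, 1))) {
    r0 <- sample(1:(H - 60), 1); c0 <- sample(1:(H - 60), 1)
    epith <- paint_rect(epith, r0, r0 + sample(30:59, 1),
                        c0, c0 + sample(30:59, 1), e)
  }
  image <- multiplex_image(list(dapi = dapi, rnapol2 = marker,
                                marker = marker), PX, name = paste0("fx", seed))
  list(nuclei = nuclei, nucleoli = nucleoli, foci = foci, epithelium = epith,
       image = image)
}

# small simulation parameters for quick end-to-end tests
small_sim_params <- function(...) {
  simulation_params(width_px = 384L, height_px = 384L, n_nuclei = 25L, ...)
}
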