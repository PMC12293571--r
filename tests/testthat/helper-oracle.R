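# Independent brute-force reimplementation of the complete filter ledger
# over raw label masks. Deliberately written with naive per-object pixel
# loops (which/intersect set arithmetic) rather than the package's
# vectorised tabulations, so it can serve as an oracle for the
# retained-object sets and foci-positive flags.

oracle_pixels <- function(lab, l) which(lab == l)

oracle_records <- function(nuclei, nucleoli, foci, epithelium, image, cfg) {
  px <- cfg$pixel_size_um
  dapi <- get_channel(image, "dapi")
  marker <- get_channel(image, "marker")
  H <- nrow(nuclei); W <- ncol(nuclei)

  # 1. nucleolus size filter: area strictly > 3 um2
  ncl_labels <- sort(unique(nucleoli[nucleoli > 0]))
  ncl_kept_size <- c()
  for (l in ncl_labels) {
    if (length(oracle_pixels(nucleoli, l)) * px^2 > cfg$nucleolus_min_area_um2) {
      ncl_kept_size <- c(ncl_kept_size, l)
    }
  }

  # 2. containment assignment: inside, or >= 95% in one nucleus;
  #    tie by larger overlap then lower nucleus label
  nuc_labels <- sort(unique(nuclei[nuclei > 0]))
  parent <- c()
  for (l in ncl_kept_size) {
    pix <- oracle_pixels(nucleoli, l)
    best_n <- NA; best_ov <- -1
    for (n in nuc_labels) {
      ov <- length(intersect(pix, oracle_pixels(nuclei, n)))
      if (ov > best_ov) { best_ov <- ov; best_n <- n }
    }
    ok <- best_ov == length(pix) ||
      best_ov / length(pix) >= cfg$nucleolus_containment_fraction
    parent[as.character(l)] <- if (ok && best_ov > 0) best_n else NA
  }
  ncl_assigned <- ncl_kept_size[!is.na(parent[as.character(ncl_kept_size)])]

  # 3. epithelial flags: >= 50% of nucleus pixels in ONE region
  tissue <- identical(cfg$mode, "tissue") && !is.null(epithelium)
  epi <- setNames(rep(TRUE, length(nuc_labels)), nuc_labels)
  if (tissue) {
    for (n in nuc_labels) {
      pix <- oracle_pixels(nuclei, n)
      best <- 0
      for (e in sort(unique(epithelium[epithelium > 0]))) {
        best <- max(best, length(intersect(pix, oracle_pixels(epithelium, e))))
      }
      epi[as.character(n)] <- best / length(pix) >= cfg$epithelial_fraction
    }
  }

  # 4. nucleus filters
  nuc_kept <- c()
  for (n in nuc_labels) {
    pix <- oracle_pixels(nuclei, n)
    rows <- (pix - 1) %% H + 1; cols <- (pix - 1) %/% H + 1
    on_edge <- any(rows == 1 | rows == H | cols == 1 | cols == W)
    n_ncl <- sum(parent[as.character(ncl_assigned)] == n, na.rm = TRUE)
    if (length(pix) * px^2 < cfg$nucleus_max_area_um2 &&
        sum(dapi[pix]) > cfg$nucleus_min_dapi_sum &&
        n_ncl >= 1 && !on_edge && epi[as.character(n)]) {
      nuc_kept <- c(nuc_kept, n)
    }
  }
  ncl_final <- ncl_assigned[parent[as.character(ncl_assigned)] %in% nuc_kept]

  # 5. 1-px box dilation with nearest-object collision rule
  dil <- matrix(0L, H, W)
  for (l in ncl_final) dil[oracle_pixels(nucleoli, l)] <- l
  base <- dil
  for (idx in which(base == 0)) {
    r <- (idx - 1) %% H + 1; cc <- (idx - 1) %/% H + 1
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= H && ccc >= 1 && ccc <= W && base[rr, ccc] > 0) {
        nb <- c(nb, base[rr, ccc])
      }
    }
    if (length(nb)) dil[idx] <- min(nb)
  }

  # 6. focus filters: overlap >= 10% with the best dilated nucleolus
  #    (ties lower label) and max marker intensity strictly > 400
  foc_labels <- sort(unique(foci[foci > 0]))
  foc_parent <- c(); foc_kept <- c()
  for (f in foc_labels) {
    pix <- oracle_pixels(foci, f)
    best_l <- NA; best_ov <- 0
    for (l in ncl_final) {
      ov <- length(intersect(pix, which(dil == l)))
      if (ov > best_ov) { best_ov <- ov; best_l <- l }
    }
    keep <- best_ov / length(pix) >= cfg$focus_overlap_fraction &&
      max(marker[pix]) > cfg$focus_max_intensity_min
    if (!is.na(best_l) && keep) {
      foc_parent[as.character(f)] <- best_l
      foc_kept <- c(foc_kept, f)
    }
  }

  # 7. per-nucleolus count window, cell positive if any nucleolus passes
  positive <- setNames(rep(FALSE, length(nuc_kept)), nuc_kept)
  for (n in nuc_kept) {
    for (l in ncl_final[parent[as.character(ncl_final)] == n]) {
      cnt <- sum(foc_parent[as.character(foc_kept)] == l)
      if (cnt >= cfg$foci_count_min && cnt <= cfg$foci_count_max) {
        positive[as.character(n)] <- TRUE
      }
    }
  }

  list(nuclei_kept = as.integer(sort(nuc_kept)),
       nucleoli_kept = as.integer(sort(ncl_final)),
       foci_kept = as.integer(sort(foc_kept)), positive = positive)
}
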