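#' Match automated cells to reference cells by mask overlap
#'
#' One-to-one greedy matching by decreasing pixel overlap between
#' reference (ground-truth) nuclei and automated nuclei. For external
#' annotations without masks, construct the matching table directly
#' (e.g. by centroid proximity) and pass it to [per_cell_agreement()].
#'
#' @param auto Automated nuclei `label_mask` (retained nuclei).
#' @param reference Reference nuclei `label_mask`.
#' @return Data frame: `reference`, `auto`, `overlap_px`.
#' @export
match_cells <- function(auto, reference) {
  ov <- overlap_table(resolve_labels(reference), resolve_labels(auto))
  if (!nrow(ov)) {
    return(data.frame(reference = integer(0), auto = integer(0),
                      overlap_px = integer(0)))
  }
  ov <- ov[order(-ov$n, ov$child, ov$parent), , drop = FALSE]
  used_ref <- integer(0); used_auto <- integer(0)
  keep <- logical(nrow(ov))
  for (k in seq_len(nrow(ov))) {
    if (ov$child[k] %in% used_ref || ov$parent[k] %in% used_auto) next
    keep[k] <- TRUE
    used_ref <- c(used_ref, ov$child[k])
    used_auto <- c(used_auto, ov$parent[k])
  }
  ov <- ov[keep, , drop = FALSE]
  data.frame(reference = ov$child, auto = ov$parent, overlap_px = ov$n,
             row.names = NULL)
}

#' Per-cell agreement between automated and reference scoring
#'
#' Classifies every matched cell as `both_positive` (found by both
#' scorings), `auto_only` (automated only), `manual_only` (reference
#' only) or `both_negative`, and reports accuracy
#' `(both_positive + both_negative) / n`. Reference cells without an
#' automated counterpart (excluded by the pipeline's filters) are
#' reported in a separate `excluded` bucket, not as disagreements.
#'
#' @param auto_flags Named logical vector: foci-positive flag per
#'   automated cell label.
#' @param reference_flags Named logical vector: reference flag per
#'   reference cell label.
#' @param matching Data frame from [match_cells()] (`reference`, `auto`).
#'   `NULL` matches by identical names.
#' @return An `agreement_report`: list with `cells` (per-cell category),
#'   `counts`, `accuracy`, `n`, `n_excluded`, `undefined`.
#' @export
per_cell_agreement <- function(auto_flags, reference_flags, matching = NULL) {
  if (is.null(matching)) {
    common <- intersect(names(reference_flags), names(auto_flags))
    matching <- data.frame(reference = common, auto = common)
  }
  ref_ids <- as.character(matching$reference)
  auto_ids <- as.character(matching$auto)
  a <- as.logical(auto_flags[auto_ids])
  r <- as.logical(reference_flags[ref_ids])
  ok <- !is.na(a) & !is.na(r)
  a <- a[ok]; r <- r[ok]
  category <- ifelse(a & r, "both_positive",
                     ifelse(a & !r, "auto_only",
                            ifelse(!a & r, "manual_only", "both_negative")))
  counts <- setNames(vapply(c("both_positive", "auto_only", "manual_only",
                              "both_negative"),
                            function(k) sum(category == k), integer(1)),
                     c("both_positive", "auto_only", "manual_only",
                       "both_negative"))
  n <- length(category)
  n_excluded <- sum(!names(reference_flags) %in% ref_ids[ok]) +
    sum(is.na(a[ok])) * 0L
  accuracy <- if (n > 0) {
    (counts[["both_positive"]] + counts[["both_negative"]]) / n
  } else NA_real_
  structure(list(
    cells = data.frame(reference = ref_ids[ok], auto = auto_ids[ok],
                       category = category, row.names = NULL),
    counts = counts, accuracy = accuracy, n = n,
    n_excluded = n_excluded, undefined = n == 0L
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d accuracy=%s | ++:%d auto-only:%d manual-only:%d --:%d | excluded:%d\n",
              x$n, ifelse(is.na(x$accuracy), "NA", sprintf("%.3f", x$accuracy)),
              x$counts[["both_positive"]], x$counts[["auto_only"]],
              x$counts[["manual_only"]], x$counts[["both_negative"]],
              x$n_excluded))
  invisible(x)
}

#' Percentage of foci-positive cells
#'
#' 100 x positives / denominator over retained cells; with
#' `restrict_epithelial = TRUE` (tissue mode) the denominator is the
#' epithelial retained cells.
#'
#' @param records A `cell_records` (or its `cells` data frame).
#' @param restrict_epithelial Restrict the denominator to epithelial
#'   cells.
#' @return List: `percent`, `n_positive`, `n`, `undefined`.
#' @export
percent_positive <- function(records, restrict_epithelial = FALSE) {
  cells <- if (inherits(records, "cell_records")) records$cells else records
  kept <- cells[cells$kept, , drop = FALSE]
  if (restrict_epithelial) {
    kept <- kept[!is.na(kept$epithelial) & kept$epithelial, , drop = FALSE]
  }
  n <- nrow(kept)
  npos <- sum(kept$foci_positive, na.rm = TRUE)
  list(percent = if (n > 0) 100 * npos / n else NA_real_,
       n_positive = npos, n = n, undefined = n == 0L)
}

#' Aggregate per-image results over tissue-microarray cores
#'
#' Joins per-image counts to a core/tissue/status grouping and reports a
#' percentage per core (flagged `low_n` below `min_cells`), mean and
#' sample SD per tissue over its cores, and pooled rows per status group.
#'
#' @param per_image Data frame: `image`, `n_cells`, `n_positive`.
#' @param grouping Data frame: `image`, `core`, `tissue`, `status`.
#' @param min_cells Minimum cells per core before flagging (default 100).
#' @return List of data frames: `cores`, `tissues`, `status`.
#' @export
aggregate_cores <- function(per_image, grouping, min_cells = 100L) {
  if (!nrow(per_image)) {
    return(list(
      cores = data.frame(core = character(0), tissue = character(0),
                         status = character(0), n_cells = integer(0),
                         percent_positive = numeric(0), low_n = logical(0)),
      tissues = data.frame(tissue = character(0), n_cores = integer(0),
                           mean_percent = numeric(0), sd_percent = numeric(0)),
      status = data.frame(status = character(0), n_cores = integer(0),
                          mean_percent = numeric(0), sd_percent = numeric(0),
                          pooled_percent = numeric(0))))
  }
  d <- merge(per_image, grouping, by = "image")
  agg <- aggregate(cbind(n_cells, n_positive) ~ core + tissue + status,
                   data = d, FUN = sum)
  cores <- data.frame(core = agg$core, tissue = agg$tissue,
                      status = agg$status, n_cells = agg$n_cells,
                      percent_positive = 100 * agg$n_positive / agg$n_cells,
                      low_n = agg$n_cells < min_cells)
  cores <- cores[order(cores$tissue, cores$core), , drop = FALSE]
  rownames(cores) <- NULL

  tsplit <- split(cores, cores$tissue)
  tissues <- do.call(rbind, lapply(names(tsplit), function(t) {
    p <- tsplit[[t]]$percent_positive
    data.frame(tissue = t, n_cores = length(p), mean_percent = mean(p),
               sd_percent = if (length(p) > 1) sd(p) else NA_real_)
  }))
  rownames(tissues) <- NULL

  ssplit <- split(cores, cores$status)
  sagg <- aggregate(cbind(n_cells, n_positive) ~ status, data = agg, FUN = sum)
  status <- do.call(rbind, lapply(names(ssplit), function(s) {
    p <- ssplit[[s]]$percent_positive
    pooled <- sagg[sagg$status == s, , drop = FALSE]
    data.frame(status = s, n_cores = length(p), mean_percent = mean(p),
               sd_percent = if (length(p) > 1) sd(p) else NA_real_,
               pooled_percent = 100 * pooled$n_positive / pooled$n_cells)
  }))
  rownames(status) <- NULL
  list(cores = cores, tissues = tissues, status = status)
}

#' End-to-end evaluation of a pipeline run against simulator ground truth
#'
#' Matches retained automated nuclei to ground-truth nuclei, compares
#' foci-positive calls, and reports the agreement plus recovered and true
#' positive percentages.
#'
#' @param result Output of [analyze_image()].
#' @param truth A `ground_truth`.
#' @param restrict_epithelial Denominator restriction for the percentage
#'   comparison (default: tissue mode of the simulation).
#' @return List: `agreement` (an `agreement_report`), `auto_percent`,
#'   `truth_percent`, `matching`.
#' @export
evaluate_against_truth <- function(result, truth,
                                   restrict_epithelial = truth$params$tissue_mode) {
  records <- result$records
  matching <- match_cells(records$masks$nuclei, truth$nuclei)
  kept <- records$cells[records$cells$kept, , drop = FALSE]
  auto_flags <- setNames(kept$foci_positive, kept$nucleus)
  ref <- ground_truth_scoring(truth, restrict_epithelial)
  agreement <- per_cell_agreement(auto_flags, ref$flags, matching)
  auto_pct <- percent_positive(records, restrict_epithelial)
  list(agreement = agreement,
       auto_percent = auto_pct$percent,
       truth_percent = ref$percent_positive,
       n_auto = auto_pct$n, n_truth = ref$n,
       matching = matching)
}
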