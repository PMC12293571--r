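test_that("agreement on identical flags is perfect", {
  flags <- setNames(rep(c(TRUE, FALSE), 10), 1:20)
  rep_ <- per_cell_agreement(flags, flags)
  expect_equal(rep_$accuracy, 1.0)
  expect_identical(rep_$n, 20L)
  expect_identical(unname(rep_$counts[["auto_only"]]), 0L)
  expect_identical(unname(rep_$counts[["manual_only"]]), 0L)
})

test_that("all-negative scorings agree with accuracy 1 and zero positives", {
  a <- setNames(rep(FALSE, 5), 1:5)
  rep_ <- per_cell_agreement(a, a)
  expect_equal(rep_$accuracy, 1.0)
  expect_identical(unname(rep_$counts[["both_positive"]]), 0L)
  expect_identical(unname(rep_$counts[["both_negative"]]), 5L)
})

test_that("the four agreement categories follow the green/yellow/red semantics", {
  reference <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE, FALSE, TRUE), 1:10)
  auto <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, TRUE, FALSE), 1:10)
  rep_ <- per_cell_agreement(auto, reference)
  expect_identical(unname(rep_$counts[["both_positive"]]), 2L)  # green
  expect_identical(unname(rep_$counts[["both_negative"]]), 6L)
  expect_identical(unname(rep_$counts[["auto_only"]]), 1L)      # yellow
  expect_identical(unname(rep_$counts[["manual_only"]]), 1L)    # red
  expect_equal(rep_$accuracy, 0.8)
})

test_that("accuracy is symmetric under swapping label polarity", {
  set.seed(23)
  r <- setNames(runif(40) < 0.4, 1:40)
  a <- setNames(runif(40) < 0.4, 1:40)
  acc1 <- per_cell_agreement(a, r)$accuracy
  acc2 <- per_cell_agreement(!a, !r)$accuracy
  expect_equal(acc1, acc2)
})

test_that("reference cells missing from the matching land in the excluded bucket", {
  reference <- setNames(c(TRUE, FALSE, FALSE, TRUE), 1:4)
  auto <- setNames(c(TRUE, FALSE), c("1", "2"))
  matching <- data.frame(reference = c(1, 2), auto = c(1, 2))
  rep_ <- per_cell_agreement(auto, reference, matching)
  expect_identical(rep_$n, 2L)
  expect_identical(rep_$n_excluded, 2L)
  # empty matching is flagged undefined
  rep0 <- per_cell_agreement(auto, reference,
                             data.frame(reference = integer(0),
                                        auto = integer(0)))
  expect_true(rep0$undefined)
  expect_true(is.na(rep0$accuracy))
})

test_that("mask-based cell matching is one-to-one by maximal overlap", {
  H <- 60
  truth <- matrix(0L, H, H)
  truth <- paint_rect(truth, 5, 20, 5, 20, 1L)
  truth <- paint_rect(truth, 30, 45, 30, 45, 2L)
  auto <- matrix(0L, H, H)
  auto <- paint_rect(auto, 6, 21, 6, 21, 4L)    # overlaps truth 1
  auto <- paint_rect(auto, 31, 44, 31, 44, 9L)  # overlaps truth 2
  m <- match_cells(auto, truth)
  expect_identical(m$auto[m$reference == 1L], 4L)
  expect_identical(m$auto[m$reference == 2L], 9L)
  expect_identical(anyDuplicated(m$auto), 0L)
})

test_that("percent positive uses retained (and optionally epithelial) cells", {
  cells <- data.frame(nucleus = 1:10, kept = c(rep(TRUE, 8), FALSE, FALSE),
                      epithelial = c(rep(TRUE, 8), TRUE, TRUE),
                      foci_positive = c(TRUE, TRUE, rep(FALSE, 8)))
  p <- percent_positive(cells)
  expect_equal(p$percent, 25.0)
  expect_identical(p$n, 8L)
  p0 <- percent_positive(cells[cells$nucleus > 8, ])
  expect_true(p0$undefined)
  # 0 of n is 0, not NA
  cells$foci_positive <- FALSE
  expect_equal(percent_positive(cells)$percent, 0.0)
})

test_that("core aggregation reports per-core, per-tissue and per-status rows", {
  per_image <- data.frame(image = c("i1", "i2", "i3", "i4"),
                          n_cells = c(200L, 300L, 50L, 400L),
                          n_positive = c(20L, 30L, 5L, 80L))
  grouping <- data.frame(image = c("i1", "i2", "i3", "i4"),
                         core = c("c1", "c2", "c3", "c4"),
                         tissue = c("thyroid", "thyroid", "colon", "colon"),
                         status = c("normal", "normal", "cancer", "cancer"))
  agg <- aggregate_cores(per_image, grouping, min_cells = 100L)
  thy <- agg$tissues[agg$tissues$tissue == "thyroid", ]
  expect_equal(thy$mean_percent, 10.0)
  expect_equal(thy$sd_percent, 0.0)
  # two cores at 10% and 20%: mean 15, sample SD 7.07
  g2 <- grouping; g2$tissue <- "one"; g2$status <- "x"
  p2 <- per_image[c(1, 3), ]; p2$n_positive <- c(20L, 10L)  # 10% and 20%
  a2 <- aggregate_cores(p2, g2[c(1, 3), ], min_cells = 100L)
  expect_equal(a2$tissues$mean_percent, 15.0)
  expect_equal(a2$tissues$sd_percent, 7.07, tolerance = 1e-3)
  # low-n flagging below 100 cells
  expect_true(agg$cores$low_n[agg$cores$core == "c3"])
  # single core: SD undefined
  a1 <- aggregate_cores(per_image[1, ], grouping[1, ])
  expect_true(is.na(a1$tissues$sd_percent))
  # empty input: empty summaries with full headers
  a0 <- aggregate_cores(per_image[0, ], grouping[0, ])
  expect_identical(nrow(a0$cores), 0L)
  expect_identical(nrow(a0$tissues), 0L)
})
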