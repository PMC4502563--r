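test_that("field background is the mean/sd over non-ROI pixels", {
  img <- matrix(5, 50, 50)
  labels <- matrix(0L, 50, 50); labels[10:20, 10:20] <- 1L
  expect_equal(estimate_background(img, labels), c(mean = 5, sd = 0))

  img2 <- matrix(0, 50, 50); img2[10:19, 10:19] <- 100
  labels2 <- matrix(0L, 50, 50); labels2[10:19, 10:19] <- 1L
  expect_equal(estimate_background(img2, labels2), c(mean = 0, sd = 0))

  set.seed(1)
  img3 <- matrix(rnorm(100 * 100, 100, 10), 100, 100)
  bg <- estimate_background(img3, matrix(0L, 100, 100))
  expect_lt(abs(bg[["mean"]] - 100), 1)
  expect_lt(abs(bg[["sd"]] - 10), 1)

  tiny <- matrix(0L, 12, 12); tiny[] <- 1L; tiny[1, 1] <- 0L
  expect_error(estimate_background(matrix(0, 12, 12), tiny),
               class = "clutraffic_error_coverage")
})

test_that("Otsu segmentation separates a bimodal ROI and filters small objects", {
  img <- matrix(10, 60, 60)
  roi <- matrix(TRUE, 60, 60)
  img[20:44, 20:39] <- 200 # 500 px compact high region
  seg <- segment_golgi(img, roi, min_object_px = 20)
  expect_identical(seg$mask, img > seg$threshold_value & roi)
  expect_identical(unname(which(seg$mask)), unname(which(img == 200)))

  img2 <- matrix(10, 60, 60); img2[30, 30:39] <- 200 # 10 px only
  seg2 <- segment_golgi(img2, roi, min_object_px = 20)
  expect_false(any(seg2$mask))

  expect_error(segment_golgi(matrix(7, 20, 20), matrix(TRUE, 20, 20)),
               class = "clutraffic_error_degenerate_threshold")
})

test_that("Golgi segmentation recovers the truth mask on a default scene", {
  sc <- default_scene()
  for (id in 1:4) {
    roi <- sc$truth$cell == id
    seg <- segment_golgi(sc$channels$golgi, roi, min_object_px = 20)
    truth <- sc$truth$golgi == id
    dice <- 2 * sum(seg$mask & truth) / (sum(seg$mask) + sum(truth))
    expect_gte(dice, 0.8)
  }
})

test_that("enrichment ratio matches hand arithmetic and flags degenerate cells", {
  img <- matrix(3, 20, 20)
  roi <- matrix(TRUE, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:10, 5:10] <- TRUE
  expect_equal(golgi_enrichment_ratio(img, roi, mask, 0)$golgi_ratio, 1)

  img2 <- matrix(2, 20, 20); img2[mask] <- 10
  res <- golgi_enrichment_ratio(img2, roi, mask, background_mean = 1)
  expect_equal(res$golgi_ratio, (10 - 1) / (2 - 1))
  expect_equal(res$mean_outside, 1)

  res_empty <- golgi_enrichment_ratio(img2, roi, matrix(FALSE, 20, 20), 1)
  expect_identical(res_empty$flag, "empty_golgi")
  expect_true(is.na(res_empty$golgi_ratio))

  res_deg <- golgi_enrichment_ratio(img2, roi, mask, background_mean = 5)
  expect_identical(res_deg$flag, "degenerate_denominator")
})

test_that("ratio is invariant to intensity shift and scale", {
  sc <- default_scene()
  roi <- sc$truth$cell == 1
  rep_ch <- sc$channels$reporter
  seg <- segment_golgi(sc$channels$golgi, roi, 20)
  bg <- estimate_background(rep_ch, sc$truth$cell)[["mean"]]
  r0 <- golgi_enrichment_ratio(rep_ch, roi, seg$mask, bg)$golgi_ratio
  for (c_shift in c(-20, 13.7, 250)) {
    shifted <- rep_ch + c_shift
    bg_s <- estimate_background(shifted, sc$truth$cell)[["mean"]]
    r1 <- golgi_enrichment_ratio(shifted, roi, seg$mask, bg_s)$golgi_ratio
    expect_lt(abs(r1 - r0), 1e-9)
  }
  for (k in c(0.25, 3, 1000)) {
    r2 <- golgi_enrichment_ratio(rep_ch * k, roi, seg$mask, bg * k)$golgi_ratio
    expect_lt(abs(r2 - r0), 1e-9)
  }
})

test_that("low-signal exclusion flags exactly the cells below the cutoff", {
  m <- tibble::tibble(mean_outside = c(5, 1, 7, 0.5, 3, 9, 2, 8, 0.1, 6),
                      excluded = FALSE)
  out <- exclude_low_signal(m, cutoff = 2)
  expect_identical(which(out$excluded), which(m$mean_outside < 2))
  expect_identical(nrow(out), nrow(m))
  expect_false(any(exclude_low_signal(m, 0)$excluded))
  expect_true(all(exclude_low_signal(m, 100)$excluded))
})

test_that("Pearson colocalization matches a brute-force oracle", {
  roi <- matrix(TRUE, 100, 100)
  set.seed(5)
  a <- matrix(runif(1e4, 0, 100), 100, 100)
  b <- matrix(a + rnorm(1e4, 0, 30), 100, 100)
  expect_equal(pearson_colocalization(a, a, roi), 1.0)
  expect_equal(pearson_colocalization(a, max(a) - a, roi), -1.0)
  # independent covariance/variance computation
  av <- a[roi]; bv <- b[roi]
  oracle <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_lt(abs(pearson_colocalization(a, b, roi) - oracle), 1e-12)
  expect_equal(pearson_colocalization(a, b, roi),
               pearson_colocalization(b, a, roi))
  expect_error(pearson_colocalization(a, matrix(1, 100, 100), roi),
               class = "clutraffic_error_constant_channel")
})

test_that("batch quantification emits one consistent record per ROI", {
  sc <- default_scene()
  cells <- quantify_scene(sc)
  expect_identical(nrow(cells), 6L)
  expect_identical(cells$cell_id, 1:6)
  expect_true(all(cells$genotype %in% c("wt", "mut")))
  expect_true(all(cells$pearson_er >= -1 & cells$pearson_er <= 1, na.rm = TRUE))
  bg <- estimate_background(sc$channels$reporter, sc$truth$cell)
  cutoff <- bg[["mean"]] + 2 * bg[["sd"]]
  expect_identical(cells$excluded, cells$mean_outside < cutoff)
  expect_true(all(is.finite(cells$golgi_ratio[cells$flag == "ok"])))
  expect_identical(quantify_scene(sc), cells)

  empty <- quantify_cells(sc$channels, matrix(0L, 320, 320))
  expect_identical(nrow(empty), 0L)
})

test_that("phenotype separation goes in the expected direction", {
  sc <- default_scene()
  cells <- quantify_scene(sc)
  wt <- cells[cells$genotype == "wt" & !cells$excluded, ]
  mut <- cells[cells$genotype == "mut" & !cells$excluded, ]
  expect_gt(median(wt$golgi_ratio), median(mut$golgi_ratio))
  expect_lt(median(wt$pearson_er), median(mut$pearson_er))
})
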