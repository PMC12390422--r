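test_that("trimmed variance matches hand computations", {
  expect_equal(as.numeric(trimmed_variance(rep(7, 10))), 0)
  # 1..10 at trim 90: threshold 9.1, retained 1..9, sample variance 7.5
  sc <- trimmed_variance(1:10)
  expect_equal(as.numeric(sc), 7.5)
  expect_equal(attr(sc, "threshold"), 9.1)
  expect_equal(attr(sc, "n_retained"), 9L)
  # trim 100 keeps everything: var({2,4,6}) = 4
  p100 <- heterogeneity_params(trim_percentile = 100)
  expect_equal(as.numeric(trimmed_variance(c(2, 4, 6), p100)), 4)
  # population convention
  ppop <- heterogeneity_params(trim_percentile = 100, variance_convention = "population")
  expect_equal(as.numeric(trimmed_variance(c(2, 4, 6), ppop)), 8 / 3)
})

test_that("trimmed variance equals the brute-force oracle on random lists", {
  # length 2 is always degenerate at trim 90 (one value retained), so the
  # defined range starts at 3
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(3:200, 1)
    x <- runif(n, 0, 100)
    got <- as.numeric(trimmed_variance(x))
    want <- oracle_trimmed_variance(x, 90)
    expect_lt(abs(got - want) / max(1e-12, abs(want)), 1e-9)
  }
})

test_that("trimming is order-invariant and monotone against no trimming", {
  set.seed(17)
  x <- c(runif(50, 0, 60), 500)  # strict upper outlier
  expect_identical(as.numeric(trimmed_variance(sample(x))),
                   as.numeric(trimmed_variance(x)))
  p100 <- heterogeneity_params(trim_percentile = 100)
  expect_lt(as.numeric(trimmed_variance(x)),
            as.numeric(trimmed_variance(x, p100)))
  # when the threshold ties the maximum nothing is removed and scores agree
  tied <- c(1, 2, 3, 9, 9)
  expect_equal(as.numeric(trimmed_variance(tied)),
               as.numeric(trimmed_variance(tied, p100)))
})

test_that("degenerate ROIs raise a classed condition with counts", {
  err <- tryCatch(trimmed_variance(c(0, 100), heterogeneity_params(1)),
                  condition = identity)
  expect_s3_class(err, "degenerate_roi")
  expect_equal(err$n_retained, 1L)
  expect_equal(err$n_total, 2L)
})

test_that("roi_values extracts exactly the in-mask voxels in raster order", {
  vals <- array(seq(0, 99.9, length.out = 27), c(3, 3, 3))
  memb <- array(FALSE, c(3, 3, 3)); memb[1:2, 1, 1] <- TRUE; memb[3, 3, 3] <- TRUE
  v <- roi_values(pdff_volume(vals), roi_mask(memb))
  expect_equal(as.numeric(v), vals[memb])
  expect_equal(attr(v, "n_total"), 3L)

  const <- pdff_volume(array(50, c(3, 2, 2)))
  full <- roi_mask(array(TRUE, c(3, 2, 2)))
  expect_equal(as.numeric(roi_values(const, full)), rep(50, 12))

  # sentinel inside the mask is a validation error
  bad <- array(50, c(3, 2, 2)); bad[1, 1, 1] <- NA
  expect_error(roi_values(pdff_volume(bad), full), "non-finite")
  expect_error(roi_values(const, roi_mask(array(FALSE, c(3, 2, 2)))), "empty")
})

test_that("score_dataset yields one record per successful manifest row", {
  geom <- test_geom()
  ds <- simulate_study(list(list(spec = healthy_course(), n_mice = 1)),
                       geom, seed = 12)
  ct <- score_dataset(ds)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$group, "healthy")
  expect_true(all(c("score", "mean_pdff", "n_voxels_total",
                    "n_voxels_retained", "trim_percentile") %in% names(ct)))
  expect_gt(ct$n_voxels_total, ct$n_voxels_retained)

  # a row with a broken path is logged and dropped, not scored as zero
  ds$manifest <- rbind(ds$manifest, ds$manifest[1, ])
  ds$manifest$mouse_id[2] <- "ghost"
  ds$manifest$volume_path[2] <- file.path(tempdir(), "missing.nii.gz")
  expect_warning(ct2 <- score_dataset(ds), "ghost")
  expect_equal(nrow(ct2), 1)
})

test_that("heatmap slices keep raw values, NA background and a fixed scale", {
  ph <- generate_volume(test_geom(), 50, 49, seed = 8)
  s <- test_geom()$grid_shape[3] - 1L  # a distal slice, 0-based
  hm <- heatmap_slice(ph$volume, ph$mask, s)
  expect_equal(attr(hm, "scale"), c(0, 100))
  m <- ph$mask$membership[, , s + 1L]
  expect_true(all(is.na(hm[!m])))
  expect_identical(unclass(hm[m]), ph$volume$values[, , s + 1L][m])
  # a slice outside the mask tube does not exist in this phantom; use an
  # empty-mask volume instead
  empty_mask <- roi_mask(array(rep(c(TRUE, FALSE), each = 8 * 8 * 3), c(8, 8, 6)))
  vol <- pdff_volume(array(10, c(8, 8, 6)))
  expect_error(heatmap_slice(vol, empty_mask, 5L), "no mask voxels")
})
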