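test_that("disease-course evaluation follows the closed forms", {
  h <- healthy_course()
  for (d in h$days)
    expect_equal(simulate_course(h, d)$mean_pdff, 50)

  flat <- disease_course("nonresponder", days = c(0L, 10L, 20L),
                         mu0 = 40, mu_floor = 5, decay_rate = 0,
                         v0 = 30, v_floor = 2, v_decay_rate = 0,
                         day0_inflation = 1)
  for (d in flat$days) {
    out <- simulate_course(flat, d)
    expect_equal(out$mean_pdff, 40)
    expect_equal(out$target_variance, 30)
  }

  nr <- disease_course("nonresponder", days = c(0L, 55L),
                       mu0 = 50, mu_floor = 2, decay_rate = 0.05,
                       v0 = 60, v_floor = 3, v_decay_rate = 0.08,
                       day0_inflation = 2)
  expect_equal(simulate_course(nr, 55)$mean_pdff, 2 + 48 * exp(-2.75))
  expect_equal(simulate_course(nr, 55)$mean_pdff, 5.0686, tolerance = 1e-4)
  expect_equal(simulate_course(nr, 0)$target_variance, 120)

  expect_error(simulate_course(nr, 33), "not a scheduled study day")
})

test_that("nonresponder variance decays strictly over post-baseline days", {
  nr <- nonresponder_course(dropout_prob = 0)
  post <- nr$days[-1]
  v <- vapply(post, function(d) simulate_course(nr, d)$target_variance, 0)
  expect_true(all(diff(v) < 0))
  # responder recovers toward the healthy level
  rs <- responder_course(dropout_prob = 0)
  vr <- vapply(rs$days[-1], function(d) simulate_course(rs, d)$target_variance, 0)
  expect_true(all(diff(vr) > 0))
})

test_that("course specification invariants are enforced", {
  expect_error(disease_course("healthy", days = c(1L, 2L), mu0 = 50, mu_floor = 50,
                              decay_rate = 0, v0 = 10, v_floor = 10, v_decay_rate = 0),
               "days")
  expect_error(disease_course("nonresponder", days = 0L, mu0 = 40, mu_floor = 50,
                              decay_rate = 0.1, v0 = 10, v_floor = 1, v_decay_rate = 0.1),
               "mu_floor")
  expect_error(disease_course("nonresponder", days = 0L, mu0 = 50, mu_floor = 5,
                              decay_rate = 0.1, v0 = 0, v_floor = 0, v_decay_rate = 0.1),
               "v0")
  expect_error(disease_course("nonresponder", days = 0L, mu0 = 50, mu_floor = 5,
                              decay_rate = 0.1, v0 = 10, v_floor = 1, v_decay_rate = 0.1,
                              dropout_prob = 1), "dropout")
})

test_that("generated phantoms honour the requested voxel law", {
  geom <- test_geom()
  # degenerate law: every distal voxel equals the mean exactly
  ph0 <- generate_volume(geom, 42, 0, seed = 5)
  distal <- ph0$mask$region == 3L
  expect_true(all(ph0$volume$values[distal] == 42))

  # proximal slice means sit below distal slice means on a healthy phantom
  ph <- generate_volume(geom, 50, 49, seed = 9)
  tr <- axial_mean_trajectory(ph$volume, ph$mask)
  prox_means <- tr$mean_pdff[tr$slice_index < geom$n_slices_proximal]
  dist_means <- tr$mean_pdff[tr$slice_index >= geom$n_slices_proximal + geom$n_slices_transition]
  expect_true(max(prox_means) < min(dist_means))

  # all in-mask values inside the physical range, out-of-mask is NA sentinel
  vals <- ph$volume$values[ph$mask$membership]
  expect_true(all(vals >= 0 & vals <= 100))
  expect_true(all(is.na(ph$volume$values[!ph$mask$membership])))

  # identical seed gives bit-identical arrays
  ph2 <- generate_volume(geom, 50, 49, seed = 9)
  expect_identical(ph$volume$values, ph2$volume$values)
  expect_identical(ph$mask$region, ph2$mask$region)

  # large-sample variance: >= 1e4 distal voxels within +/-10% of target
  big <- big_distal_geom()
  phb <- generate_volume(big, 50, 49, seed = 3)
  dv <- phb$volume$values[phb$mask$region == 3L]
  expect_gte(length(dv), 1e4)
  expect_lt(abs(var(dv) - 49) / 49, 0.10)

  expect_error(generate_volume(geom, 120, 10, seed = 1), "outside")
  expect_error(generate_volume(geom, 50, 2600, seed = 1), "infeasible")
})

test_that("study simulation bookkeeping, dropout and spleen courses", {
  geom <- test_geom()
  empty <- simulate_study(list(list(spec = healthy_course(), n_mice = 0)),
                          geom, seed = 1, write_volumes = FALSE)
  expect_equal(nrow(empty$manifest), 0)

  nr <- nonresponder_course(dropout_prob = 0)
  expect_equal(nr$days, c(0L, 64L, 69L, 74L))
  ds <- simulate_study(list(list(spec = nr, n_mice = 17)), geom, seed = 2,
                       write_volumes = FALSE)
  expect_equal(nrow(ds$manifest), 17 * 4)
  expect_false(anyDuplicated(paste(ds$manifest$mouse_id, ds$manifest$day)) > 0)

  # reproducible row-for-row
  ds2 <- simulate_study(list(list(spec = nr, n_mice = 17)), geom, seed = 2,
                        write_volumes = FALSE)
  expect_identical(ds$manifest, ds2$manifest)

  # dropout hits only post-baseline days
  drop <- nonresponder_course(dropout_prob = 0.5)
  dsd <- simulate_study(list(list(spec = drop, n_mice = 30)), geom, seed = 4,
                        write_volumes = FALSE)
  day0 <- dsd$manifest[dsd$manifest$day == 0, ]
  expect_equal(nrow(day0), 30)
  expect_lt(nrow(dsd$manifest), 30 * 4)

  # spleen: nonresponders non-decreasing, responders >= 50% drop by final day
  for (m in unique(ds$manifest$mouse_id)) {
    sp <- ds$manifest$spleen_volume[ds$manifest$mouse_id == m]
    expect_true(all(diff(sp) >= 0))
  }
  rs <- responder_course(dropout_prob = 0)
  dsr <- simulate_study(list(list(spec = rs, n_mice = 10)), geom, seed = 6,
                        write_volumes = FALSE)
  for (m in unique(dsr$manifest$mouse_id)) {
    sp <- dsr$manifest$spleen_volume[dsr$manifest$mouse_id == m]
    expect_lte(sp[length(sp)], 0.5 * sp[1])
  }
})

test_that("trimmed scores recover the trim-adjusted generating variance", {
  # oracle: trim + variance applied directly to 1e6 draws of the same law
  sh <- oracle_beta_shapes(50, 49)
  set.seed(101)
  draws <- 100 * rbeta(1e6, sh["alpha"], sh["beta"])
  oracle <- oracle_trimmed_variance(draws, 90)
  # analytic trim adjustment agrees with the simulation oracle
  expect_lt(abs(trim_adjusted_variance(50, 49, 90) - oracle) / oracle, 0.02)

  geom <- test_geom()
  scores <- vapply(1:50, function(i) {
    ph <- generate_volume(geom, 50, 49, seed = 1000 + i)
    m <- roi_mask(ph$mask$region == 3L, bone_axis = 3L)
    as.numeric(trimmed_variance(roi_values(ph$volume, m)))
  }, 0)
  expect_lt(abs(mean(scores) - oracle) / oracle, 0.15)
})

test_that("calibration inverts the trim adjustment", {
  v0 <- calibrate_generating_variance(49, 50, trim = 90)
  expect_gt(v0, 49)  # one-sided trimming deflates variance
  expect_equal(trim_adjusted_variance(50, v0, 90), 49, tolerance = 1e-7)
  expect_equal(healthy_course()$v0, v0)
})
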