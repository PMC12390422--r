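test_that("permutation test matches exhaustive enumeration", {
  # no signal: identical pooled values are degenerate with p = 1
  expect_warning(res0 <- permutation_test(c(5, 5, 5, 5), c(5, 5, 5, 5)),
                 "degenerate")
  expect_equal(res0$statistic_obs, 0)
  expect_equal(res0$p_value, 1)
  expect_true(res0$degenerate)

  # 3 vs 3: all 20 labelings enumerable by the independent combn oracle
  a <- c(1, 2, 3); b <- c(7, 8, 9)
  two <- permutation_test(a, b, "two_sided")
  expect_true(two$exhaustive)
  expect_equal(two$p_value, 2 / 20)
  less <- permutation_test(a, b, "one_sided_less")
  expect_equal(less$p_value, 1 / 20)
  greater <- permutation_test(a, b, "one_sided_greater")
  expect_equal(greater$p_value, 20 / 20)

  # independent oracle on a random instance
  set.seed(33)
  x <- rnorm(4); y <- rnorm(5) + 1
  res <- permutation_test(x, y, "two_sided")
  pooled <- c(x, y)
  obs <- mean(x) - mean(y)
  splits <- combn(9, 4)
  st <- apply(splits, 2, function(ix) mean(pooled[ix]) - mean(pooled[-ix]))
  expect_equal(res$p_value, mean(abs(st) >= abs(obs) - 1e-12))
})

test_that("Monte-Carlo p agrees with exhaustive p and is reproducible", {
  set.seed(44)
  x <- rnorm(5); y <- rnorm(5) + 0.8
  exact <- permutation_test(x, y, "two_sided")$p_value
  mc <- permutation_test(x, y, "two_sided", n_perm = 10000, seed = 9,
                         exhaustive_limit = 0)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc$p_value - exact), 3 * se + 2 / 10001)
  mc2 <- permutation_test(x, y, "two_sided", n_perm = 10000, seed = 9,
                          exhaustive_limit = 0)
  expect_identical(mc$p_value, mc2$p_value)
  expect_false(mc$exhaustive)
  expect_error(permutation_test(c(1), c(2, 3)), "at least 2")
})

test_that("PCA embedding matches the covariance eigendecomposition", {
  # collinear points: PC1 carries all variance
  pts <- rbind(c(-1, 0), c(1, 0))
  emb <- pca_embed(pts, n_components = 2)
  expect_equal(emb$explained_variance[1], 1)

  x <- rbind(c(1, 2), c(3, 1), c(5, 7))
  emb2 <- pca_embed(x, n_components = 2)
  ev <- eigen(cov(x))  # independent oracle
  expect_equal(sort(emb2$explained_variance, decreasing = TRUE),
               ev$values / sum(ev$values))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(emb2$loadings[, j]), unname(v), tolerance = 1e-10)
  }
  # scores are centred and reconstruct the centred matrix exactly
  expect_equal(unname(colMeans(emb2$scores)), c(0, 0), tolerance = 1e-12)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(unname(emb2$scores %*% t(emb2$loadings)), unname(xc),
               tolerance = 1e-10)
  expect_true(all(diff(emb2$explained_variance) <= 1e-12))

  # rows with missing entries are excluded, not imputed
  xm <- rbind(x, c(NA, 1))
  expect_message(emb3 <- pca_embed(xm, 1), "excluding 1")
  expect_equal(emb3$n_dropped, 1)
  expect_error(pca_embed(rbind(c(1, 2))), "fewer than 2")
})

test_that("PCA separation p-value behaves under signal and under the null", {
  set.seed(55)
  # two clusters far apart: every permutation falls below the observed
  cl <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 50, 0.1), 10))
  lab <- rep(c("a", "b"), each = 10)
  res <- pca_separation_pvalue(cl, lab, n_components = 2, n_perm = 999, seed = 2)
  expect_equal(res$p_value, 1 / 1000)

  # one homogeneous cloud: p is typically large across label reassignments
  set.seed(56)
  cloud <- matrix(rnorm(60), 30)
  lab2 <- rep(c("a", "b"), length.out = 30)
  ps <- vapply(1:31, function(s) {
    pca_separation_pvalue(cloud, sample(lab2), n_perm = 199, seed = s)$p_value
  }, 0)
  expect_gt(median(ps), 0.3)
  expect_error(pca_separation_pvalue(cloud, rep("a", 30)), "two label classes")
})

test_that("baseline 1D PCA separates healthy from disease scores", {
  tab <- load_table1_fixture()
  base <- tab[tab$day == 0, ]
  feats <- matrix(base$score, ncol = 1)
  emb <- pca_embed(feats, n_components = 1)
  healthy <- base$group == "healthy"
  # under the sign convention the disease centroid is positive and every
  # healthy subject scores negative
  expect_gt(mean(emb$scores[!healthy, 1]), 0)
  expect_true(all(emb$scores[healthy, 1] < 0))
})

test_that("per-mouse regression and group lines are exact least squares", {
  f1 <- fit_mouse_regression(mouse_course("m1", c(0, 1, 2), score = c(10, 8, 6)))
  expect_equal(f1$slope, -2)
  expect_equal(f1$intercept, 10)
  f2 <- fit_mouse_regression(mouse_course("m2", c(0, 1, 2), score = c(1, 3, 4)))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, 7 / 6)

  g <- combine_group_line(list(
    structure(list(mouse_id = "a", slope = -2, intercept = 10, n_points = 3),
              class = "regression_fit"),
    structure(list(mouse_id = "b", slope = -4, intercept = 20, n_points = 4),
              class = "regression_fit")))
  expect_equal(g$slope, -3)
  expect_equal(g$intercept, 15)
  expect_identical(combine_group_line(list(f1))$slope, f1$slope)
  expect_error(combine_group_line(list()), "no fits")
  expect_error(fit_mouse_regression(mouse_course("m", 0, score = 5)),
               "increasing|fewer")

  # every longitudinally scanned disease-1 mouse declines from its
  # irradiated day-0 variance
  tab <- load_table1_fixture()
  d1 <- tab[tab$group == "disease1", ]
  for (m in unique(d1$mouse_id)) {
    mm <- d1[d1$mouse_id == m, ]
    f <- fit_mouse_regression(mouse_course(m, mm$day, score = mm$score))
    expect_lt(f$slope, 0)
  }
})

test_that("slope estimates recover the generating slope under noise", {
  set.seed(66)
  days <- c(0, 20, 40, 60)
  slopes <- vapply(1:200, function(i) {
    y <- 100 - 1.2 * days + rnorm(4, 0, 5)
    fit_mouse_regression(mouse_course("m", days, score = pmax(y, 0)))$slope
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-1.2)), 2 * se + 0.02)
})

test_that("quartile summaries use linear interpolation per (group, day)", {
  tab <- load_table1_fixture()
  qs <- summarize_violin(tab)
  h <- qs[qs$group == "healthy" & qs$day == 0, ]
  expect_equal(h$q1, 25.96)
  expect_equal(h$median, 46.58)
  expect_equal(h$q3, 71.37)
  expect_equal(h$n, 15)
  # one summary row per populated cell
  expect_equal(nrow(qs), length(unique(paste(tab$group, tab$day))))
  single <- summarize_violin(data.frame(group = "g", mouse_id = "m",
                                        day = 0, score = 12.5))
  expect_equal(unlist(single[, c("q1", "median", "q3")], use.names = FALSE),
               rep(12.5, 3))
})

test_that("mouse classification applies the spleen and PDFF rules in order", {
  resp <- classify_mouse(mouse_course("r", c(0, 30), mean_pdff = c(10, 30),
                                      score = c(5, 40),
                                      spleen_volume = c(100, 45)))
  expect_equal(resp$status, "responder")
  dis <- classify_mouse(mouse_course("d", c(0, 30), mean_pdff = c(40, 10),
                                     score = c(120, 5),
                                     spleen_volume = c(100, 130)))
  expect_equal(dis$status, "diseased")
  flat <- classify_mouse(mouse_course("f", c(0, 30), mean_pdff = c(40, 40),
                                      score = c(50, 50),
                                      spleen_volume = c(100, 100)))
  expect_equal(flat$status, "indeterminate")
  # no spleen data: PDFF criterion only
  nos <- classify_mouse(mouse_course("n", c(0, 30), mean_pdff = c(40, 10),
                                     score = c(120, 5)))
  expect_equal(nos$status, "diseased")
  one <- classify_mouse(mouse_course("o", 0, mean_pdff = 40, score = 50))
  expect_equal(one$status, "indeterminate")
})
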