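test_that("constant-sign runs are enumerated with zeros breaking runs", {
  runs <- sign_runs(c(1, 2, -1, -3, 0, 4))
  expect_equal(runs$start_bin, c(1L, 3L, 6L))
  expect_equal(runs$end_bin, c(2L, 4L, 6L))
  expect_equal(runs$sign, c(1, -1, 1))
  expect_equal(runs$total_abs, c(3, 4, 4))

  expect_equal(nrow(sign_runs(c(0, 0, 0))), 0L)
  one <- sign_runs(-5)
  expect_equal(one$total_abs, 5)
  expect_equal(one$sign, -1)
})

test_that("maximal run statistic honours exclusions", {
  v <- c(1, 2, -1, -3, 0, 4)
  expect_equal(max_run_statistic(v), 4)
  expect_equal(max_run_statistic(v, exclude = 3:4), 4)
  expect_equal(max_run_statistic(v, exclude = c(3, 4, 6)), 3)
  expect_equal(max_run_statistic(rep(0, 6)), 0)
  expect_error(max_run_statistic(v, exclude = 9), "out of range")
})

test_that("degenerate tracks give p = 1 with ties counted as exceedances", {
  zero <- binned_track("c", 0, 1000, rep(0, 30))
  res <- mesoscale_test(zero, n_perm = 50, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)

  single <- binned_track("c", 0, 1000, c(rep(0, 10), 7.5, rep(0, 19)))
  res <- mesoscale_test(single, rebin_factor = 10, n_perm = 100, seed = 2)
  expect_equal(res$observed, 7.5)
  expect_true(all(res$null_values == 7.5))
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo p matches the exhaustive placement oracle on the toy track", {
  values <- c(3, 3, 0, 0, 0, 0)
  p_exact <- enumerate_placement_p(values, rebin_factor = 2)
  expect_equal(p_exact, 11 / 15)

  fine <- binned_track("c", 0, 1000, values)
  n_perm <- 10000
  res <- mesoscale_test(fine, rebin_factor = 2, n_perm = n_perm, seed = 33)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), 3 * se)
})

test_that("statistic is invariant under global sign flip and runs are seeded", {
  set.seed(8)
  v <- rnorm(200)
  bt <- binned_track("c", 0, 1000, v)
  bt_neg <- binned_track("c", 0, 1000, -v)
  r1 <- mesoscale_test(bt, n_perm = 200, seed = 5)
  r2 <- mesoscale_test(bt_neg, n_perm = 200, seed = 5)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$null_values, r2$null_values)

  r3 <- mesoscale_test(bt, n_perm = 200, seed = 5)
  expect_identical(r1$null_values, r3$null_values)
  expect_identical(r1$p_value, r3$p_value)
})

test_that("exclusion zone is frozen and reported in coarse coordinates", {
  vp <- viewpoint("v", "c", 49000, 51000)  # midpoint 50000
  v <- c(rnorm(45), rep(100, 10), rnorm(45))  # large values inside the zone
  fine <- binned_track("c", 0, 1000, v, viewpoint_bin = 51L)
  res <- mesoscale_test(fine, vp, exclusion_radius = 5000, rebin_factor = 10,
                        n_perm = 100, seed = 4)
  # frozen zone spans fine bins 46..55 -> coarse bins 5 and 6 excluded
  expect_equal(res$excluded_coarse, c(5L, 6L))
  # the run of 100s inside the zone must not drive the statistic
  expect_lt(res$observed, 100)
  expect_error(
    mesoscale_test(fine, vp, exclusion_radius = 60000, n_perm = 10, seed = 1),
    "whole region")
})

test_that("meso-scale test is calibrated when fine bins are exchangeable", {
  vp <- viewpoint("v", "c", 99000, 101000)
  n_sim <- 300
  set.seed(314)
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    fine <- binned_track("c", 0, 1000, rnorm(200), viewpoint_bin = 101L)
    rej[i] <- mesoscale_test(fine, vp, exclusion_radius = 10000,
                             n_perm = 400, seed = i)$p_value <= 0.05
  }
  ci <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])
})
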