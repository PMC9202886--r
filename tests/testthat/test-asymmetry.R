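test_that("mirror pairs are built symmetrically around the viewpoint bin", {
  vp <- viewpoint("v", "c", 4000, 5000)  # midpoint 4500, bin 5 of a 1 kb grid
  sym <- binned_track("c", 0, 1000, c(4, 3, 2, 1, 9, 1, 2, 3, 4))
  pairs <- build_mirror_pairs(sym, vp, n_pairs = 4)
  expect_equal(pairs$diffs, rep(0, 4))
  expect_equal(pairs$viewpoint_bin, 5L)

  asym <- binned_track("c", 0, 1000, c(0, 3, 2, 1, 9, 0, 0, 0, 0))
  pairs <- build_mirror_pairs(asym, vp, n_pairs = 3)
  expect_equal(pairs$up, c(1, 2, 3))
  expect_equal(pairs$down, c(0, 0, 0))
  expect_equal(pairs$diffs, c(1, 2, 3))

  expect_error(build_mirror_pairs(sym, vp, n_pairs = 10), "pairs need")
})

test_that("up/down statistic sums the paired differences and negates on swap", {
  pairs <- mk_pairs(c(1, 2, 3), c(0, 0, 0))
  expect_equal(updown_statistic(pairs), 6)
  expect_equal(updown_statistic(mk_pairs(c(0, 0, 0), c(1, 2, 3))), -6)
  expect_equal(updown_statistic(mk_pairs(c(2, 5), c(2, 5))), 0)
})

test_that("exact enumeration matches the printed example and brute force", {
  res <- asymmetry_test(mk_pairs(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(res$method, "exact")
  expect_equal(res$n_perm, 8)
  expect_equal(res$p_value, 0.25)

  set.seed(77)
  for (rep in 1:6) {
    x <- round(rnorm(sample(5:12, 1)), 2)
    res <- asymmetry_test(mk_pairs(x, numeric(length(x))))
    expect_equal(res$p_value, brute_force_signflip_p(x))
    for (alt in c("greater", "less")) {
      res_a <- asymmetry_test(mk_pairs(x, numeric(length(x))), alternative = alt)
      expect_equal(res_a$p_value, brute_force_signflip_p(x, alt))
    }
  }

  expect_equal(asymmetry_test(mk_pairs(rep(0, 6), rep(0, 6)))$p_value, 1)
})

test_that("Monte Carlo converges to the exact p and is seed-reproducible", {
  set.seed(13)
  x <- rnorm(10)
  pairs <- mk_pairs(x, numeric(10))
  p_exact <- asymmetry_test(pairs)$p_value
  n_perm <- 20000
  res <- asymmetry_test(pairs, n_perm = n_perm, seed = 6, exact_threshold = 0)
  expect_equal(res$method, "monte_carlo")
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), 3 * se)

  res2 <- asymmetry_test(pairs, n_perm = n_perm, seed = 6, exact_threshold = 0)
  expect_identical(res$null_values, res2$null_values)
  expect_error(asymmetry_test(pairs, seed = NULL, exact_threshold = 0), "seed")
})

test_that("two-sided p is invariant to relabelling upstream and downstream", {
  set.seed(23)
  x <- rnorm(14)
  p_ud <- asymmetry_test(mk_pairs(x, numeric(14)))$p_value
  p_du <- asymmetry_test(mk_pairs(numeric(14), x))$p_value
  expect_equal(p_ud, p_du)
})

test_that("the permutation space size is 2^n, exact at the default 50 pairs", {
  expect_identical(count_permutations(50), 1125899906842624)
  expect_identical(count_permutations(0), 1)
  expect_identical(count_permutations(10), 1024)
  expect_error(count_permutations(-1), "non-negative")
})

test_that("sign-flip test is calibrated for independent symmetric differences", {
  n_sim <- 400
  set.seed(271)
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    pairs <- mk_pairs(rnorm(50), numeric(50))
    rej[i] <- asymmetry_test(pairs, n_perm = 2000, seed = i)$p_value <= 0.05
  }
  ci <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])
})

test_that("a doubled flank amplitude is detected with high power", {
  sc <- null_scenario()
  g <- scenario_genome(sc, sc$seed)
  eff <- list(neuron = list(injected_effect(flank = "upstream", flank_scale = 2)),
              esc = list())
  n_sim <- 25
  set.seed(55)
  seeds <- sample.int(2^31 - 2, n_sim)
  hits <- 0L
  for (i in seq_len(n_sim)) {
    cm <- simulate_experiment(g$fragments, g$vp, sc$conditions, 2,
                              decay_model(), eff, c(0.5, 2), seed = seeds[i])
    d <- delta_track(normalize_counts(cm), "neuron", "esc")
    fine <- bin_track(trim_to_roi(d, g$vp), 1000, vp = g$vp)
    p <- asymmetry_test(build_mirror_pairs(fine, g$vp, 50), 10000,
                        seed = seeds[i] + 1)$p_value
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits / n_sim, 0.9)
})
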