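test_that("simulation is deterministic given a seed and demands one", {
  fr <- frag_grid(rep(500, 100))
  vp <- viewpoint("v", "chrT", 24500, 25500)
  t1 <- simulate_track(fr, vp, seed = 10)
  t2 <- simulate_track(fr, vp, seed = 10)
  expect_identical(t1$counts, t2$counts)
  t3 <- simulate_track(fr, vp, seed = 11)
  expect_false(identical(t1$counts, t3$counts))
  expect_error(simulate_track(fr, vp), "seed")
  expect_error(simulate_experiment(fr, vp), "seed")
  expect_error(simulate_significance(fr, NULL), "seed")
})

test_that("empirical means follow the distance-decay model", {
  model <- decay_model(amplitude = 300, half_distance = 4000, exponent = 1.3,
                       dispersion = 5)
  fr <- frag_grid(rep(1000, 100))
  vp <- viewpoint("v", "chrT", 49000, 51000)  # midpoint 50000, inside frag 50
  n_rep <- 400
  acc <- matrix(0, n_rep, 3)
  probe <- c(51L, 60L, 90L)  # viewpoint fragment, ~9 kb, ~39 kb downstream
  for (r in seq_len(n_rep)) {
    tr <- simulate_track(fr, vp, model, seed = 1000 + r)
    acc[r, ] <- tr$counts[probe]
  }
  d <- c(0, 9000, 39000)  # near-edge distances of the probed fragments
  mu <- 300 * (1 + d / 4000)^(-1.3)
  for (j in 1:3) {
    sem <- sd(acc[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(acc[, j]) - mu[j]), 4 * sem + 1e-9)
  }
})

test_that("an injected fold is recovered from replicate draws", {
  model <- decay_model()
  fr <- frag_grid(rep(1000, 100))
  vp <- viewpoint("v", "chrT", 0, 1000)
  region <- gr0("chrT", 40000, 60000)
  eff <- injected_effect(region, fold = 3)
  inside <- which(IRanges::countOverlaps(fr, region) > 0)
  n_rep <- 500
  ratios <- numeric(n_rep)
  d_in <- GenomicRanges::start(fr)[inside] - 1 - vp$midpoint
  base_mu <- 300 * (1 + d_in / 4000)^(-1.3)
  for (r in seq_len(n_rep)) {
    tr <- simulate_track(fr, vp, model, list(eff), seed = 5000 + r)
    ratios[r] <- mean(tr$counts[inside] / base_mu)
  }
  sem <- sd(ratios) / sqrt(n_rep)
  expect_lt(abs(mean(ratios) - 3), 3 * sem)
})

test_that("depth factors are recovered by size-factor estimation", {
  fr <- frag_grid(rep(1000, 300))
  vp <- viewpoint("v", "chrT", 149000, 151000)
  depths <- c(1, 1, 2, 1)
  tracks <- lapply(1:4, function(j)
    simulate_track(fr, vp, decay_model(), depth_factor = depths[j],
                   seed = 100 + j, sample_id = paste0("s", j),
                   condition = c("a", "a", "b", "b")[j],
                   replicate = c("r1", "r2", "r1", "r2")[j]))
  sf <- size_factors(bind_tracks(tracks))
  ratio <- sf[3] / exp(mean(log(sf[-3])))
  expect_lt(abs(ratio - 2) / 2, 0.1)
})

test_that("flank scaling raises one flank only", {
  fr <- frag_grid(rep(1000, 100))
  vp <- viewpoint("v", "chrT", 49000, 51000)
  eff <- injected_effect(flank = "upstream", flank_scale = 4)
  n_rep <- 100
  up_ratio <- down_ratio <- numeric(n_rep)
  up_idx <- 20:40; down_idx <- 60:80
  for (r in seq_len(n_rep)) {
    t_eff <- simulate_track(fr, vp, effects = list(eff), seed = 300 + r)
    t_null <- simulate_track(fr, vp, seed = 300 + r + n_rep)
    up_ratio[r] <- sum(t_eff$counts[up_idx]) / max(1, sum(t_null$counts[up_idx]))
    down_ratio[r] <- sum(t_eff$counts[down_idx]) / max(1, sum(t_null$counts[down_idx]))
  }
  expect_gt(mean(up_ratio), 2.5)
  expect_lt(mean(down_ratio), 1.5)
})

test_that("synthetic significance tables obey their construction rules", {
  fr <- frag_grid(rep(1000, 50))
  region <- gr0("chrT", 20000, 25000)  # fragments 21..25
  sig <- simulate_significance(fr, region, cell_types = c("A", "B"), seed = 9)
  expect_named(sig, c("A", "B"))
  inside <- 21:25
  for (ct in names(sig)) {
    expect_true(all(sig[[ct]][inside, c("q_rep1", "q_rep2")] < 0.05))
    expect_true(all(sig[[ct]][-inside, c("q_rep1", "q_rep2")] >= 0.2))
    expect_true(all(sig[[ct]]$p_rep1 <= sig[[ct]]$q_rep1))
  }
  sets <- replicated_significant(sig, q_threshold = 0.1)
  expect_length(sets$A, 5L)

  # background can never replicate below q = 0.1
  none <- simulate_significance(fr, NULL, cell_types = c("A", "B"), seed = 10)
  sets0 <- replicated_significant(none, q_threshold = 0.1)
  expect_length(attr(sets0, "all_keys"), 0L)

  again <- simulate_significance(fr, region, cell_types = c("A", "B"), seed = 9)
  expect_identical(sig, again)
})
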