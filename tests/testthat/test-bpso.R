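# Binary particle swarm search: update equations against scalar oracles,
# fitness against a hand nearest-neighbour oracle, bookkeeping rules, and
# whole-run behaviour against exhaustive search.

test_that("swarm initialization is seeded, shaped and repaired", {
  cfg <- bpso_config(swarm_size = 4, seed = 3)
  s1 <- with_seed(1, init_swarm(5, cfg))
  s2 <- with_seed(1, init_swarm(5, cfg))
  expect_identical(s1, s2)
  expect_length(s1, 4L)
  for (p in s1) {
    expect_true(all(p$position %in% c(0L, 1L)))
    expect_length(p$position, 5L)
    expect_true(all(abs(p$velocity) <= cfg$v_max))
    expect_gte(sum(p$position), 1L)  # never an empty mask
    expect_identical(p$pbest_position, p$position)
  }
  expect_error(init_swarm(0, cfg), ">= 1")
})

test_that("empty masks are repaired to a single random bit", {
  with_seed(2, {
    reps <- replicate(200, repair_empty_mask(rep(0L, 6)))
  })
  expect_true(all(colSums(reps == 1L) == 1L))
  # all coordinates get chosen eventually (uniform choice)
  expect_true(all(rowSums(reps) > 0))
  # non-empty masks pass through untouched
  expect_identical(repair_empty_mask(c(0L, 1L, 0L)), c(0L, 1L, 0L))
})

test_that("velocity update matches a literal scalar transcription", {
  cfg <- bpso_config(c1 = 1.7, c2 = 2.3, v_max = 4)
  p <- list(position = c(1L, 0L, 1L, 0L),
            velocity = c(0.5, -1, 2, 0),
            pbest_position = c(1L, 1L, 0L, 0L),
            pbest_fitness = 0.2)
  gbest <- c(0L, 1L, 1L, 0L)
  r1 <- c(0.11, 0.52, 0.93, 0.44)
  r2 <- c(0.71, 0.02, 0.33, 0.84)
  got <- update_velocity(p, gbest, cfg, w = 0.73, r1 = r1, r2 = r2)
  # independent scalar-loop oracle
  expected <- numeric(4)
  for (d in 1:4) {
    v <- 0.73 * p$velocity[d] +
      1.7 * r1[d] * (p$pbest_position[d] - p$position[d]) +
      2.3 * r2[d] * (gbest[d] - p$position[d])
    expected[d] <- max(-4, min(4, v))
  }
  expect_equal(got, expected, tolerance = 1e-15)

  # x = pbest = gbest with w = 1: both attraction terms vanish
  q <- list(position = c(1L, 0L), velocity = c(0.3, -0.2),
            pbest_position = c(1L, 0L), pbest_fitness = 0)
  expect_equal(update_velocity(q, c(1L, 0L), cfg, w = 1), q$velocity)

  # w = 0, x = pbest, gbest differs in one coordinate: only that
  # coordinate moves, toward gbest
  q$velocity <- c(0, 0)
  v <- update_velocity(q, c(0L, 0L), cfg, w = 0, r1 = c(.5, .5), r2 = c(.5, .5))
  expect_lt(v[1], 0)
  expect_identical(v[2], 0)

  expect_error(update_velocity(p, c(0L, 1L), cfg), "dimension mismatch")
})

test_that("sigmoid transfer is the logistic function with its symmetries", {
  expect_equal(sigmoid_transfer(0), 0.5)
  v <- with_seed(8, rnorm(50, sd = 3))
  expect_equal(sigmoid_transfer(v) + sigmoid_transfer(-v), rep(1, 50))
  big <- sigmoid_transfer(c(5, 10, 20))
  expect_true(all(diff(big) > 0))
  expect_gt(big[3], 1 - 1e-8)
})

test_that("position update resamples from the sigmoid of the velocity", {
  # saturated velocities pin the position
  p <- list(velocity = rep(20, 6))
  expect_identical(with_seed(1, update_position(p)), rep(1L, 6))
  # strongly negative velocities give all zeros; repair leaves one bit
  pneg <- list(velocity = rep(-20, 6))
  expect_identical(sum(with_seed(1, update_position(pneg))), 1L)
  expect_identical(sum(with_seed(1, update_position(pneg, repair = FALSE))), 0L)

  # zero velocity: fair coin flips, frequency about one half
  pz <- list(velocity = rep(0, 10))
  freq <- with_seed(12, mean(replicate(1000, mean(update_position(pz)))))
  expect_lt(abs(freq - 0.5), 0.02)

  # fixed rng stream reproduces positions
  pr <- list(velocity = rnorm(8))
  expect_identical(with_seed(4, update_position(pr)),
                   with_seed(4, update_position(pr)))
})

test_that("kNN fitness agrees with a hand nearest-neighbour oracle", {
  # n = 8, D = 3, k = 1, fixed holdout: compute 1-NN by explicit distances
  x <- matrix(c(0, 0, 0,
                0.1, 0, 0,
                5, 5, 5,
                5.1, 5, 5,
                0, 0.2, 0,
                5, 5.2, 5,
                2.4, 2.4, 2.4,
                2.8, 2.6, 2.6), ncol = 3, byrow = TRUE)
  labels <- c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  d <- feature_dataset(x, labels)
  holdout <- list(train = 1:6, val = 7:8)
  cfg <- bpso_config(knn_k = 1)
  mask <- c(1L, 1L, 1L)
  got <- knn_fitness(mask, d, cfg, holdout)
  # oracle: explicit distance table
  pred <- vapply(holdout$val, function(i) {
    dist2 <- colSums((t(x[holdout$train, ]) - x[i, ])^2)
    labels[holdout$train][which.min(dist2)]
  }, integer(1))
  expect_equal(got, mean(pred != labels[holdout$val]))
  # hand distance table: point 7 is nearest (0, 0.2, 0) (class 0), point 8
  # is nearest (5, 5, 5) (class 1); both correct, so the error is 0
  expect_equal(got, 0)
})

test_that("separable data reach zero fitness and permuted labels sit near 0.5", {
  d <- tiny_separable(n = 40)
  cfg <- bpso_config(knn_k = 3)
  holdout <- with_seed(1, stratified_split_for_tests(d$labels, 0.8))
  expect_equal(knn_fitness(c(1L, 0L, 0L, 0L), d, cfg, holdout), 0)

  perm <- with_seed(6, feature_dataset(d$x, sample(d$labels)))
  fits <- vapply(1:8, function(s) {
    h <- with_seed(s, stratified_split_for_tests(perm$labels, 0.8))
    knn_fitness(rep(1L, ncol(perm$x)), perm, cfg, h)
  }, numeric(1))
  expect_lt(abs(mean(fits) - 0.5), 0.2)
})

test_that("pbest and gbest move only on strict improvement", {
  swarm <- list(list(position = c(1L, 0L), velocity = c(0, 0),
                     pbest_position = c(1L, 1L), pbest_fitness = 0.3))
  gbest <- list(position = c(1L, 1L), fitness = 0.3)

  # worsening leaves pbest untouched
  st <- update_pbest_gbest(swarm, 0.5, gbest)
  expect_equal(st$swarm[[1]]$pbest_fitness, 0.3)
  expect_identical(st$swarm[[1]]$pbest_position, c(1L, 1L))

  # exact tie keeps the incumbent
  st <- update_pbest_gbest(swarm, 0.3, gbest)
  expect_identical(st$swarm[[1]]$pbest_position, c(1L, 1L))
  expect_identical(st$gbest$position, c(1L, 1L))

  # strict improvement replaces both
  st <- update_pbest_gbest(swarm, 0.1, gbest)
  expect_equal(st$swarm[[1]]$pbest_fitness, 0.1)
  expect_identical(st$swarm[[1]]$pbest_position, c(1L, 0L))
  expect_equal(st$gbest$fitness, 0.1)
})

test_that("gbest tracks the minimum of all pbests across iterations", {
  d <- tiny_separable(n = 30, noise_cols = 5)
  sel <- bpso_select(d, bpso_config(swarm_size = 6, max_iter = 10, seed = 2))
  expect_true(all(diff(sel$history) <= 0))
  expect_equal(sel$fitness, min(sel$history))
  expect_gte(sel$n_selected, 1L)
  expect_identical(sel$selected, which(sel$mask == 1L))
})

test_that("full runs are deterministic under a fixed seed", {
  d <- tiny_separable(n = 30, noise_cols = 4)
  cfg <- bpso_config(swarm_size = 5, max_iter = 8, seed = 42)
  a <- bpso_select(d, cfg)
  b <- bpso_select(d, cfg)
  expect_identical(a$mask, b$mask)
  expect_identical(a$history, b$history)
  expect_identical(a$fitness, b$fitness)
})

test_that("exhaustive search lower-bounds gbest and tiny problems are solved", {
  d <- with_seed(13, {
    labels <- rep(c(0L, 1L), each = 15)
    x <- cbind(rnorm(30, 3 * labels), rnorm(30, -2 * labels),
               matrix(rnorm(30 * 3), 30, 3))
    feature_dataset(x, labels)
  })
  cfg <- bpso_config(swarm_size = 8, max_iter = 15, knn_k = 3, seed = 5)
  sel <- bpso_select(d, cfg)
  best <- exhaustive_best_fitness(d, cfg, sel$holdout)
  expect_gte(sel$fitness, best)        # oracle lower bound
  expect_lte(sel$fitness, best + 0.15) # and close at this budget

  # single-class data are refused
  mono <- feature_dataset(matrix(rnorm(20), 10, 2), rep(1L, 10))
  expect_error(bpso_select(mono, cfg), "both classes")
})

test_that("planted informative features are recovered across seeded runs", {
  d <- make_feature_fixture(feature_fixture_spec(
    n_samples = 100, n_informative = 2, n_noise = 10, seed = 17))
  cfg <- bpso_config(swarm_size = 10, max_iter = 20)
  batch <- bpso_select_runs(d, cfg, seeds = 0:6)
  expect_true(all(batch$majority_mask[d$informative] == 1L))
  # selected-set fitness no worse than the all-features mask, per run
  for (run in batch$runs) {
    all_feat <- knn_fitness(rep(1L, ncol(d$x)), d, cfg, run$holdout)
    expect_lte(run$fitness, all_feat)
  }
  # mean curve is an average of non-increasing curves, hence non-increasing
  expect_true(all(diff(batch$mean_history) <= 1e-12))
})
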