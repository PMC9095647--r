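test_that("kNN construction is exact and deterministic", {
  # three collinear points: the middle one is everyone's first neighbor
  x <- cbind(c(0, 1, 2), 0)
  g <- build_knn(x, 1)
  expect_equal(g$indices[, 1], c(2L, c(1L, 3L)[1], 2L))

  set.seed(13)
  y <- matrix(rnorm(200 * 8), 200, 8)
  g2 <- build_knn(y, 7)
  expect_identical(g2$indices, brute_knn(y, 7))

  # duplicate points: ties broken by index
  z <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 5))
  g3 <- build_knn(z, 2)
  expect_equal(g3$indices[4, ], c(1L, 2L))
  expect_equal(g3$indices[3, ], c(1L, 2L))
  expect_error(build_knn(z, 4), "smaller")
})

test_that("kBET is 1 for disjoint batches and near alpha under the null", {
  set.seed(14)
  x <- rbind(matrix(rnorm(500 * 20), 500), matrix(rnorm(500 * 20, 10), 500))
  b <- rep(c("A", "B"), each = 500)
  g <- build_knn(x, 50)
  r <- kbet_rejection_rate(g, b, alpha = 0.05, n_subsets = 100, seed = 1)
  expect_gte(r$rejection_rate, 0.95)

  # identical-distribution batches: mean rejection over Monte-Carlo
  # repeats stays at most twice the nominal level
  rates <- vapply(1:50, function(i) {
    set.seed(100 + i)
    xx <- matrix(rnorm(400 * 10), 400)
    gg <- build_knn(xx, 40)
    kbet_rejection_rate(gg, rep(c("A", "B"), 200), n_subsets = 50,
                        seed = i)$rejection_rate
  }, 0)
  expect_lte(mean(rates), 0.10)

  # seeded determinism
  expect_identical(kbet_rejection_rate(g, b, seed = 5)$rejection_rate,
                   kbet_rejection_rate(g, b, seed = 5)$rejection_rate)
  expect_error(kbet_rejection_rate(g, rep("A", 1000)), "2 batches")
  sub <- c(1:25, 501:525)
  expect_warning(kbet_rejection_rate(build_knn(x[sub, ], 5),
                                     b[sub], seed = 1), "k < 10")
})

test_that("kBET rejection increases monotonically with batch shift", {
  med_rate <- vapply(c(0.2, 0.6, 1.8), function(shift) {
    rates <- vapply(1:10, function(i) {
      set.seed(200 + i)
      x <- rbind(matrix(rnorm(300 * 5), 300),
                 matrix(rnorm(300 * 5, shift), 300))
      g <- build_knn(x, 50)
      kbet_rejection_rate(g, rep(c("A", "B"), each = 300), n_subsets = 50,
                          seed = i)$rejection_rate
    }, 0)
    median(rates)
  }, 0)
  expect_lt(med_rate[1], med_rate[2])
  expect_lt(med_rate[2], med_rate[3])
})

test_that("stratified sampling draws exact per-group counts, seeded", {
  sim <- simulate_cell_table(sim_table_config(seed = 15))
  s <- stratified_sample(sim$table, 600, seed = 4)
  expect_equal(nrow(s), 5400)   # 3 cores x 3 batches x 600
  expect_true(all(table(s$core_id, s$batch_id) == 600))
  expect_identical(s, stratified_sample(sim$table, 600, seed = 4))
  expect_false(identical(s, stratified_sample(sim$table, 600, seed = 5)))

  # a group of exactly n cells is returned whole
  mini <- sim$table[sim$table$core_id == "core01" &
                    sim$table$batch_id == "B1", ][1:50, ]
  whole <- stratified_sample(mini, 50, seed = 1)
  expect_setequal(whole$cell_id, mini$cell_id)

  # a deficient group is named in the error
  short <- rbind(mini, sim$table[sim$table$core_id == "core02" &
                                 sim$table$batch_id == "B1", ][1:49, ])
  expect_error(stratified_sample(short, 50, seed = 1), "core02")
})

test_that("graph clustering separates blobs and is reproducible", {
  set.seed(16)
  x <- rbind(matrix(rnorm(300 * 5), 300), matrix(rnorm(300 * 5, 6), 300))
  cl <- cluster_cells(x, resolution = 0.6, seed = 2)
  expect_gte(min(cl), 0)
  expect_equal(sort(unique(cl)), seq_len(length(unique(cl))) - 1L)
  expect_gt(ari(cl, rep(1:2, each = 300)), 0.95)
  expect_identical(cl, cluster_cells(x, resolution = 0.6, seed = 2))

  expect_equal(cluster_cells(matrix(1, 2, 2)), c(0L, 0L))
  expect_error(cluster_cells(matrix(1, 1, 2)), "at least 2")
})

test_that("cluster composition correlation handles replicate structure", {
  # identical composition vectors correlate perfectly
  labs <- rep(c(0, 1, 2), times = c(50, 30, 20))
  r1 <- cluster_composition_correlation(c(labs, labs),
                                        rep(c("s1", "s2"), each = 100),
                                        rep("coreA", 200))
  expect_equal(r1$r, 1)

  # hand-computed Pearson for reversed fractions
  la <- rep(c(0, 1, 2), times = c(50, 30, 20))
  lb <- rep(c(0, 1, 2), times = c(20, 30, 50))
  r2 <- cluster_composition_correlation(c(la, lb),
                                        rep(c("s1", "s2"), each = 100),
                                        rep("coreA", 200))
  expect_equal(r2$r, cor(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5)))
  expect_equal(r2$r, -0.9285714, tolerance = 1e-6)

  # 3 cores x 3 replicates yield 9 pairwise values
  set.seed(17)
  n <- 900
  labs3 <- sample(0:4, n, replace = TRUE)
  reps <- rep(c("s1", "s2", "s3"), each = 300)
  units <- rep(rep(c("c1", "c2", "c3"), each = 100), 3)
  r3 <- cluster_composition_correlation(labs3, reps, units)
  expect_equal(nrow(r3), 9)

  # a unit absent from a replicate is an error
  expect_error(cluster_composition_correlation(
    labs3[1:500], reps[1:500], units[1:500]), "absent")
})

test_that("composition vectors sum to one per unit and replicate", {
  set.seed(18)
  labs <- sample(0:3, 600, replace = TRUE)
  reps <- rep(c("s1", "s2"), each = 300)
  units <- rep(rep(c("c1", "c2"), each = 150), 2)
  # correlation of a composition vector with itself is 1 regardless of unit
  same <- cluster_composition_correlation(c(labs, labs),
                                          rep(c("a", "b"), each = 600),
                                          rep(units, 2))
  expect_true(all(same$r > 0.99))
})
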