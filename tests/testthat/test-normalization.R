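test_that("intensity transforms follow their definitions", {
  expect_equal(transform_intensity(0, "log2"), 0)
  expect_equal(transform_intensity(1023, "log2"), 10)
  expect_equal(transform_intensity(c(3, 7), "raw"), c(3, 7))
  x <- sort(rlnorm(200, 4, 1))
  expect_false(is.unsorted(transform_intensity(x, "arcsinh")))
  expect_equal(transform_intensity(10, "arcsinh"), asinh(2))
  expect_error(transform_intensity(-1, "log2"), "negative")
})

test_that("scalers normalize as specified", {
  expect_equal(apply_scaler(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  z <- apply_scaler(rlnorm(500, 3, 1), "standard")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(max(abs(apply_scaler(c(-4, 2, 8), "maxabs"))), 1)
  r <- apply_scaler(c(1, 2, 3, 4, 100), "robust")
  expect_equal(r[3], 0)  # median maps to 0

  # quantile scaler: rank-to-uniform, Kolmogorov distance < 0.05 at n=1000
  set.seed(2)
  q <- apply_scaler(rlnorm(1000, 5, 2), "quantile")
  expect_true(all(q > 0 & q < 1))
  ks <- max(abs(sort(q) - (seq_len(1000) - 0.5) / 1000))
  expect_lt(ks, 0.05)

  # power transform stabilizes a lognormal toward normality
  set.seed(3)
  x <- rlnorm(2000, 2, 0.8)
  p <- apply_scaler(x, "power")
  expect_lt(abs(mean(p)), 1e-6)
  expect_lt(abs(mean(((p - mean(p)) / sd(p))^3)), abs(mean(scale(x)^3)))

  expect_error(apply_scaler(rep(3, 10), "standard"), "zero variance")
  expect_error(apply_scaler(rep(3, 10), "minmax"), "zero range")
})

test_that("exclusivity score matches its closed form and calibration", {
  set.seed(4)
  x <- rlnorm(5000, 5, 1)
  expect_equal(exclusivity_score(x, x), 0, tolerance = 1e-6)

  # bivariate normal with correlation r scores sqrt((1 - r) / (1 + r))
  for (r in c(0.9, 0.5)) {
    a <- rnorm(50000)
    b <- r * a + sqrt(1 - r^2) * rnorm(50000)
    expect_equal(exclusivity_score(a + 10, b + 10),
                 sqrt((1 - r) / (1 + r)), tolerance = 0.02)
  }

  # exclusive L-pair (each cell positive in exactly one marker, 50/50)
  # clears the 0.5 selection cut-off
  z <- runif(4000) < 0.5
  hi <- function(n) 2000 * rlnorm(n, 0, 0.85)
  lo <- function(n) rlnorm(n, log(40), 0.5)
  a <- ifelse(z, hi(4000), lo(4000))
  b <- ifelse(z, lo(4000), hi(4000))
  expect_gt(exclusivity_score(a, b), 0.5)
  expect_error(exclusivity_score(rep(1, 200), rnorm(200)), "constant")
})

test_that("pair selection applies primary and fallback cut-offs", {
  set.seed(6)
  n <- 3000
  z <- runif(n) < 0.5
  A <- ifelse(z, 2000 * rlnorm(n, 0, 0.85), rlnorm(n, log(40), 0.5))
  B <- ifelse(z, rlnorm(n, log(40), 0.5), 2000 * rlnorm(n, 0, 0.85))
  C <- A * rlnorm(n, 0, 0.1)   # co-expressed with A
  tab <- data.frame(A = A, B = B, C = C)
  pairs <- select_exclusive_pairs(tab, c("A", "B", "C"), scope = "core")
  a_rows <- pairs[pairs$marker == "A", ]
  expect_identical(a_rows$partner, "B")
  expect_identical(a_rows$cutoff, "primary")

  # all markers co-expressed: everything unnormalizable
  co <- data.frame(A = A, B = A * rlnorm(n, 0, 0.1),
                   C = A * rlnorm(n, 0, 0.1))
  p2 <- select_exclusive_pairs(co, c("A", "B", "C"), scope = "core")
  expect_equal(nrow(p2), 0)
  expect_setequal(attr(p2, "unnormalizable"), c("A", "B", "C"))

  # a pair whose score lies between the fallback and primary cut-offs is
  # selected through the fallback path
  r <- (1 - 0.3^2) / (1 + 0.3^2)   # closed form: score ~ 0.3
  a <- rnorm(n); b <- r * a + sqrt(1 - r^2) * rnorm(n)
  mid <- data.frame(A = a + 10, B = b + 10)
  p3 <- select_exclusive_pairs(mid, c("A", "B"), scope = "core")
  expect_identical(unique(p3$cutoff), "fallback")

  expect_error(select_exclusive_pairs(tab, "A"), "at least 2")
})

test_that("restore_threshold takes the median candidate over partners", {
  sim <- simulate_cell_table(sim_table_config(seed = 5))
  b1 <- sim$table[sim$table$batch_id == "B1", ]
  pairs <- select_exclusive_pairs(b1, scope = "global")
  rec <- restore_threshold(b1, "CK19", pairs)
  cands <- attr(rec, "candidates")
  expect_gte(length(cands), 2)
  expect_equal(rec$value, median(cands))
  expect_identical(rec$provenance, "restore")

  single <- restore_threshold(b1, "CK19", "CD45")
  expect_equal(unname(single$value),
               unname(attr(single, "candidates")[["CD45"]]))

  # partner-positive subpopulations under 20 cells are skipped
  tiny <- b1[1:60, ]
  expect_warning(
    expect_error(restore_threshold(tiny, "CK19", "CD45", min_cells = 50),
                 "skipped"),
    "partner-positive")
})

test_that("restore_threshold recovers planted thresholds within 10%", {
  sim <- simulate_cell_table(sim_table_config(n_cells_per_group = 5000,
                                              seed = 1))
  tab <- sim$table
  for (b in c("B1", "B3")) {
    tb <- tab[tab$batch_id == b, ]
    pairs <- select_exclusive_pairs(tb, scope = "global")
    for (m in c("CK19", "CD45", "aSMA")) {
      rec <- restore_threshold(tb, m, pairs)
      expect_lt(abs(rec$value / sim$truth$thresholds[m, b] - 1), 0.1,
                label = sprintf("threshold error (%s, %s)", m, b))
    }
  }
})

test_that("restore_scale maps onto (0, 1] with the 0.02 floor", {
  set.seed(7)
  v <- c(rlnorm(900, log(50), 0.5), rlnorm(100, log(2000), 0.4))
  t <- 150
  s <- restore_scale(v, t, seed = 9)
  expect_equal(max(s), 1)                       # top cell maps to exactly 1
  expect_equal(s[which.max(v)], 1)
  expect_true(all(s[v <= t] <= 0.02))           # below-threshold floor
  expect_true(all(s > 0 & s <= 1))
  # order among above-threshold cells is preserved
  ab <- v > t
  expect_false(is.unsorted(s[ab][order(v[ab])]))
  # seeded determinism
  expect_identical(s, restore_scale(v, t, seed = 9))
  expect_false(identical(s, restore_scale(v, t, seed = 10)))
  expect_error(restore_scale(v, t), "seed")
})

test_that("reverse-compartment threshold is the opposite compartment's Q3", {
  tab <- data.frame(mean_Ki67_nucleus = rlnorm(100, 6, 1),
                    mean_Ki67_cytoplasm = 1:100)
  rec <- reverse_compartment_threshold(tab, "Ki67", "nucleus")
  expect_equal(rec$value, 75.25)   # linear-interpolation quantile
  expect_identical(rec$provenance, "reverse_quantile")
  tab2 <- data.frame(mean_Ki67_nucleus = rlnorm(100, 6, 1))
  expect_error(reverse_compartment_threshold(tab2, "Ki67", "nucleus"),
               "missing compartment")
  tab$mean_Ki67_cytoplasm <- NA_real_
  expect_error(reverse_compartment_threshold(tab, "Ki67", "nucleus"),
               "no finite")
})

test_that("batch adjustment recovers planted batch effects", {
  set.seed(8)
  n <- 2000
  base <- matrix(rnorm(2 * n * 6, 10, 2), 2 * n, 6)
  batch <- rep(c("B1", "B2"), each = n)
  shifts <- c(3, -2, 1, 4, -1, 2)   # marker-specific batch effects
  shifted <- base
  shifted[batch == "B2", ] <- sweep(shifted[batch == "B2", ], 2, shifts, "+")
  adj <- combat_adjust(shifted, batch)
  gap <- abs(colMeans(adj[batch == "B1", ]) - colMeans(adj[batch == "B2", ]))
  expect_true(all(gap < 0.05))

  # single batch: identity
  one <- combat_adjust(base, rep("B1", 2 * n))
  expect_identical(one, base)

  # no-shrinkage limit equalizes training means and variances exactly
  adj0 <- combat_adjust(shifted, batch, eb = FALSE)
  expect_equal(colMeans(adj0[batch == "B1", ]),
               colMeans(adj0[batch == "B2", ]), tolerance = 1e-6)
  expect_equal(apply(adj0[batch == "B1", ], 2, var),
               apply(adj0[batch == "B2", ], 2, var), tolerance = 1e-6)

  # errors: batch without training cells; zero-variance feature
  expect_error(combat_adjust(shifted, batch, training = batch == "B1"),
               "no training cells")
  zv <- shifted; zv[, 2] <- 5
  expect_error(combat_adjust(zv, batch), "zero-variance")
})

test_that("control-tissue training modes parameterize the batch model", {
  sim <- simulate_cell_table(sim_table_config(seed = 13,
                                              core_composition_sd = 0.4))
  tab <- sim$table
  mks <- marker_columns(tab)
  lg <- log2(as.matrix(tab[, mks]))
  tr_same <- training_cells(tab, "same", "core01")
  tr_samp <- training_cells(tab, "sampled",
                            c("core01", "core02", "core03"))
  expect_lt(sum(tr_same), sum(tr_samp))
  expect_error(training_cells(tab, "same"), "control_cores")

  kb <- function(training) {
    ta <- tab
    ta[, mks] <- combat_adjust(lg, tab$batch_id, training = training)
    s <- stratified_sample(ta, 600, seed = 7)
    g <- build_knn(as.matrix(s[, mks]), kbet_default_k(s$batch_id))
    kbet_rejection_rate(g, s$batch_id, seed = 7)$rejection_rate
  }
  same <- kb(tr_same)
  sampled <- kb(tr_samp)
  # both parameterizations remove the planted (multiplicative) batch
  # effect; pooling control cores is never worse than a single control
  expect_lte(sampled, same + 0.05)
  expect_lte(sampled, 0.2)
  expect_lte(same, 0.3)
})

test_that("combat_adjust agrees with the reference EB implementation", {
  skip_if_not_installed("sva")
  sim <- simulate_cell_table(sim_table_config(n_cells_per_group = 300,
                                              seed = 11))
  tab <- sim$table
  x <- log2(as.matrix(tab[, marker_columns(tab)]))
  mine <- combat_adjust(x, tab$batch_id)
  ref <- t(suppressMessages(sva::ComBat(t(x), batch = tab$batch_id)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("regress_out_batch equalizes means and keeps variances", {
  set.seed(12)
  x <- matrix(rlnorm(600 * 4, 4, 1), 600, 4)
  batch <- rep(c("B1", "B2", "B3"), each = 200)
  x[batch == "B2", ] <- x[batch == "B2", ] + 5
  out <- regress_out_batch(x, batch)
  for (b in unique(batch))
    expect_equal(colMeans(out[batch == b, ]), colMeans(out),
                 tolerance = 1e-10)
  for (b in unique(batch))
    expect_equal(apply(out[batch == b, ], 2, var),
                 apply(x[batch == b, ], 2, var), tolerance = 1e-10)

  # hand-computed example: batch means 2 and 11, grand mean 6.5
  hx <- matrix(c(1, 3, 10, 12), 4, 1)
  hb <- c("a", "a", "b", "b")
  got <- regress_out_batch(hx, hb)
  expect_equal(as.vector(got), c(5.5, 7.5, 5.5, 7.5))
})

test_that("full recovery chain: pairs, thresholds, batch mixing", {
  sim <- simulate_cell_table(sim_table_config(seed = 5))
  tab <- sim$table
  mks <- marker_columns(tab)

  # planted exclusive pairs are exactly the selected ones (per batch)
  b1 <- tab[tab$batch_id == "B1", ]
  pairs <- select_exclusive_pairs(b1, mks, scope = "global")
  sel <- unique(vapply(seq_len(nrow(pairs)), function(i)
    paste(sort(c(pairs$marker[i], pairs$partner[i])), collapse = "-"), ""))
  planted <- vapply(sim$truth$exclusive_pairs, function(p)
    paste(sort(p), collapse = "-"), "")
  expect_setequal(sel, planted)

  # batch adjustment on log-scale intensities: kBET drops from near 1 to
  # at most 0.2 (normalize the full table, then stratify-sample)
  lg <- log2(as.matrix(tab[, mks]))
  k <- 450
  samp_rows <- function(t2) {
    s <- stratified_sample(t2, 600, seed = 2)
    list(x = as.matrix(s[, mks]), b = s$batch_id)
  }
  tab_raw <- tab; tab_raw[, mks] <- lg
  raw <- samp_rows(tab_raw)
  kb_raw <- kbet_rejection_rate(build_knn(raw$x, k), raw$b, seed = 3)
  expect_gte(kb_raw$rejection_rate, 0.9)

  tab_adj <- tab; tab_adj[, mks] <- combat_adjust(lg, tab$batch_id)
  adj <- samp_rows(tab_adj)
  kb_adj <- kbet_rejection_rate(build_knn(adj$x, k), adj$b, seed = 3)
  expect_lte(kb_adj$rejection_rate, 0.2)
})
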