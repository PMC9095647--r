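test_that("image simulation is seed-deterministic and honors the config", {
  cfg <- sim_image_config(shape = c(96L, 96L), n_cells = 10L, rounds = 2L,
                          channels = "c2", seed = 19)
  a <- simulate_image_experiment(cfg)
  b <- simulate_image_experiment(cfg)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth$nuclei$labels, b$truth$nuclei$labels)
  c2 <- simulate_image_experiment(sim_image_config(shape = c(96L, 96L),
                                                   n_cells = 10L,
                                                   rounds = 2L,
                                                   channels = "c2",
                                                   seed = 20))
  expect_false(identical(a$stack$images, c2$stack$images))

  # degenerate config: no noise, no AF, no jitter reproduces the clean
  # signal exactly (up to rounding)
  clean <- simulate_image_experiment(sim_image_config(
    shape = c(96L, 96L), n_cells = 8L, rounds = 1L, channels = "c2",
    af_diffuse_mean = 0, af_n_fibers = 0L, gaussian_sd = 0,
    poisson_noise = FALSE, seed = 21))
  img <- stack_image(clean$stack, 1, "c2")
  expect_lte(max(abs(img - clean$truth$signal[["r1_c2"]])), 0.5)

  # nuclei do not touch: expanding each by one pixel stays disjoint
  lab <- a$truth$nuclei$labels
  grown <- expand_labels(lab, 1)$labels
  expect_equal(sum(grown > 0),
               sum(vapply(setdiff(unique(as.vector(lab)), 0L), function(k)
                 sum(expand_labels(1L * (lab == k), 1)$labels > 0), 0)))
})

test_that("planted retention schedules are realized exactly", {
  sched <- seq(1, 0.95, length.out = 10)
  rs <- simulate_dapi_retention(2000, 10, sched, seed = 22)
  expect_equal(rs$retention, round(sched * 2000) / 2000, tolerance = 1e-12)
  expect_identical(rs$dapi, simulate_dapi_retention(2000, 10, sched,
                                                    seed = 22)$dapi)
  # loss is cumulative: a lost cell never reappears
  for (r in 2:10) expect_true(all(rs$retained[, r] <= rs$retained[, r - 1]))

  img_sim <- simulate_image_experiment(sim_image_config(
    shape = c(128L, 128L), n_cells = 20L, rounds = 5L, channels = "c2",
    retention_schedule = c(1, 1, 0.9, 0.9, 0.8), seed = 23))
  expect_equal(unname(img_sim$truth$retention), c(1, 1, 0.9, 0.9, 0.8))
  expect_error(sim_image_config(retention_schedule = c(1, 0.8, 0.9),
                                rounds = 3L), "diff")
})

test_that("cell-table simulation plants exclusivity and batch effects", {
  sim <- simulate_cell_table(sim_table_config(seed = 24))
  tab <- sim$table
  expect_equal(nrow(tab), 9 * 1000)
  expect_identical(tab, simulate_cell_table(sim_table_config(seed = 24))$table)

  # exclusive markers are never jointly in their top quartiles
  for (p in sim$truth$exclusive_pairs) {
    qa <- quantile(tab[[p[1]]], 0.75)
    qb <- quantile(tab[[p[2]]], 0.75)
    both <- mean(tab[[p[1]]] >= qa & tab[[p[2]]] >= qb)
    expect_lt(both, 0.01, label = paste(p, collapse = "-"))
  }

  # batch gain: per-marker means scale with the planted gain matrix
  g <- sim$truth$gain_matrix
  m_b1 <- mean(tab$CK19[tab$batch_id == "B1"])
  m_b2 <- mean(tab$CK19[tab$batch_id == "B2"])
  expect_equal(m_b2 / m_b1, g["CK19", "B2"] / g["CK19", "B1"],
               tolerance = 0.1)
})

test_that("generated images round-trip through image I/O losslessly", {
  sim <- small_sim(seed = 25)
  img <- stack_image(sim$stack, 1, "c2")
  p <- withr::local_tempfile(fileext = ".tif")
  write_image(img, p)
  attr(img, "meta") <- NULL
  expect_identical(read_image(p), img)
})

test_that("segmentation_f1 scores matches and count errors correctly", {
  truth <- matrix(0L, 40, 40)
  truth[5:10, 5:10] <- 1L; truth[20:26, 20:26] <- 2L; truth[30:34, 5:9] <- 3L
  expect_equal(segmentation_f1(truth, truth)$f1, 1)

  pred <- truth
  pred[pred == 3L] <- 0L                      # one miss
  pred[35:39, 30:34] <- 4L                    # one spurious object
  s <- segmentation_f1(pred, truth)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$count_error, 0)

  # sub-threshold overlap does not count as a match
  shifted <- matrix(0L, 40, 40)
  shifted[9:14, 9:14] <- 1L   # IoU with truth object 1 well under 0.5
  s2 <- segmentation_f1(shifted, truth)
  expect_equal(s2$recall, 0)
})
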